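#' Logger memory fill time
#'
#' Mission planning for a data-logging accelerometer: the memory holds a
#' fixed number of sample slots, a fixed header overhead is written per
#' mission, and every enabled axis consumes one slot per sample, so
#' `fill_time_s = (memory_units - header_units) / (samples_per_s * n_axes)`.
#' The defaults describe a pendant logger with ~65,000 slots, a 500-slot
#' header, one sample every 30 s and all 3 axes enabled, which fills in
#' about 7.5 d. Memory and header are interpreted in sample slots, not
#' bytes; vendor documentation is loose on the unit, and only the slot
#' reading is consistent with the observed mission length.
#'
#' @param memory_units Sample-slot capacity, default 65000.
#' @param header_units Output-header overhead in slots, default 500.
#' @param samples_per_s Sampling rate in samples per second per axis,
#'   default `1/30`.
#' @param n_axes Number of axes enabled (1-3), default 3.
#' @return One-row tibble: `fill_time_s`, `fill_time_d`, plus the inputs.
#' @examples
#' logger_fill_time()                      # ~7.5 d at the 30-s epoch
#' logger_fill_time(samples_per_s = 1)     # 1 Hz: under 6 h
#' @export
logger_fill_time <- function(memory_units = 65000, header_units = 500,
                             samples_per_s = 1 / 30, n_axes = 3) {
  if (!(memory_units > header_units) || header_units < 0) {
    abort("memory_units must exceed header_units >= 0",
          class = "calanmeals_argument_error")
  }
  if (samples_per_s <= 0 || n_axes < 1) {
    abort("samples_per_s and n_axes must be positive",
          class = "calanmeals_argument_error")
  }
  s <- (memory_units - header_units) / (samples_per_s * n_axes)
  tibble::tibble(
    memory_units = memory_units, header_units = header_units,
    samples_per_s = samples_per_s, n_axes = n_axes,
    fill_time_s = s, fill_time_d = s / 86400
  )
}
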