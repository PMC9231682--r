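#' Classify door state from tilt angle
#'
#' A closed Calan-gate door reads ~0 deg tilt and a fully open one > 60 deg,
#' so a single threshold separates the states with margin for bracket sag.
#' Tilt at or above the threshold is coded 1 (open); below, 0 (closed). The
#' boundary is inclusive on the open side.
#'
#' @param series Tilt tibble (`cow_id`, `timestamp`, `tilt_deg`; a `day`
#'   column from [segment_days()] is carried through if present).
#' @param threshold_deg Open-door threshold in degrees, default 30.
#'
#' @return State tibble: input identifier columns plus `state` (integer 0/1),
#'   `run_id` (index of the consecutive-state run within each cow(-day)) and
#'   `run_len` (samples in the run so far).
#' @export
classify_state <- function(series, threshold_deg = 30) {
  stopifnot(threshold_deg > 0, threshold_deg < 180)
  out <- series
  out$state <- as.integer(series$tilt_deg >= threshold_deg)
  out$tilt_deg <- NULL
  add_runs(out)
}

# Annotate run_id / run_len within each cow (and day, if segmented).
add_runs <- function(states) {
  keys <- intersect(c("cow_id", "day"), names(states))
  states |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::mutate(
      run_id = cumsum(c(1L, as.integer(diff(.data$state) != 0L))),
      run_len = dplyr::row_number() -
        match(.data$run_id, .data$run_id)[dplyr::row_number()] + 1L
    ) |>
    dplyr::ungroup()
}

#' Smooth a binary state series with a centered windowed mode
#'
#' Replaces each sample by the mode of the `k` previous samples, the sample
#' itself, and the `k` following samples (a centered window of `2k + 1`).
#' Series edges use whatever window is available; ties — impossible in the
#' odd-sized interior window, possible at edges — keep the raw value. Used
#' in validation to suppress brief disturbances (an observer walking past
#' the door) before comparing sensor and observer calls.
#'
#' @param states State tibble from [classify_state()].
#' @param k Window half-width in samples, default 5.
#' @return State tibble with `state` smoothed and runs re-annotated.
#' @export
smooth_mode <- function(states, k = 5L) {
  stopifnot(k >= 1L)
  keys <- intersect(c("cow_id", "day"), names(states))
  out <- states |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::mutate(state = windowed_mode(.data$state, k)) |>
    dplyr::ungroup()
  out$run_id <- NULL
  out$run_len <- NULL
  add_runs(out)
}

windowed_mode <- function(x, k) {
  n <- length(x)
  # cumulative-sum window counts: O(n) for a binary series
  cs <- c(0L, cumsum(x))
  lo <- pmax(seq_len(n) - k, 1L)
  hi <- pmin(seq_len(n) + k, n)
  ones <- cs[hi + 1L] - cs[lo]
  len <- hi - lo + 1L
  out <- ifelse(2L * ones > len, 1L,
                ifelse(2L * ones < len, 0L, x))
  as.integer(out)
}

#' Run-length encode a state series into feeding bouts
#'
#' Collapses consecutive identical door states into alternating open/closed
#' bouts with wall-clock durations. Decoding the bout table at the same
#' epoch reproduces the input series exactly.
#'
#' @param states State tibble (one or more cow-days).
#' @param epoch_s Sampling epoch in seconds; inferred from the timestamps
#'   when `NULL`.
#'
#' @return Event tibble: `cow_id` (and `day` if present), `kind`
#'   (`"open"`/`"closed"`), `start`, `end` (timestamps of the first and last
#'   sample of the bout), `n_samples`, `duration_s = n_samples * epoch_s`.
#' @export
encode_bouts <- function(states, epoch_s = NULL) {
  if (nrow(states) == 0L) {
    abort("cannot encode an empty state series", class = "calanmeals_data_error")
  }
  epoch_s <- epoch_s %||% infer_epoch(states$timestamp)
  keys <- intersect(c("cow_id", "day"), names(states))
  if (!"run_id" %in% names(states)) states <- add_runs(states)
  states |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "run_id")))) |>
    dplyr::summarise(
      kind = ifelse(.data$state[1L] == 1L, "open", "closed"),
      start = min(.data$timestamp),
      end = max(.data$timestamp),
      n_samples = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(duration_s = .data$n_samples * epoch_s) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(keys)), .data$start) |>
    dplyr::select(-"run_id")
}

#' Decode a bout table back to a per-sample state series
#'
#' Inverse of [encode_bouts()]; useful for checking that encoding is
#' lossless.
#'
#' @param events Event tibble from [encode_bouts()].
#' @param epoch_s Sampling epoch in seconds.
#' @return State tibble with `cow_id`, (`day`,) `timestamp`, `state`.
#' @export
decode_bouts <- function(events, epoch_s) {
  keys <- intersect(c("cow_id", "day"), names(events))
  events |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::group_by(.data$.row) |>
    dplyr::reframe(
      dplyr::across(dplyr::all_of(keys), dplyr::first),
      timestamp = seq(.data$start[1L], .data$end[1L], by = epoch_s),
      state = as.integer(.data$kind[1L] == "open")
    ) |>
    dplyr::select(-".row") |>
    add_runs()
}

#' Extract between-feeding intervals from a bout table
#'
#' A between-feeding interval is a closed bout flanked by open bouts on both
#' sides within the same cow-day. Leading and trailing closed time of a day
#' is censored (there is no bounding feeding event) and never counted as an
#' interval.
#'
#' @param events Event tibble from [encode_bouts()].
#' @return Interval tibble: `cow_id`, (`day`,) `duration_s`, `start`, `end`.
#' @export
extract_intervals <- function(events) {
  keys <- intersect(c("cow_id", "day"), names(events))
  events |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::filter(
      .data$kind == "closed",
      dplyr::row_number() > 1L,
      dplyr::row_number() < dplyr::n()
    ) |>
    dplyr::ungroup() |>
    dplyr::select(dplyr::all_of(keys), "duration_s", "start", "end")
}
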