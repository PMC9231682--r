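#' Read a logger export CSV
#'
#' Logger vendors export CSV dialects that differ only in column naming, so
#' the reader takes a column map rather than assuming a fixed header. The
#' file must carry a timestamp column plus either per-axis acceleration (in
#' g) or per-axis tilt (degrees).
#'
#' @param path Path to a CSV export.
#' @param column_map Named list mapping canonical names (`timestamp`, and
#'   either `ax`/`ay`/`az` for acceleration in g or `tilt_deg` for a
#'   precomputed tilt angle) to the column names in the file. The default
#'   matches a `Date Time, X accel, Y accel, Z accel` layout.
#' @param cow_id Identifier attached to the series (default from filename).
#' @param time_format Passed to [as.POSIXct()]; default ISO-8601.
#' @param delim Field delimiter, default `","`.
#'
#' @return A tibble sorted by time with a `cow_id` column, `timestamp`
#'   (POSIXct), and either `ax`, `ay`, `az` (class `"accel_series"` semantics,
#'   units g) or `tilt_deg` (degrees). The unit layout is recorded in the
#'   `"units"` attribute (`"g"` or `"degrees"`).
#'
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("Date Time,X accel,Y accel,Z accel",
#'              "2021-06-01 05:00:00,0,0,-1",
#'              "2021-06-01 05:00:30,0,0,0",
#'              "2021-06-01 05:01:00,0,0,1"), f)
#' read_logger_csv(f, cow_id = "cow1")
#' @export
read_logger_csv <- function(path,
                            column_map = list(timestamp = "Date Time",
                                              ax = "X accel",
                                              ay = "Y accel",
                                              az = "Z accel"),
                            cow_id = NULL,
                            time_format = "%Y-%m-%d %H:%M:%S",
                            delim = ",") {
  if (!file.exists(path)) {
    abort(paste0("logger file not found: ", path), class = "calanmeals_format_error")
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  missing_cols <- setdiff(unlist(column_map), names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("logger export is missing mapped column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "calanmeals_format_error")
  }
  has_tilt <- "tilt_deg" %in% names(column_map)
  out <- tibble::tibble(
    cow_id = cow_id %||% sub("\\.[^.]*$", "", basename(path)),
    timestamp = as.POSIXct(as.character(raw[[column_map$timestamp]]),
                           format = time_format, tz = cm_tz)
  )
  if (anyNA(out$timestamp)) {
    abort(paste0("unparseable timestamp at row ",
                 which(is.na(out$timestamp))[1L]),
          class = "calanmeals_data_error")
  }
  if (has_tilt) {
    out$tilt_deg <- as.numeric(raw[[column_map$tilt_deg]])
  } else {
    out$ax <- as.numeric(raw[[column_map$ax]])
    out$ay <- as.numeric(raw[[column_map$ay]])
    out$az <- as.numeric(raw[[column_map$az]])
  }
  out <- dplyr::arrange(out, .data$timestamp)
  dup <- duplicated(out$timestamp)
  if (any(dup)) {
    abort(paste0("duplicate timestamp at row ", which(dup)[1L]),
          class = "calanmeals_data_error")
  }
  attr(out, "units") <- if (has_tilt) "degrees" else "g"
  out
}

#' Write a normalized tilt series to CSV
#'
#' @param series Tilt tibble (`cow_id`, `timestamp`, `tilt_deg`).
#' @param path Output path. Timestamps are written ISO-8601.
#' @return `path`, invisibly.
#' @export
write_tilt_csv <- function(series, path) {
  out <- dplyr::mutate(
    series,
    timestamp = format(.data$timestamp, "%Y-%m-%d %H:%M:%S", tz = cm_tz)
  )
  readr::write_csv(out[, c("cow_id", "timestamp", "tilt_deg")], path,
                   progress = FALSE)
  invisible(path)
}

#' Read back a normalized tilt CSV written by [write_tilt_csv()]
#'
#' @param path Path to the tilt CSV.
#' @return Tilt tibble with `cow_id`, `timestamp`, `tilt_deg`.
#' @export
read_tilt_csv <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  for (col in c("cow_id", "timestamp", "tilt_deg")) {
    if (!col %in% names(raw)) {
      abort(paste0("tilt CSV is missing column: ", col),
            class = "calanmeals_format_error")
    }
  }
  ts <- raw$timestamp
  if (!inherits(ts, "POSIXct")) {
    ts <- as.POSIXct(as.character(ts), format = "%Y-%m-%d %H:%M:%S",
                     tz = cm_tz)
  } else {
    attr(ts, "tzone") <- cm_tz
  }
  if (anyNA(ts)) {
    abort(paste0("unparseable timestamp at row ", which(is.na(ts))[1L]),
          class = "calanmeals_data_error")
  }
  tibble::tibble(
    cow_id = as.character(raw$cow_id),
    timestamp = ts,
    tilt_deg = as.numeric(raw$tilt_deg)
  )
}

#' Convert per-axis acceleration to tilt angle
#'
#' The door-mounted logger reports static acceleration in multiples of g;
#' the orientation of an axis relative to gravity is recovered as
#' `tilt = 180 - acos(a)` in degrees, so `a = -1` maps to 0 deg (hanging
#' straight down, door closed), `a = 0` to 90 deg, and `a = +1` to 180 deg.
#' Sensor noise can push `|a|` slightly above 1 where acos is undefined;
#' values within `tol` of the unit sphere are clipped (and counted), values
#' beyond it indicate mis-scaled units and raise an error.
#'
#' @param samples Acceleration tibble from [read_logger_csv()] with `ax`,
#'   `ay`, `az` columns in g.
#' @param axis Which axis to convert: `"X"`, `"Y"` or `"Z"` (default `"Z"`,
#'   the axis that tracks a feed-bunk door swinging open).
#' @param tol Clipping tolerance in g (default 0.05).
#'
#' @return Tilt tibble (`cow_id`, `timestamp`, `tilt_deg` in \[0, 180\]) with
#'   attribute `n_clipped`, the number of samples clipped to the unit sphere.
#'
#' @examples
#' acc <- tibble::tibble(
#'   cow_id = "c1",
#'   timestamp = as.POSIXct("2021-06-01 05:00:00", tz = "UTC") + c(0, 30, 60),
#'   ax = 0, ay = 0, az = c(-1, 0, 1)
#' )
#' compute_tilt(acc)$tilt_deg  # 0, 90, 180
#' @export
compute_tilt <- function(samples, axis = c("Z", "X", "Y"), tol = 0.05) {
  axis <- match.arg(axis)
  col <- c(X = "ax", Y = "ay", Z = "az")[[axis]]
  if (!col %in% names(samples)) {
    abort(paste0("acceleration column '", col, "' not present"),
          class = "calanmeals_format_error")
  }
  a <- samples[[col]]
  if (any(!is.finite(a))) {
    abort("non-finite acceleration value", class = "calanmeals_data_error")
  }
  over <- abs(a) > 1 + tol
  if (any(over)) {
    abort(paste0("|acceleration| exceeds ", 1 + tol,
                 " g at row ", which(over)[1L],
                 "; units are likely mis-scaled"),
          class = "calanmeals_data_error")
  }
  n_clipped <- sum(abs(a) > 1)
  a <- pmin(1, pmax(-1, a))
  out <- tibble::tibble(
    cow_id = samples$cow_id,
    timestamp = samples$timestamp,
    tilt_deg = 180 - acos(a) * 180 / pi
  )
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Split a tilt series into experimental days
#'
#' An experimental day is the 24-h period between consecutive feed
#' deliveries, anchored at a local clock boundary (default 05:00, when cows
#' are locked out of the feed alleyway for fresh feed). Each sample is
#' assigned to exactly one day; the first and last day of a record are
#' flagged partial when they do not span the full 24 h.
#'
#' @param series Tilt tibble for one cow.
#' @param boundary Day boundary as `"HH:MM"` local clock time.
#'
#' @return The input with `day` (integer index, 1-based) and a per-day
#'   `partial` flag joined on, plus attribute `day_table`, a tibble of day
#'   start/end/sample counts.
#' @export
segment_days <- function(series, boundary = "05:00") {
  if (nrow(series) == 0L) {
    out <- dplyr::mutate(series, day = integer(), partial = logical())
    attr(out, "day_table") <- tibble::tibble(
      day = integer(), start = as.POSIXct(character(), tz = cm_tz),
      end = as.POSIXct(character(), tz = cm_tz),
      n_samples = integer(), partial = logical()
    )
    return(out)
  }
  bparts <- as.integer(strsplit(boundary, ":", fixed = TRUE)[[1L]])
  offset_s <- bparts[1L] * 3600 + bparts[2L] * 60
  t0 <- as.numeric(series$timestamp)
  # day index counts 24-h windows since the boundary preceding the first sample
  anchor <- floor((t0[1L] - offset_s) / 86400) * 86400 + offset_s
  day <- as.integer(floor((t0 - anchor) / 86400)) + 1L
  epoch <- infer_epoch(series$timestamp)
  day_table <- tibble::tibble(day = day, t = t0) |>
    dplyr::group_by(.data$day) |>
    dplyr::summarise(
      start = as.POSIXct(min(.data$t), tz = cm_tz, origin = "1970-01-01"),
      end = as.POSIXct(max(.data$t), tz = cm_tz, origin = "1970-01-01"),
      n_samples = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      window_start = anchor + (.data$day - 1L) * 86400,
      partial = as.numeric(.data$start) - .data$window_start > epoch |
        (.data$window_start + 86400) - as.numeric(.data$end) > epoch
    ) |>
    dplyr::select(-"window_start")
  out <- dplyr::mutate(series, day = day)
  out <- dplyr::left_join(out, day_table[, c("day", "partial")], by = "day")
  attr(out, "day_table") <- day_table
  out
}

#' Sag quality-control report
#'
#' Door-mounted sensor brackets lose tension over a mission, so a closed
#' door can read a small positive tilt instead of ~0 deg. Samples with
#' `0 < tilt < open_threshold` are counted as sag-affected; the study
#' expectation is a few percent of all samples.
#'
#' @param series Tilt tibble.
#' @param open_threshold Open-door threshold in degrees (default 30).
#' @return A one-row tibble: `n_total`, `n_sag`, `sag_fraction`.
#' @export
sag_report <- function(series, open_threshold = 30) {
  stopifnot(open_threshold > 0, open_threshold < 180)
  n_total <- nrow(series)
  n_sag <- sum(series$tilt_deg > 0 & series$tilt_deg < open_threshold)
  tibble::tibble(
    n_total = n_total,
    n_sag = n_sag,
    sag_fraction = if (n_total > 0) n_sag / n_total else 0
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
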