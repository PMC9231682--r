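#' Merge feeding bouts into meals using the minimum intermeal interval
#'
#' Open bouts separated by closed gaps shorter than the minimum intermeal
#' interval belong to the same meal; a gap at or above the MII splits. Meal
#' length is the wall-clock span from the start of the first merged open
#' bout to the end of the last one (within-meal closed gaps count toward
#' length); the door-open time alone is also reported as `open_time_s`.
#'
#' @param events Event tibble from [encode_bouts()] (one or more cow-days).
#' @param mii_minutes Minimum intermeal interval in minutes.
#' @param epoch_s Sampling epoch in seconds; inferred when `NULL`.
#'
#' @return Meal tibble: `cow_id`, (`day`,) `meal_id`, `start`, `end`,
#'   `length_s` (span, end - start + one epoch), `open_time_s`, `n_events`
#'   (merged open bouts).
#' @export
assemble_meals <- function(events, mii_minutes, epoch_s = NULL) {
  stopifnot(mii_minutes > 0)
  mii_s <- mii_minutes * 60
  epoch_s <- epoch_s %||% (events$duration_s[1L] / events$n_samples[1L])
  keys <- intersect(c("cow_id", "day"), names(events))
  opens <- events |>
    dplyr::filter(.data$kind == "open") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::mutate(
      # closed gap preceding this open bout, within the cow-day
      gap_s = as.numeric(.data$start) - dplyr::lag(as.numeric(.data$end)) -
        epoch_s,
      meal_id = cumsum(dplyr::if_else(is.na(.data$gap_s), TRUE,
                                      .data$gap_s >= mii_s))
    ) |>
    dplyr::ungroup()
  opens |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "meal_id")))) |>
    dplyr::summarise(
      start = min(.data$start),
      end = max(.data$end),
      open_time_s = sum(.data$duration_s),
      n_events = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      length_s = as.numeric(.data$end) - as.numeric(.data$start) + epoch_s
    ) |>
    dplyr::select(dplyr::all_of(keys), "meal_id", "start", "end",
                  "length_s", "open_time_s", "n_events")
}

#' Drop meals at or below the minimum meal length
#'
#' Single-sample "meals" (one 30-s epoch of door-open time) are spurious
#' door touches rather than feeding; meals with `length_s <= min_length_s`
#' are removed, making the effective criterion a meal length strictly
#' greater than `min_length_s`.
#'
#' @param meals Meal tibble from [assemble_meals()].
#' @param min_length_s Minimum meal length in seconds, default 30.
#' @param epoch_s Sampling epoch; `min_length_s` must be at least one epoch.
#' @return Filtered meal tibble with attribute `n_removed`.
#' @export
filter_min_length <- function(meals, min_length_s = 30, epoch_s = 30) {
  stopifnot(min_length_s >= epoch_s)
  keep <- meals$length_s > min_length_s
  out <- meals[keep, ]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Per cow-day meal summaries
#'
#' @param meals Meal tibble tagged with cow and day.
#' @return Tibble with one row per cow-day: `meals_per_day`,
#'   `mean_length_min`, `total_open_min`; attribute `pooled`, a one-row
#'   tibble of pooled statistics (mean/SD of daily frequency, mean/SD and
#'   10th/90th percentiles of meal length in minutes).
#' @export
summarize_days <- function(meals) {
  if (nrow(meals) == 0L) {
    out <- tibble::tibble(cow_id = character(), day = integer(),
                          meals_per_day = integer(),
                          mean_length_min = numeric(),
                          total_open_min = numeric())
    attr(out, "pooled") <- tibble::tibble(
      mean_meals_per_day = NA_real_, sd_meals_per_day = NA_real_,
      mean_length_min = NA_real_, sd_length_min = NA_real_,
      p10_length_min = NA_real_, p90_length_min = NA_real_
    )
    return(out)
  }
  daily <- meals |>
    dplyr::group_by(.data$cow_id, .data$day) |>
    dplyr::summarise(
      meals_per_day = dplyr::n(),
      mean_length_min = mean(.data$length_s) / 60,
      total_open_min = sum(.data$open_time_s) / 60,
      .groups = "drop"
    )
  pooled <- tibble::tibble(
    mean_meals_per_day = mean(daily$meals_per_day),
    sd_meals_per_day = sd(daily$meals_per_day),
    mean_length_min = mean(meals$length_s) / 60,
    sd_length_min = sd(meals$length_s) / 60,
    p10_length_min = quantile(meals$length_s, 0.1, names = FALSE) / 60,
    p90_length_min = quantile(meals$length_s, 0.9, names = FALSE) / 60
  )
  attr(daily, "pooled") <- pooled
  daily
}
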