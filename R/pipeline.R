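#' Pipeline configuration
#'
#' One place for every stage threshold, with the conventional analysis
#' settings as defaults so the standard run needs no configuration: 30-deg
#' open threshold, 2-min short-interval filter, >30-s minimum meal length,
#' 05:00 day boundary, mixture candidates K = 2 and 3 selected by BIC.
#'
#' @param open_threshold_deg Open-door tilt threshold (degrees).
#' @param min_interval_s Short-interval exclusion before mixture fitting.
#' @param min_meal_length_s Minimum meal length; meals at or under it drop.
#' @param day_boundary Feed-delivery clock time, `"HH:MM"`.
#' @param K_candidates Mixture component counts to fit and compare.
#' @param criterion_rule `"BIC"`, `"AICc"` or `"minus2LL"`.
#' @param n_restarts EM restarts per candidate.
#' @param smooth Apply the windowed-mode smoother to states before bout
#'   encoding (off by default; it exists for observer-validation alignment).
#' @param seed Seed for EM restart jitter.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(open_threshold_deg = 30, min_interval_s = 120,
                            min_meal_length_s = 30, day_boundary = "05:00",
                            K_candidates = c(2L, 3L),
                            criterion_rule = c("BIC", "AICc", "minus2LL"),
                            n_restarts = 10L, smooth = FALSE, seed = 1L) {
  criterion_rule <- match.arg(criterion_rule)
  stopifnot(open_threshold_deg > 0, min_interval_s > 0, min_meal_length_s > 0)
  if (length(K_candidates) < 2L) {
    abort("need at least two K candidates to select a criterion model",
          class = "calanmeals_config_error")
  }
  structure(
    list(open_threshold_deg = open_threshold_deg,
         min_interval_s = min_interval_s,
         min_meal_length_s = min_meal_length_s,
         day_boundary = day_boundary,
         K_candidates = as.integer(K_candidates),
         criterion_rule = criterion_rule,
         n_restarts = as.integer(n_restarts),
         smooth = smooth, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the full feeding-behavior pipeline
#'
#' Tilt series in, meal report out: segment experimental days, classify
#' open/closed states, run-length encode bouts, pool between-feeding
#' intervals across cow-days, fit and select the log-interval Gaussian
#' mixture, derive the meal criterion, assemble and filter meals, and
#' summarize per cow-day. Every filter's in/out counts are recorded.
#'
#' @param tilt Tilt tibble (`cow_id`, `timestamp`, `tilt_deg`), one or more
#'   cows.
#' @param config A [pipeline_config()].
#' @return List of class `"feeding_report"`: `events`, `intervals`,
#'   `models` (all candidates), `model` (selected), `criterion`, `meals`,
#'   `daily`, `pooled`, `sag`, `counts` (per-stage accounting tibble),
#'   `config`.
#' @export
run_feeding_pipeline <- function(tilt, config = pipeline_config()) {
  if (nrow(tilt) == 0L) {
    abort("empty tilt input", class = "calanmeals_data_error")
  }
  epoch_s <- infer_epoch(tilt$timestamp)
  sag <- sag_report(tilt, config$open_threshold_deg)

  segmented <- tilt |>
    dplyr::group_by(.data$cow_id) |>
    dplyr::group_modify(~ segment_days(.x, boundary = config$day_boundary)) |>
    dplyr::ungroup()

  states <- classify_state(segmented[, c("cow_id", "day", "timestamp",
                                         "tilt_deg")],
                           threshold_deg = config$open_threshold_deg)
  if (isTRUE(config$smooth)) states <- smooth_mode(states)
  events <- encode_bouts(states, epoch_s = epoch_s)
  intervals <- extract_intervals(events)
  log_iv <- prepare_intervals(intervals, min_interval_s = config$min_interval_s)

  models <- purrr::map(config$K_candidates, function(K) {
    fit_mixture(log_iv, K = K, n_restarts = config$n_restarts,
                seed = config$seed)
  })
  model <- select_model(models, rule = config$criterion_rule)
  criterion <- meal_criterion(model)

  meals_all <- assemble_meals(events, mii_minutes = criterion$mii_minutes,
                              epoch_s = epoch_s)
  meals <- filter_min_length(meals_all,
                             min_length_s = config$min_meal_length_s,
                             epoch_s = epoch_s)
  daily <- summarize_days(meals)

  counts <- tibble::tibble(
    stage = c("samples", "open_bouts", "raw_intervals",
              "intervals_excluded_short", "intervals_fitted",
              "meals_assembled", "meals_removed_short", "meals_kept"),
    n = c(nrow(tilt), sum(events$kind == "open"), nrow(intervals),
          attr(log_iv, "n_excluded_short"), attr(log_iv, "n"),
          nrow(meals_all), attr(meals, "n_removed"), nrow(meals))
  )

  structure(
    list(events = events, intervals = intervals, models = models,
         model = model, criterion = criterion, meals = meals,
         daily = daily, pooled = attr(daily, "pooled"), sag = sag,
         counts = counts, epoch_s = epoch_s, config = config),
    class = "feeding_report"
  )
}

#' @export
print.feeding_report <- function(x, ...) {
  cat("Feeding-behavior pipeline report\n")
  print(x$counts)
  cat(sprintf("Selected mixture: K = %d (%s rule)\n",
              x$model$K, x$config$criterion_rule))
  print(x$criterion)
  if (!is.null(x$pooled) && is.finite(x$pooled$mean_meals_per_day)) {
    cat(sprintf("Meals: %.1f +/- %.1f per day; length %.1f +/- %.1f min\n",
                x$pooled$mean_meals_per_day, x$pooled$sd_meals_per_day,
                x$pooled$mean_length_min, x$pooled$sd_length_min))
  }
  invisible(x)
}

#' Write a feeding report to disk
#'
#' Emits events, intervals, meals and daily summaries as CSV plus a JSON
#' report of the mixture candidates, the selected criterion, the pooled
#' statistics and the stage accounting.
#'
#' @param report A `"feeding_report"`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_feeding_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(report$events, file.path(dir, "events.csv"),
                   progress = FALSE)
  readr::write_csv(report$intervals, file.path(dir, "intervals.csv"),
                   progress = FALSE)
  readr::write_csv(report$meals, file.path(dir, "meals.csv"),
                   progress = FALSE)
  readr::write_csv(report$daily, file.path(dir, "daily_summary.csv"),
                   progress = FALSE)
  json <- list(
    models = purrr::map(report$models, function(m) {
      list(K = m$K, weight = m$weight, mean = m$mean, sd = m$sd,
           minus2LL = m$minus2LL, AICc = m$AICc, BIC = m$BIC, n = m$n)
    }),
    selected_K = report$model$K,
    criterion = list(C = report$criterion$C,
                     mii_minutes = report$criterion$mii_minutes),
    pooled = as.list(report$pooled),
    sag = as.list(report$sag),
    counts = setNames(as.list(report$counts$n), report$counts$stage)
  )
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Plot a day of door states as an ethogram-style ribbon
#'
#' @param states State tibble from [classify_state()].
#' @param cow One cow id to plot (default the first).
#' @return A ggplot of open bouts over time, one row per day if segmented.
#' @export
plot_state_ribbon <- function(states, cow = states$cow_id[1L]) {
  df <- dplyr::filter(states, .data$cow_id == cow)
  ev <- encode_bouts(df)
  opens <- dplyr::filter(ev, .data$kind == "open")
  has_day <- "day" %in% names(opens)
  p <- ggplot2::ggplot(opens)
  if (has_day) {
    p <- p + ggplot2::geom_segment(
      ggplot2::aes(x = .data$start, xend = .data$end,
                   y = factor(.data$day), yend = factor(.data$day)),
      linewidth = 4, color = "steelblue") +
      ggplot2::labs(y = "experimental day")
  } else {
    p <- p + ggplot2::geom_segment(
      ggplot2::aes(x = .data$start, xend = .data$end, y = 1, yend = 1),
      linewidth = 4, color = "steelblue") +
      ggplot2::labs(y = NULL)
  }
  p + ggplot2::labs(x = NULL, title = paste("Door-open bouts:", cow)) +
    ggplot2::theme_minimal()
}
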