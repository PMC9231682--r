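#' Configuration for the synthetic feeding-behavior generator
#'
#' Describes a group of cows visiting keyed feed-bunk doors: each cow
#' alternates door-open bouts with closed gaps drawn from a log-normal
#' mixture whose two rightmost components sit at the drink-pause and
#' intermeal regimes; a third, leftmost component populates the sub-2-min
#' within-meal pauses that the short-interval filter removes. The door
#' sensor reads ~0 deg closed and ~70 deg open, with occasional bracket
#' slack ("sag") that lets the closed baseline drift until the bracket is
#' re-tightened, and Gaussian read noise. A human observer samples door
#' state about every 2 min 50 s with timing jitter and an optional
#' label-flip error rate.
#'
#' @param n_cows Number of cows/doors, default 48.
#' @param n_days Number of 24-h experimental days, default 7.
#' @param epoch_s Logger epoch in seconds, default 30.
#' @param gap_meanlog,gap_sdlog,gap_weight Log-scale means, SDs and weights
#'   of the closed-gap mixture (log-seconds). Defaults place components at
#'   `exp(4.0) ~ 55 s` (within-meal pauses), `exp(6.34) ~ 9.4 min` (drink
#'   pauses) and `exp(8.77) ~ 107 min` (between meals) with weights
#'   0.69/0.19/0.12 so roughly 63% of raw gaps fall under the 2-min filter.
#' @param open_meanlog,open_sdlog Log-normal open-bout length (seconds);
#'   default median 5 min.
#' @param closed_angle_deg Closed-door baseline tilt, default 0.
#' @param open_angle_mean_deg Open-door mean tilt, default 70.
#' @param angle_noise_sd_deg Read-noise SD on open-door tilt, default 2.
#' @param closed_noise_sd_deg Read-noise SD on closed-door tilt, default 0
#'   (a slack-free closed door presses the sensor to its resting angle).
#' @param sag_prob Probability that a tightening interval develops slack,
#'   default 0.06.
#' @param sag_rate_deg_per_day Drift rate of a slack bracket, default 50.
#' @param sag_cap_deg Maximum sag, default 25; must stay below the open
#'   threshold or closed doors would misclassify.
#' @param sag_reset_hours Hours between bracket tightenings, default 12
#'   (checked twice daily).
#' @param observer_cadence_s Mean seconds between observer records,
#'   default 170.
#' @param observer_jitter_s SD of cadence jitter, default 15.
#' @param observer_flip_rate Probability an observer label is recorded
#'   wrong, default 0.
#' @param day_boundary Feed-delivery clock time anchoring experimental
#'   days, default `"05:00"`.
#' @param start Date-time of the first feed delivery.
#' @param seed Integer seed; mandatory, all randomness derives from it.
#'
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_cows = 48L, n_days = 7L, epoch_s = 30,
                       gap_meanlog = c(4.0, 6.34, 8.77),
                       gap_sdlog = c(0.60, 0.61, 0.63),
                       gap_weight = c(0.69, 0.19, 0.12),
                       open_meanlog = log(300), open_sdlog = 0.5,
                       closed_angle_deg = 0, open_angle_mean_deg = 70,
                       angle_noise_sd_deg = 2, closed_noise_sd_deg = 0,
                       sag_prob = 0.06, sag_rate_deg_per_day = 50,
                       sag_cap_deg = 25, sag_reset_hours = 12,
                       observer_cadence_s = 170, observer_jitter_s = 15,
                       observer_flip_rate = 0,
                       day_boundary = "05:00",
                       start = as.POSIXct("2021-06-01 05:00:00", tz = "UTC"),
                       seed) {
  if (missing(seed)) {
    abort("a seed is mandatory for reproducible simulation",
          class = "calanmeals_config_error")
  }
  stopifnot(length(gap_meanlog) == length(gap_sdlog),
            length(gap_meanlog) == length(gap_weight))
  if (abs(sum(gap_weight) - 1) > 1e-8) {
    abort("gap_weight must sum to 1", class = "calanmeals_config_error")
  }
  if (sag_cap_deg >= 30) {
    abort("sag_cap_deg must stay below the 30-deg open threshold",
          class = "calanmeals_config_error")
  }
  structure(
    list(n_cows = n_cows, n_days = n_days, epoch_s = epoch_s,
         gap_meanlog = gap_meanlog, gap_sdlog = gap_sdlog,
         gap_weight = gap_weight,
         open_meanlog = open_meanlog, open_sdlog = open_sdlog,
         closed_angle_deg = closed_angle_deg,
         open_angle_mean_deg = open_angle_mean_deg,
         angle_noise_sd_deg = angle_noise_sd_deg,
         closed_noise_sd_deg = closed_noise_sd_deg,
         sag_prob = sag_prob, sag_rate_deg_per_day = sag_rate_deg_per_day,
         sag_cap_deg = sag_cap_deg, sag_reset_hours = sag_reset_hours,
         observer_cadence_s = observer_cadence_s,
         observer_jitter_s = observer_jitter_s,
         observer_flip_rate = observer_flip_rate,
         day_boundary = day_boundary, start = start,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate true visit events for all cows
#'
#' Generates, per cow, an alternating sequence of closed gaps and open
#' bouts covering `n_days` experimental days. Gap durations come from the
#' configured log-normal mixture, open bouts from the open-bout log-normal;
#' all durations snap to whole epochs (minimum one epoch) so the event
#' table is exactly representable on the logger grid.
#'
#' @param config A [sim_config()].
#' @return Event tibble: `cow_id`, `kind`, `start`, `end` (first/last
#'   sample timestamps), `n_samples`, `duration_s`, `gap_component`
#'   (mixture component index for closed bouts, NA for open).
#' @export
simulate_visits <- function(config) {
  withr_seed(config$seed, {
    purrr::map_dfr(seq_len(config$n_cows), function(i) {
      simulate_cow_events(config, sprintf("cow%02d", i))
    })
  })
}

simulate_cow_events <- function(config, cow_id) {
  ep <- config$epoch_s
  span_samples <- config$n_days * 86400 / ep
  t0 <- as.numeric(config$start)
  # draw in blocks until the span is covered
  kind <- character(0); n_smp <- integer(0); comp <- integer(0)
  total <- 0L
  while (total < span_samples) {
    g_comp <- sample.int(length(config$gap_weight), 1L,
                         prob = config$gap_weight)
    gap <- rlnorm(1L, config$gap_meanlog[g_comp], config$gap_sdlog[g_comp])
    open <- rlnorm(1L, config$open_meanlog, config$open_sdlog)
    gap_n <- max(1L, as.integer(round(gap / ep)))
    open_n <- max(1L, as.integer(round(open / ep)))
    kind <- c(kind, "closed", "open")
    n_smp <- c(n_smp, gap_n, open_n)
    comp <- c(comp, g_comp, NA_integer_)
    total <- total + gap_n + open_n
  }
  # trim the final bout to the span
  cum <- cumsum(n_smp)
  last <- which(cum >= span_samples)[1L]
  kind <- kind[seq_len(last)]; n_smp <- n_smp[seq_len(last)]
  comp <- comp[seq_len(last)]
  n_smp[last] <- n_smp[last] - (cum[last] - span_samples)
  keep <- n_smp > 0L
  kind <- kind[keep]; n_smp <- n_smp[keep]; comp <- comp[keep]
  start_idx <- cumsum(c(0L, head(n_smp, -1L)))
  tibble::tibble(
    cow_id = cow_id,
    kind = kind,
    start = as.POSIXct(t0 + start_idx * ep, tz = cm_tz,
                       origin = "1970-01-01"),
    end = as.POSIXct(t0 + (start_idx + n_smp - 1L) * ep, tz = cm_tz,
                     origin = "1970-01-01"),
    n_samples = n_smp,
    duration_s = n_smp * ep,
    gap_component = comp
  )
}

#' Simulate the tilt series a logger would record for true events
#'
#' Per-epoch tilt is the open angle plus read noise during open bouts and
#' the closed baseline plus sag during closed bouts. Sag is modeled as
#' bracket slack: at every tightening (every `sag_reset_hours`) the
#' baseline resets to the closed angle; a tightening interval develops
#' slack with probability `sag_prob`, in which case the baseline ramps
#' linearly at `sag_rate_deg_per_day`, capped at `sag_cap_deg`.
#'
#' @param events Event tibble from [simulate_visits()].
#' @param config A [sim_config()].
#' @return Tilt tibble: `cow_id`, `timestamp`, `tilt_deg`, plus truth
#'   columns `true_state` (0/1) and `sag_deg` (planted closed-door
#'   baseline).
#' @export
simulate_tilt <- function(events, config) {
  withr_seed(config$seed + 1L, {
    purrr::map_dfr(split(events, events$cow_id), function(ev) {
      simulate_cow_tilt(ev, config)
    })
  })
}

simulate_cow_tilt <- function(ev, config) {
  ep <- config$epoch_s
  t0 <- as.numeric(min(ev$start))
  t1 <- as.numeric(max(ev$end))
  ts <- seq(t0, t1, by = ep)
  n <- length(ts)
  state <- integer(n)
  for (j in which(ev$kind == "open")) {
    i0 <- as.integer((as.numeric(ev$start[j]) - t0) / ep) + 1L
    i1 <- as.integer((as.numeric(ev$end[j]) - t0) / ep) + 1L
    state[i0:i1] <- 1L
  }
  # per-tightening-interval slack
  reset_s <- config$sag_reset_hours * 3600
  interval <- floor((ts - t0) / reset_s)
  n_int <- max(interval) + 1L
  slack <- runif(n_int) < config$sag_prob
  t_in <- (ts - t0) - interval * reset_s
  sag <- ifelse(slack[interval + 1L],
                pmin(config$sag_rate_deg_per_day * t_in / 86400,
                     config$sag_cap_deg),
                0)
  tilt <- ifelse(
    state == 1L,
    rnorm(n, config$open_angle_mean_deg, config$angle_noise_sd_deg),
    config$closed_angle_deg + sag +
      if (config$closed_noise_sd_deg > 0) {
        rnorm(n, 0, config$closed_noise_sd_deg)
      } else 0
  )
  tibble::tibble(
    cow_id = ev$cow_id[1L],
    timestamp = as.POSIXct(ts, tz = cm_tz, origin = "1970-01-01"),
    tilt_deg = pmin(pmax(tilt, 0), 180),
    true_state = state,
    sag_deg = ifelse(state == 1L, NA_real_, sag)
  )
}

#' Simulate an observer log over true events
#'
#' Samples the true door state at jittered timestamps (~one record every
#' `observer_cadence_s`) across a window, flipping each label with
#' probability `observer_flip_rate`.
#'
#' @param events Event tibble for one cow from [simulate_visits()].
#' @param config A [sim_config()].
#' @param window_start,window_end Observation window; defaults to the first
#'   6 h of the record.
#' @return Observer tibble: `cow_id`, `timestamp`, `label`, `true_label`.
#' @export
simulate_observer <- function(events, config,
                              window_start = min(events$start),
                              window_end = min(events$start) + 6 * 3600) {
  stopifnot(config$observer_cadence_s > 0)
  withr_seed(config$seed + 2L, {
    t0 <- as.numeric(window_start)
    t1 <- as.numeric(window_end)
    n_max <- ceiling((t1 - t0) / config$observer_cadence_s) + 10L
    steps <- config$observer_cadence_s +
      rnorm(n_max, 0, config$observer_jitter_s)
    steps <- pmax(steps, config$observer_cadence_s / 4)
    ts <- t0 + cumsum(steps)
    ts <- ts[ts <= t1]
    truth <- state_at(events, ts)
    flip <- runif(length(ts)) < config$observer_flip_rate
    lab <- ifelse(xor(truth == 1L, flip), "open", "closed")
    tibble::tibble(
      cow_id = events$cow_id[1L],
      timestamp = as.POSIXct(ts, tz = cm_tz, origin = "1970-01-01"),
      label = lab,
      true_label = ifelse(truth == 1L, "open", "closed")
    )
  })
}

# True door state at arbitrary instants. Sample timestamps mark epoch
# centers, so an open bout's footprint is [start - epoch/2, end + epoch/2):
# the instantaneous truth then agrees with nearest-sample alignment.
state_at <- function(events, ts) {
  opens <- events[events$kind == "open", ]
  ep <- events$duration_s[1L] / events$n_samples[1L]
  out <- integer(length(ts))
  s <- as.numeric(opens$start) - ep / 2
  e <- as.numeric(opens$end) + ep / 2
  idx <- findInterval(ts, s)
  inside <- idx >= 1L & ts < e[pmax(idx, 1L)]
  out[inside] <- 1L
  out
}

#' Generate a full ground-truthed synthetic study
#'
#' Bundles [simulate_visits()], [simulate_tilt()] and (for the first door)
#' [simulate_observer()] together with the planted meal criterion — the
#' density intersection of the two rightmost gap components — so every
#' pipeline stage can be checked against truth.
#'
#' @param config A [sim_config()].
#' @return List of class `"truth_bundle"`: `events`, `tilt`, `observer`,
#'   `planted_criterion` (a `"meal_criterion"`), `config`.
#' @export
simulate_feeding_study <- function(config) {
  events <- simulate_visits(config)
  tilt <- simulate_tilt(events, config)
  first_cow <- events[events$cow_id == events$cow_id[1L], ]
  observer <- simulate_observer(first_cow, config)
  m <- length(config$gap_meanlog)
  ord <- order(config$gap_meanlog)
  i <- ord[(m - 1L):m]
  planted <- meal_criterion_from_params(
    config$gap_meanlog[i[1L]], config$gap_sdlog[i[1L]],
    config$gap_meanlog[i[2L]], config$gap_sdlog[i[2L]]
  )
  structure(
    list(events = events, tilt = tilt, observer = observer,
         planted_criterion = planted, config = config),
    class = "truth_bundle"
  )
}
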