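# Shared fixture builders. Everything is generated in code; no stored data.

t_origin <- as.POSIXct("2021-06-01 05:00:00", tz = "UTC")

# A tilt tibble on a regular epoch grid.
make_tilt <- function(tilt_deg, epoch_s = 30, cow_id = "c1",
                      start = t_origin) {
  tibble::tibble(
    cow_id = cow_id,
    timestamp = start + (seq_along(tilt_deg) - 1L) * epoch_s,
    tilt_deg = tilt_deg
  )
}

# A state tibble straight from a 0/1 vector.
make_states <- function(state, epoch_s = 30, cow_id = "c1",
                        start = t_origin) {
  calanmeals:::add_runs(tibble::tibble(
    cow_id = cow_id,
    timestamp = start + (seq_along(state) - 1L) * epoch_s,
    state = as.integer(state)
  ))
}

# Event tibble from a run-length spec: kinds and sample counts.
make_events <- function(kind, n_samples, epoch_s = 30, cow_id = "c1",
                        start = t_origin) {
  start_idx <- cumsum(c(0L, head(n_samples, -1L)))
  bout_start <- start + start_idx * epoch_s
  bout_end <- start + (start_idx + n_samples - 1L) * epoch_s
  tibble::tibble(
    cow_id = cow_id,
    kind = kind,
    start = bout_start,
    end = bout_end,
    n_samples = as.integer(n_samples),
    duration_s = n_samples * epoch_s
  )
}

# Brute-force windowed mode of a binary vector (independent of the
# implementation's cumulative-sum path).
brute_mode <- function(x, k) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    w <- x[max(1, i - k):min(n, i + k)]
    n1 <- sum(w == 1)
    n0 <- length(w) - n1
    if (n1 > n0) 1L else if (n0 > n1) 0L else as.integer(x[i])
  }, integer(1))
}

# Bisection root of the difference of two unit-mass normal densities on
# (mu1, mu2); the independent oracle for intersection_point().
bisect_intersection <- function(mu1, s1, mu2, s2, tol = 1e-12) {
  f <- function(x) dnorm(x, mu1, s1) - dnorm(x, mu2, s2)
  lo <- mu1
  hi <- mu2
  stopifnot(f(lo) > 0, f(hi) < 0)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Random component parameters with a guaranteed density crossing between
# the means (each component dominates at its own mean, as in any fit where
# the two regimes are actually distinct).
draw_crossing_params <- function(mu_lo = -5, mu_hi = 5, gap_lo = 0.5,
                                 gap_hi = 6, s_lo = 0.2, s_hi = 2) {
  repeat {
    mu1 <- runif(1, mu_lo, mu_hi)
    mu2 <- mu1 + runif(1, gap_lo, gap_hi)
    s1 <- runif(1, s_lo, s_hi)
    s2 <- runif(1, s_lo, s_hi)
    if (abs(s1 - s2) < 1e-6) next
    if (dnorm(mu1, mu1, s1) > dnorm(mu1, mu2, s2) &&
        dnorm(mu2, mu2, s2) > dnorm(mu2, mu1, s1)) {
      return(c(mu1 = mu1, s1 = s1, mu2 = mu2, s2 = s2))
    }
  }
}

# Brute-force meal merge: scan open bouts, join when the preceding closed
# gap is under the criterion. Returns number of meals per cow-day group.
brute_meal_count <- function(events, mii_s, epoch_s = 30) {
  opens <- events[events$kind == "open", ]
  if (nrow(opens) == 0) return(0L)
  n_meals <- 1L
  for (j in seq_len(nrow(opens))[-1]) {
    gap <- as.numeric(opens$start[j]) - as.numeric(opens$end[j - 1]) - epoch_s
    if (gap >= mii_s) n_meals <- n_meals + 1L
  }
  n_meals
}

# A random alternating event table starting and ending with an open bout.
random_events <- function(n_open, epoch_s = 30, max_len = 40L) {
  n_bouts <- 2L * n_open - 1L
  kind <- rep(c("open", "closed"), length.out = n_bouts)
  n_samples <- sample.int(max_len, n_bouts, replace = TRUE)
  make_events(kind, n_samples, epoch_s = epoch_s)
}
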