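#' Align observer annotations to sensor states
#'
#' Each observer record is paired with the sensor call at the nearest sensor
#' timestamp (absolute time distance, ties to the earlier sample), taken as
#' the mode of the window of `k` samples before through `k` after that
#' sample. The windowed mode suppresses brief disturbances to the cow's
#' behavior caused by the observer's presence. Observer records outside the
#' sensor recording span are dropped and counted.
#'
#' @param log Observer tibble: `timestamp`, `label` (`"open"`/`"closed"`),
#'   optionally `door_id`/`cow_id`.
#' @param states Sensor state tibble from [classify_state()] for the same
#'   door.
#' @param k Mode window half-width in samples, default 5.
#'
#' @return Tibble of pairs: `timestamp`, `sensor` and `observer` (both
#'   integer 0/1), with attribute `n_dropped`.
#' @export
align_to_sensor <- function(log, states, k = 5L) {
  st <- as.numeric(states$timestamp)
  ot <- as.numeric(log$timestamp)
  inside <- ot >= min(st) & ot <= max(st)
  n_dropped <- sum(!inside)
  if (n_dropped > 0) {
    warn(paste0(n_dropped, " observer record(s) outside the sensor span dropped"))
  }
  ot <- ot[inside]
  lab <- log$label[inside]
  # nearest sensor index; findInterval gives the left neighbor
  left <- findInterval(ot, st)
  left[left == 0L] <- 1L
  right <- pmin(left + 1L, length(st))
  dl <- abs(ot - st[left])
  dr <- abs(ot - st[right])
  idx <- ifelse(dr < dl, right, left)  # ties -> earlier sample
  sensor <- vapply(idx, function(i) {
    w <- states$state[max(1L, i - k):min(length(st), i + k)]
    binary_mode(w, tie = states$state[i])
  }, integer(1))
  out <- tibble::tibble(
    timestamp = as.POSIXct(ot, tz = cm_tz, origin = "1970-01-01"),
    sensor = sensor,
    observer = as.integer(lab == "open")
  )
  attr(out, "n_dropped") <- n_dropped
  out
}

#' 2x2 contingency table of sensor vs observer calls
#'
#' @param pairs Pair tibble from [align_to_sensor()].
#' @return One-row tibble: `n11` (both open), `n10` (sensor open, observer
#'   closed), `n01`, `n00`, `n`.
#' @export
contingency <- function(pairs) {
  stopifnot(nrow(pairs) > 0)
  tibble::tibble(
    n11 = sum(pairs$sensor == 1L & pairs$observer == 1L),
    n10 = sum(pairs$sensor == 1L & pairs$observer == 0L),
    n01 = sum(pairs$sensor == 0L & pairs$observer == 1L),
    n00 = sum(pairs$sensor == 0L & pairs$observer == 0L),
    n = nrow(pairs)
  )
}

#' Cohen's kappa with asymptotic confidence interval
#'
#' Chance-corrected agreement between the sensor and the observer:
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement `p_o` and
#' chance agreement `p_e` from the marginals. The standard large-sample
#' standard error `sqrt(p_o (1 - p_o) / (n (1 - p_e)^2))` gives the 95% CI
#' as `kappa +/- 1.96 SE`.
#'
#' @param table One-row contingency tibble from [contingency()].
#' @return One-row tibble: `kappa`, `se_kappa`, `ci_lo`, `ci_hi`,
#'   `observed_agreement`, `expected_agreement`.
#' @examples
#' cohens_kappa(tibble::tibble(n11 = 40, n10 = 5, n01 = 10, n00 = 45, n = 100))
#' @export
cohens_kappa <- function(table) {
  n <- table$n11 + table$n10 + table$n01 + table$n00
  stopifnot(n > 0)
  p_o <- (table$n11 + table$n00) / n
  p_sensor_open <- (table$n11 + table$n10) / n
  p_obs_open <- (table$n11 + table$n01) / n
  p_e <- p_sensor_open * p_obs_open + (1 - p_sensor_open) * (1 - p_obs_open)
  if (1 - p_e < .Machine$double.eps) {
    abort("kappa undefined: chance agreement is 1 (degenerate marginals)",
          class = "calanmeals_argument_error")
  }
  kappa <- (p_o - p_e) / (1 - p_e)
  se <- sqrt(p_o * (1 - p_o) / (n * (1 - p_e)^2))
  tibble::tibble(
    kappa = kappa, se_kappa = se,
    ci_lo = kappa - qnorm(0.975) * se,
    ci_hi = kappa + qnorm(0.975) * se,
    observed_agreement = p_o,
    expected_agreement = p_e
  )
}

#' Positive and negative predictive values of the sensor
#'
#' PPV is the probability that a sensor "open" call is correct against the
#' observer reference, `n11 / (n11 + n10)`; NPV the same for "closed",
#' `n00 / (n00 + n01)`.
#'
#' @param table One-row contingency tibble from [contingency()].
#' @return One-row tibble `ppv`, `npv` (NA with a warning when a sensor
#'   margin is empty).
#' @export
predictive_values <- function(table) {
  open_total <- table$n11 + table$n10
  closed_total <- table$n00 + table$n01
  if (open_total == 0 || closed_total == 0) {
    warn("a sensor margin is empty; the corresponding predictive value is NA")
  }
  tibble::tibble(
    ppv = if (open_total > 0) table$n11 / open_total else NA_real_,
    npv = if (closed_total > 0) table$n00 / closed_total else NA_real_
  )
}

#' Full sensor-vs-observer validation
#'
#' Aligns an observer log to sensor states and computes the contingency
#' table, Cohen's kappa with its 95% CI, and predictive values in one call.
#'
#' @inheritParams align_to_sensor
#' @return A list of class `"agreement_validation"`: `pairs`, `table`,
#'   `kappa` (tibble), `predictive` (tibble), `n_dropped`.
#' @export
validate_agreement <- function(log, states, k = 5L) {
  pairs <- align_to_sensor(log, states, k = k)
  tab <- contingency(pairs)
  structure(
    list(pairs = pairs, table = tab, kappa = cohens_kappa(tab),
         predictive = predictive_values(tab),
         n_dropped = attr(pairs, "n_dropped")),
    class = "agreement_validation"
  )
}

#' @export
print.agreement_validation <- function(x, ...) {
  cat("Sensor vs observer agreement\n")
  cat(sprintf("  n = %d pairs (%d dropped outside span)\n",
              x$table$n, x$n_dropped))
  cat(sprintf("  kappa = %.3f (95%% CI %.3f-%.3f)\n",
              x$kappa$kappa, x$kappa$ci_lo, x$kappa$ci_hi))
  cat(sprintf("  PPV = %.3f  NPV = %.3f\n",
              x$predictive$ppv, x$predictive$npv))
  invisible(x)
}

#' One-row summary of an agreement validation
#' @param x An `"agreement_validation"`.
#' @param ... Unused.
#' @return Tibble with counts, kappa, CI, PPV and NPV.
#' @method glance agreement_validation
#' @export
glance.agreement_validation <- function(x, ...) {
  dplyr::bind_cols(x$table, x$kappa, x$predictive)
}

#' Tidy the contingency table of an agreement validation
#' @param x An `"agreement_validation"`.
#' @param ... Unused.
#' @return Long tibble: `sensor`, `observer`, `count`.
#' @method tidy agreement_validation
#' @export
tidy.agreement_validation <- function(x, ...) {
  tibble::tibble(
    sensor = c("open", "open", "closed", "closed"),
    observer = c("open", "closed", "open", "closed"),
    count = c(x$table$n11, x$table$n10, x$table$n01, x$table$n00)
  )
}
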