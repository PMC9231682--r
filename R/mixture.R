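#' Prepare between-feeding intervals for mixture fitting
#'
#' Intervals shorter than `min_interval_s` (default 2 min) are dropped
#' before fitting: at a 30-s epoch the short-pause regime is badly resolved,
#' and meal criteria in comparable systems are far above 2 min, so the short
#' mass only distorts the fit. Surviving durations are natural-log
#' transformed (log-seconds, the scale on which the mixture is modeled).
#'
#' @param intervals Interval tibble from [extract_intervals()], or a numeric
#'   vector of durations in seconds.
#' @param min_interval_s Short-interval exclusion cutoff in seconds,
#'   default 120.
#' @param min_n Minimum surviving count below which fitting would be
#'   unstable (default 50).
#'
#' @return A tibble with one column `log_s` and attributes `n`,
#'   `n_excluded_short`, `n_raw`.
#' @export
prepare_intervals <- function(intervals, min_interval_s = 120, min_n = 50L) {
  durations <- if (is.data.frame(intervals)) intervals$duration_s else intervals
  stopifnot(all(durations > 0))
  keep <- durations >= min_interval_s
  n_excluded <- sum(!keep)
  out <- tibble::tibble(log_s = log(durations[keep]))
  if (nrow(out) < min_n) {
    abort(paste0("only ", nrow(out), " intervals survive the ",
                 min_interval_s, "-s cutoff; need at least ", min_n),
          class = "calanmeals_insufficient_data")
  }
  attr(out, "n") <- nrow(out)
  attr(out, "n_excluded_short") <- n_excluded
  attr(out, "n_raw") <- length(durations)
  out
}

#' Fit a univariate Gaussian mixture by EM
#'
#' Fits a `K`-component normal mixture to log-transformed between-feeding
#' intervals by maximum likelihood (expectation-maximization). Components
#' are returned sorted by ascending mean. Initialization uses quantile-based
#' means, the pooled SD and uniform weights; additional restarts jitter the
#' initial means, and the best restart by likelihood is kept. Because
#' interval durations are quantized to whole epochs, tied values make the
#' mixture likelihood unbounded (a component can spike on an atom);
#' component SDs are therefore floored at `min_sigma`, and a restart that
#' empties a component is discarded as degenerate.
#'
#' Free parameters are counted as `k = 3K - 1` (K means, K SDs, K - 1
#' weights); `AICc = -2LL + 2k + 2k(k + 1)/(n - k - 1)` and
#' `BIC = -2LL + k log(n)`.
#'
#' @param data Output of [prepare_intervals()], or a numeric vector on the
#'   log scale.
#' @param K Number of components (1 to 4 are sensible here).
#' @param n_restarts EM restarts, default 10.
#' @param seed Seed controlling restart jitter; default 1.
#' @param tol Convergence tolerance on the log-likelihood change,
#'   default 1e-8.
#' @param max_iter Maximum EM iterations per restart, default 500.
#' @param min_sigma Variance floor: minimum component SD, default 0.05
#'   (log-units; about half the log-scale spacing of epoch-quantized
#'   durations near the short-interval cutoff).
#'
#' @return An object of class `"meal_mixture"`: list with `K`, `weight`,
#'   `mean`, `sd` (sorted by mean), `loglik`, `minus2LL`, `AICc`, `BIC`,
#'   `n`, `k_free`, `n_iter`, `loglik_trace`.
#'
#' @examples
#' set.seed(1)
#' x <- c(rnorm(300, 6.3, 0.6), rnorm(300, 8.8, 0.6))
#' fit <- fit_mixture(x, K = 2)
#' tidy(fit)
#' @export
fit_mixture <- function(data, K, n_restarts = 10L, seed = 1L,
                        tol = 1e-8, max_iter = 500L, min_sigma = 0.05) {
  x <- if (is.data.frame(data)) data$log_s else as.numeric(data)
  n <- length(x)
  k_free <- 3L * K - 1L
  if (n <= 10L * k_free) {
    abort(paste0("n = ", n, " is too small to fit K = ", K,
                 " components stably"),
          class = "calanmeals_insufficient_data")
  }
  if (K == 1L) {
    mu <- mean(x)
    sigma <- sqrt(mean((x - mu)^2))  # MLE variance
    ll <- sum(dnorm(x, mu, sigma, log = TRUE))
    return(new_meal_mixture(1L, 1, mu, sigma, ll, n, n_iter = 0L,
                            loglik_trace = ll))
  }

  best <- NULL
  withr_seed(seed, {
    for (r in seq_len(n_restarts)) {
      init_mu <- quantile(x, probs = (seq_len(K) - 0.5) / K, names = FALSE)
      if (r > 1L) init_mu <- init_mu + rnorm(K, 0, sd(x) / 4)
      fit <- em_once(x, K, init_mu, sd_init = sd(x), tol = tol,
                     max_iter = max_iter, min_sigma = min_sigma)
      if (is.null(fit)) next
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
  })
  if (is.null(best)) {
    abort("all EM restarts collapsed a component; cannot fit",
          class = "calanmeals_fit_error")
  }
  ord <- order(best$mu)
  new_meal_mixture(K, best$pi[ord], best$mu[ord], best$sigma[ord],
                   best$loglik, n, n_iter = best$n_iter,
                   loglik_trace = best$trace)
}

# Evaluate an R expression with a temporary RNG state.
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

em_once <- function(x, K, init_mu, sd_init, tol, max_iter, min_sigma) {
  n <- length(x)
  pi_k <- rep(1 / K, K)
  mu <- init_mu
  sigma <- pmax(rep(sd_init, K), min_sigma)
  ll_old <- -Inf
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    # E step in log space for numerical stability
    logd <- vapply(seq_len(K),
                   function(k) log(pi_k[k]) + dnorm(x, mu[k], sigma[k], log = TRUE),
                   numeric(n))
    m <- apply(logd, 1L, max)
    lse <- m + log(rowSums(exp(logd - m)))
    ll <- sum(lse)
    trace <- c(trace, ll)
    resp <- exp(logd - lse)
    # M step
    nk <- colSums(resp)
    if (any(nk < 1)) return(NULL)  # empty component: degenerate restart
    pi_k <- nk / n
    mu <- colSums(resp * x) / nk
    sigma <- sqrt(colSums(resp * sweep(matrix(x, n, K), 2L, mu)^2) / nk)
    # variance floor: durations are quantized to whole epochs, so the
    # likelihood is unbounded at tied values; a component narrower than the
    # local quantization is a numerical spike, not a behavioral regime
    sigma <- pmax(sigma, min_sigma)
    if (is.finite(ll_old) && ll - ll_old < tol) break
    ll_old <- ll
  }
  list(pi = pi_k, mu = mu, sigma = sigma, loglik = ll, n_iter = it,
       trace = trace)
}

new_meal_mixture <- function(K, weight, mu, sigma, loglik, n, n_iter,
                             loglik_trace) {
  k_free <- 3L * K - 1L
  ic <- information_criteria(-2 * loglik, K = K, n = n)
  structure(
    list(K = K, weight = weight, mean = mu, sd = sigma,
         loglik = loglik, minus2LL = ic$minus2LL, AICc = ic$AICc,
         BIC = ic$BIC, n = n, k_free = k_free, n_iter = n_iter,
         loglik_trace = loglik_trace),
    class = "meal_mixture"
  )
}

#' Information criteria for a fitted mixture
#'
#' Small-sample corrected Akaike and Bayesian information criteria from a
#' -2 log-likelihood, using `k = 3K - 1` free parameters (K means, K SDs,
#' K - 1 weights):
#' `AICc = -2LL + 2k + 2k(k + 1)/(n - k - 1)`, `BIC = -2LL + k log(n)`.
#'
#' @param minus2LL Minus twice the maximized log-likelihood, or a
#'   `"meal_mixture"` object (in which case `K` and `n` are taken from it).
#' @param K Number of mixture components.
#' @param n Number of fitted observations.
#' @return A one-row tibble: `minus2LL`, `k_free`, `n`, `AICc`, `BIC`.
#' @examples
#' information_criteria(20729.3, K = 3, n = 6494)
#' @export
information_criteria <- function(minus2LL, K = NULL, n = NULL) {
  if (inherits(minus2LL, "meal_mixture")) {
    K <- minus2LL$K
    n <- minus2LL$n
    minus2LL <- minus2LL$minus2LL
  }
  k <- if (is.null(K)) 0L else 3L * K - 1L
  if (k > 0L && n <= k + 1L) {
    abort(paste0("AICc undefined: n = ", n, " <= k + 1 = ", k + 1L),
          class = "calanmeals_argument_error")
  }
  tibble::tibble(
    minus2LL = minus2LL,
    k_free = k,
    n = n %||% NA_integer_,
    AICc = minus2LL + 2 * k + if (k > 0L) 2 * k * (k + 1) / (n - k - 1) else 0,
    BIC = minus2LL + if (k > 0L) k * log(n) else 0
  )
}

#' Select the best-fitting mixture among candidates
#'
#' @param models List of `"meal_mixture"` objects fit to the same data.
#' @param rule Selection criterion: `"BIC"` (default), `"AICc"` or
#'   `"minus2LL"`; the model with the lowest value wins, first-listed on
#'   ties.
#' @return The selected `"meal_mixture"`, with attribute `comparison`, a
#'   tibble of all candidates' criteria.
#' @export
select_model <- function(models, rule = c("BIC", "AICc", "minus2LL")) {
  rule <- match.arg(rule)
  stopifnot(length(models) >= 2L)
  ns <- vapply(models, function(m) m$n, numeric(1))
  if (length(unique(ns)) != 1L) {
    abort("candidate models were fit to different n; criteria not comparable",
          class = "calanmeals_argument_error")
  }
  comparison <- purrr::map_dfr(models, function(m) {
    tibble::tibble(K = m$K, minus2LL = m$minus2LL, AICc = m$AICc, BIC = m$BIC)
  })
  crit <- vapply(models, function(m) m[[rule]], numeric(1))
  best <- models[[which.min(crit)]]
  attr(best, "comparison") <- comparison
  best
}

#' Intersection point of two Gaussian densities
#'
#' Solves `N(C; mu1, sigma1) = N(C; mu2, sigma2)` (unit-mass, unweighted
#' densities) for the root between the two means: equating log-densities
#' gives a quadratic in C whose interior root is the boundary at which an
#' interval stops looking like a within-meal pause and starts looking like
#' an intermeal gap. When the SDs are numerically equal the quadratic
#' degenerates and the limit `(mu1 + mu2)/2` is returned.
#'
#' @param mu1,sigma1 Mean and SD of the left component (log-seconds).
#' @param mu2,sigma2 Mean and SD of the right component; `mu1 < mu2`
#'   required.
#' @return The intersection point `C` on the same scale, `mu1 < C < mu2`.
#' @examples
#' intersection_point(6.34, 0.61, 8.77, 0.63)          # ~7.54 log-s
#' exp(intersection_point(6.34, 0.61, 8.77, 0.63)) / 60 # ~31.3 min
#' @export
intersection_point <- function(mu1, sigma1, mu2, sigma2) {
  if (!(mu1 < mu2)) {
    abort("mu1 must be strictly less than mu2",
          class = "calanmeals_argument_error")
  }
  stopifnot(sigma1 > 0, sigma2 > 0)
  if (abs(sigma1 - sigma2) < 1e-9) {
    return((mu1 + mu2) / 2)
  }
  # log N(C;mu1,s1) = log N(C;mu2,s2)  =>  a C^2 + b C + c = 0
  a <- 1 / sigma1^2 - 1 / sigma2^2
  b <- -2 * (mu1 / sigma1^2 - mu2 / sigma2^2)
  cc <- mu1^2 / sigma1^2 - mu2^2 / sigma2^2 + 2 * log(sigma1 / sigma2)
  disc <- b^2 - 4 * a * cc
  roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  inside <- roots[roots > mu1 & roots < mu2]
  if (length(inside) != 1L) {
    abort("no unique intersection between the means; check parameters",
          class = "calanmeals_fit_error")
  }
  inside
}

#' Derive the meal criterion from a fitted mixture
#'
#' The minimum intermeal interval (MII) is the intersection of the two
#' rightmost component densities of the selected mixture: gaps to its left
#' belong to the within-meal / drink-pause regime, gaps to its right
#' separate meals. Component weights are not used (the criterion is defined
#' on unit-mass densities); set `weighted = TRUE` for the
#' weighted-density variant.
#'
#' @param model A `"meal_mixture"` with `K >= 2`.
#' @param weighted Intersect weighted component densities instead
#'   (default `FALSE`).
#' @return An object of class `"meal_criterion"`: list with `C`
#'   (log-seconds), `mii_minutes = exp(C)/60`, `components` (indices of the
#'   two rightmost components), and the parameters used.
#' @examples
#' crit <- meal_criterion_from_params(6.34, 0.61, 8.77, 0.63)
#' crit$mii_minutes  # ~31.3
#' @export
meal_criterion <- function(model, weighted = FALSE) {
  if (model$K < 2L) {
    abort("meal criterion undefined for a single-component model",
          class = "calanmeals_argument_error")
  }
  i <- order(model$mean)[(model$K - 1L):model$K]
  mu <- model$mean[i]
  sg <- model$sd[i]
  if (!weighted) {
    C <- intersection_point(mu[1L], sg[1L], mu[2L], sg[2L])
  } else {
    w <- model$weight[i]
    # weighted equality: shift the constant term by 2 log(w1/w2)
    C <- weighted_intersection(mu[1L], sg[1L], w[1L], mu[2L], sg[2L], w[2L])
  }
  structure(
    list(C = C, mii_minutes = exp(C) / 60, components = i,
         mu = mu, sigma = sg, weighted = weighted),
    class = "meal_criterion"
  )
}

#' @rdname meal_criterion
#' @param mu1,sigma1,mu2,sigma2 Component parameters on the log-second
#'   scale, left component first.
#' @export
meal_criterion_from_params <- function(mu1, sigma1, mu2, sigma2) {
  C <- intersection_point(mu1, sigma1, mu2, sigma2)
  structure(
    list(C = C, mii_minutes = exp(C) / 60, components = c(1L, 2L),
         mu = c(mu1, mu2), sigma = c(sigma1, sigma2), weighted = FALSE),
    class = "meal_criterion"
  )
}

weighted_intersection <- function(mu1, sigma1, w1, mu2, sigma2, w2) {
  if (abs(sigma1 - sigma2) < 1e-9) {
    # linear case
    return((mu1 + mu2) / 2 +
             sigma1^2 * log(w1 / w2) / (mu2 - mu1))
  }
  a <- 1 / sigma1^2 - 1 / sigma2^2
  b <- -2 * (mu1 / sigma1^2 - mu2 / sigma2^2)
  cc <- mu1^2 / sigma1^2 - mu2^2 / sigma2^2 + 2 * log(sigma1 / sigma2) -
    2 * log(w1 / w2)
  disc <- b^2 - 4 * a * cc
  if (disc < 0) {
    abort("weighted densities do not intersect between the means",
          class = "calanmeals_fit_error")
  }
  roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  inside <- roots[roots > mu1 & roots < mu2]
  if (length(inside) < 1L) {
    abort("weighted intersection lies outside (mu1, mu2)",
          class = "calanmeals_fit_error")
  }
  inside[1L]
}

#' @export
print.meal_mixture <- function(x, ...) {
  cat(sprintf("Gaussian mixture, K = %d (n = %d, log-seconds)\n", x$K, x$n))
  print(tidy(x))
  cat(sprintf("-2LL = %.1f  AICc = %.1f  BIC = %.1f\n",
              x$minus2LL, x$AICc, x$BIC))
  invisible(x)
}

#' @export
print.meal_criterion <- function(x, ...) {
  cat(sprintf(
    "Meal criterion: C = %.3f log-s  =>  minimum intermeal interval %.1f min\n",
    x$C, x$mii_minutes))
  invisible(x)
}

#' Tidy a fitted mixture: one row per component
#' @param x A `"meal_mixture"`.
#' @param ... Unused.
#' @return Tibble with `component`, `weight`, `mean`, `sd`.
#' @method tidy meal_mixture
#' @export
tidy.meal_mixture <- function(x, ...) {
  tibble::tibble(component = seq_len(x$K), weight = x$weight,
                 mean = x$mean, sd = x$sd)
}

#' One-row model summary of a fitted mixture
#' @param x A `"meal_mixture"`.
#' @param ... Unused.
#' @return Tibble with `K`, `n`, `logLik`, `minus2LL`, `AICc`, `BIC`,
#'   `n_iter`.
#' @method glance meal_mixture
#' @export
glance.meal_mixture <- function(x, ...) {
  tibble::tibble(K = x$K, n = x$n, logLik = x$loglik, minus2LL = x$minus2LL,
                 AICc = x$AICc, BIC = x$BIC, n_iter = x$n_iter)
}

#' Mixture density at given points
#' @noRd
mixture_density <- function(model, x) {
  rowSums(vapply(seq_len(model$K), function(k) {
    model$weight[k] * dnorm(x, model$mean[k], model$sd[k])
  }, numeric(length(x))))
}

#' Plot a fitted mixture over the interval histogram
#'
#' @param object A `"meal_mixture"`.
#' @param data Optional log-interval values (vector or tibble from
#'   [prepare_intervals()]) to histogram under the density.
#' @param criterion Optional `"meal_criterion"` to mark as a vertical line.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot meal_mixture
#' @export
autoplot.meal_mixture <- function(object, data = NULL, criterion = NULL, ...) {
  lim <- range(object$mean) + c(-4, 4) * max(object$sd)
  grid <- tibble::tibble(x = seq(lim[1L], lim[2L], length.out = 400))
  grid$density <- mixture_density(object, grid$x)
  comp <- tidy(object) |>
    dplyr::mutate(curves = purrr::pmap(
      list(.data$component, .data$weight, .data$mean, .data$sd),
      function(component, weight, mean, sd) {
        tibble::tibble(component = factor(component), x = grid$x,
                       density = weight * dnorm(grid$x, mean, sd))
      })) |>
    dplyr::pull(.data$curves) |>
    dplyr::bind_rows()
  p <- ggplot2::ggplot()
  if (!is.null(data)) {
    vals <- if (is.data.frame(data)) data$log_s else as.numeric(data)
    p <- p + ggplot2::geom_histogram(
      data = tibble::tibble(log_s = vals),
      ggplot2::aes(x = .data$log_s, y = ggplot2::after_stat(.data$density)),
      binwidth = 0.25, fill = "grey80", color = "grey60"
    )
  }
  p <- p +
    ggplot2::geom_line(data = comp,
                       ggplot2::aes(x = .data$x, y = .data$density,
                                    color = .data$component),
                       linetype = "dashed") +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(x = .data$x, y = .data$density),
                       linewidth = 0.8)
  if (!is.null(criterion)) {
    p <- p + ggplot2::geom_vline(xintercept = criterion$C, linetype = "dotted")
  }
  p + ggplot2::labs(x = "log(interval, s)", y = "density",
                    color = "component") +
    ggplot2::theme_minimal()
}
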