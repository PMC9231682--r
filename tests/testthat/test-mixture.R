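test_that("interval preparation filters short gaps and log-transforms", {
  out <- prepare_intervals(c(60, 90, rep(600, 60)), min_interval_s = 120)
  expect_equal(attr(out, "n_excluded_short"), 2L)
  expect_equal(out$log_s[1], log(600), tolerance = 1e-12)
  expect_equal(attr(out, "n"), 60L)

  expect_error(prepare_intervals(c(60, 90, 600)),
               class = "calanmeals_insufficient_data")
})

test_that("short-gap exclusion matches the planted mixture mass", {
  cfg <- sim_config(seed = 77)
  set.seed(77)
  comp <- sample.int(3, 20000, replace = TRUE, prob = cfg$gap_weight)
  gaps <- rlnorm(20000, cfg$gap_meanlog[comp], cfg$gap_sdlog[comp])
  out <- prepare_intervals(gaps)
  frac <- attr(out, "n_excluded_short") / length(gaps)
  planted <- sum(cfg$gap_weight *
                   pnorm((log(120) - cfg$gap_meanlog) / cfg$gap_sdlog))
  expect_equal(frac, planted, tolerance = 0.02)
})

test_that("single-component fit reduces to closed-form MLE", {
  set.seed(5)
  x <- rnorm(500, 3, 2)
  fit <- fit_mixture(x, K = 1)
  expect_equal(fit$mean, mean(x), tolerance = 1e-12)
  expect_equal(fit$sd, sqrt(mean((x - mean(x))^2)), tolerance = 1e-12)
})

test_that("EM recovers well-separated two-component parameters", {
  set.seed(9)
  n <- 6494
  z <- runif(n) < 0.5
  x <- ifelse(z, rnorm(n, 6.34, 0.61), rnorm(n, 8.77, 0.63))
  fit <- fit_mixture(x, K = 2, n_restarts = 3, seed = 1)
  expect_lt(max(abs(fit$mean - c(6.34, 8.77))), 0.10)
  expect_lt(max(abs(fit$sd - c(0.61, 0.63))), 0.05)
  expect_lt(max(abs(fit$weight - 0.5)), 0.05)
  # EM log-likelihood is non-decreasing every iteration
  expect_true(all(diff(fit$loglik_trace) >= -1e-8))
})

test_that("two equal spikes split weight evenly", {
  x <- c(rnorm(300, 0, 0.01), rnorm(300, 10, 0.01))
  fit <- fit_mixture(x, K = 2, n_restarts = 2, seed = 2)
  expect_equal(fit$weight, c(0.5, 0.5), tolerance = 1e-6)
})

test_that("EM agrees with an independent mixture fitter", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  set.seed(21)
  x <- c(rnorm(800, 6.3, 0.6), rnorm(500, 8.8, 0.65))
  fit <- fit_mixture(x, K = 2, seed = 4)
  ref <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(fit$loglik, ref$loglik, tolerance = 1e-4)
  expect_equal(sort(fit$mean), sort(as.numeric(ref$parameters$mean)),
               tolerance = 1e-3)
})

test_that("information criteria follow the small-sample formulas", {
  ic3 <- information_criteria(20729.3, K = 3, n = 6494)
  expect_equal(ic3$AICc, 20745.3, tolerance = 0.1)
  expect_equal(ic3$BIC, 20799.5, tolerance = 0.1)
  ic2 <- information_criteria(21160.5, K = 2, n = 6494)
  expect_equal(ic2$AICc, 21170.5, tolerance = 0.1)
  expect_equal(ic2$BIC, 21204.4, tolerance = 0.1)
  # zero free parameters: both criteria equal -2LL
  ic0 <- information_criteria(123.4, K = NULL, n = 50)
  expect_equal(ic0$AICc, 123.4)
  expect_equal(ic0$BIC, 123.4)
  expect_error(information_criteria(10, K = 3, n = 9),
               class = "calanmeals_argument_error")
})

test_that("model selection picks the lowest criterion and checks n", {
  set.seed(33)
  x <- c(rnorm(600, 5, 0.5), rnorm(600, 8, 0.5))
  fits <- lapply(2:3, function(K) fit_mixture(x, K = K, seed = 1))
  best <- select_model(fits, rule = "BIC")
  expect_equal(best$K, 2L)  # true structure is 2 components
  expect_equal(nrow(attr(best, "comparison")), 2L)

  fits[[2]]$n <- fits[[2]]$n - 1L
  expect_error(select_model(fits), class = "calanmeals_argument_error")
})

test_that("three-component structure is selected on simulated intervals", {
  cfg <- sim_config(seed = 1)
  wins <- vapply(1:20, function(r) {
    set.seed(1000 + r)
    n <- 3000
    comp <- sample.int(3, n, replace = TRUE, prob = c(0.35, 0.35, 0.30))
    x <- rnorm(n, cfg$gap_meanlog[comp], cfg$gap_sdlog[comp])
    fits <- lapply(2:3, function(K) fit_mixture(x, K = K, n_restarts = 5,
                                                seed = r))
    select_model(fits, rule = "BIC")$K == 3L
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("density intersection matches a bisection oracle", {
  # equal sigmas: exact midpoint
  expect_equal(intersection_point(0, 0.7, 2, 0.7), 1.0)
  expect_error(intersection_point(5, 1, 4, 1),
               class = "calanmeals_argument_error")

  set.seed(55)
  for (i in 1:200) {
    p <- draw_crossing_params()
    C <- intersection_point(p["mu1"], p["s1"], p["mu2"], p["s2"])
    expect_gt(C, p[["mu1"]])
    expect_lt(C, p[["mu2"]])
    expect_equal(C, bisect_intersection(p["mu1"], p["s1"], p["mu2"], p["s2"]),
                 tolerance = 1e-8, ignore_attr = TRUE)
    # densities actually cross there
    expect_lt(abs(dnorm(C, p["mu1"], p["s1"]) - dnorm(C, p["mu2"], p["s2"])),
              1e-8)
  }
})

test_that("meal criterion uses the two rightmost components", {
  fit <- structure(
    list(K = 3L, weight = c(0.3, 0.4, 0.3),
         mean = c(4.0, 6.34, 8.77), sd = c(0.6, 0.61, 0.63),
         n = 6494L),
    class = "meal_mixture"
  )
  crit <- meal_criterion(fit)
  expect_equal(crit$components, c(2L, 3L))
  expect_equal(crit$mii_minutes, exp(crit$C) / 60)

  # invariant to component permutation
  perm <- fit
  ord <- c(3L, 1L, 2L)
  perm$mean <- fit$mean[ord]; perm$sd <- fit$sd[ord]
  perm$weight <- fit$weight[ord]
  expect_equal(meal_criterion(perm)$mii_minutes, crit$mii_minutes)

  one <- structure(list(K = 1L, mean = 5, sd = 1), class = "meal_mixture")
  expect_error(meal_criterion(one), class = "calanmeals_argument_error")

  # symmetric toy case forced to the midpoint
  toy <- structure(list(K = 2L, weight = c(0.5, 0.5), mean = c(0, 2),
                        sd = c(0.4, 0.4)), class = "meal_mixture")
  expect_equal(meal_criterion(toy)$mii_minutes, exp(1) / 60)
})
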