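test_that("observer records align to the nearest sensor sample", {
  st <- make_states(rep(1L, 20))
  log <- tibble::tibble(timestamp = st$timestamp[10], label = "open")
  pairs <- align_to_sensor(log, st)
  expect_equal(pairs$sensor, 1L)
  expect_equal(pairs$observer, 1L)

  # a single glitch inside the window is suppressed by the mode
  x <- rep(1L, 20); x[10] <- 0L
  stg <- make_states(x)
  pairs2 <- align_to_sensor(tibble::tibble(timestamp = stg$timestamp[10],
                                           label = "open"), stg)
  expect_equal(pairs2$sensor, 1L)

  # out-of-span records are dropped with a warning
  log3 <- tibble::tibble(timestamp = c(st$timestamp[1] - 3600,
                                       st$timestamp[5]),
                         label = c("closed", "open"))
  expect_warning(pairs3 <- align_to_sensor(log3, st), "dropped")
  expect_equal(nrow(pairs3), 1L)
  expect_equal(attr(pairs3, "n_dropped"), 1L)
})

test_that("contingency counts match a hand tally", {
  pairs <- tibble::tibble(sensor = c(1L, 1L, 1L, 0L, 0L, 1L),
                          observer = c(1L, 1L, 0L, 0L, 1L, 1L))
  tab <- contingency(pairs)
  expect_equal(tab$n11, 3L)
  expect_equal(tab$n10, 1L)
  expect_equal(tab$n01, 1L)
  expect_equal(tab$n00, 1L)

  all_open <- contingency(tibble::tibble(sensor = rep(1L, 10),
                                         observer = rep(1L, 10)))
  expect_equal(all_open$n11, 10L)
  expect_equal(all_open$n10 + all_open$n01 + all_open$n00, 0L)

  set.seed(12)
  s <- sample(0:1, 500, TRUE); o <- sample(0:1, 500, TRUE)
  tab2 <- contingency(tibble::tibble(sensor = s, observer = o))
  expect_equal(tab2$n11, sum(s & o))
  expect_equal(tab2$n00, sum(!s & !o))
})

test_that("kappa follows the definitional formula with its asymptotic CI", {
  perfect <- tibble::tibble(n11 = 50, n10 = 0, n01 = 0, n00 = 50)
  expect_equal(cohens_kappa(perfect)$kappa, 1)

  chance <- tibble::tibble(n11 = 25, n10 = 25, n01 = 25, n00 = 25)
  expect_equal(cohens_kappa(chance)$kappa, 0)

  tab <- tibble::tibble(n11 = 40, n10 = 5, n01 = 10, n00 = 45)
  got <- cohens_kappa(tab)
  # independent hand computation from the definition
  n <- 100
  po <- (40 + 45) / n
  pe <- (45 / n) * (50 / n) + (55 / n) * (50 / n)
  expect_equal(got$kappa, (po - pe) / (1 - pe), tolerance = 1e-12)
  se <- sqrt(po * (1 - po) / (n * (1 - pe)^2))
  expect_equal(got$ci_lo, got$kappa - qnorm(0.975) * se, tolerance = 1e-12)
  expect_true(got$ci_lo <= got$kappa && got$kappa <= got$ci_hi)

  # symmetric relabeling (swap open/closed for both raters) leaves kappa
  swapped <- tibble::tibble(n11 = tab$n00, n10 = tab$n01,
                            n01 = tab$n10, n00 = tab$n11)
  expect_equal(cohens_kappa(swapped)$kappa, got$kappa)

  degenerate <- tibble::tibble(n11 = 10, n10 = 0, n01 = 0, n00 = 0)
  expect_error(cohens_kappa(degenerate), class = "calanmeals_argument_error")
})

test_that("predictive values follow their definitions", {
  tab <- tibble::tibble(n11 = 98, n10 = 2, n01 = 3, n00 = 97)
  pv <- predictive_values(tab)
  expect_equal(pv$ppv, 0.98)
  expect_equal(pv$npv, 0.97)

  perfect <- tibble::tibble(n11 = 10, n10 = 0, n01 = 0, n00 = 10)
  expect_equal(unlist(predictive_values(perfect)), c(ppv = 1, npv = 1))

  set.seed(14)
  for (i in 1:20) {
    cts <- as.list(rmultinom(1, 200, c(0.4, 0.1, 0.1, 0.4)) + 1)
    names(cts) <- c("n11", "n10", "n01", "n00")
    tab <- tibble::as_tibble(cts)
    pv <- predictive_values(tab)
    expect_equal(pv$ppv, tab$n11 / (tab$n11 + tab$n10))
    expect_equal(pv$npv, tab$n00 / (tab$n00 + tab$n01))
  }
})

test_that("noise-free synthetic validation gives perfect agreement", {
  # validation missions log at 1 Hz, so the +/-5-sample mode window spans
  # seconds and never overrides a genuine bout
  cfg <- sim_config(n_cows = 1, n_days = 1, epoch_s = 1,
                    angle_noise_sd_deg = 0, sag_prob = 0,
                    observer_flip_rate = 0, seed = 99)
  b <- simulate_feeding_study(cfg)
  states <- classify_state(b$tilt[, c("cow_id", "timestamp", "tilt_deg")])
  v <- validate_agreement(b$observer, states)
  expect_equal(v$kappa$kappa, 1)
  expect_equal(v$predictive$ppv, 1)
  expect_equal(v$predictive$npv, 1)
  expect_equal(v$table$n10 + v$table$n01, 0L)
})

test_that("observer label flips lower kappa by about the expected amount", {
  cfg <- sim_config(n_cows = 1, n_days = 1, epoch_s = 1,
                    angle_noise_sd_deg = 0, sag_prob = 0,
                    observer_flip_rate = 0.05, seed = 100)
  ev <- simulate_visits(cfg)
  obs <- simulate_observer(ev, cfg, window_start = min(ev$start),
                           window_end = min(ev$start) + 86400 - 1)
  states <- classify_state(
    simulate_tilt(ev, cfg)[, c("cow_id", "timestamp", "tilt_deg")])
  v <- validate_agreement(obs, states)
  expect_lt(v$kappa$kappa, 1)
  # with flip rate f, observed agreement is at least 1 - f in expectation;
  # allow sampling slack on ~1000 pairs
  expect_gt(v$kappa$observed_agreement, 1 - 0.05 - 0.03)
  expect_gt(v$kappa$kappa, 0.7)
})
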