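test_that("logger CSV parsing reads samples in order and validates columns", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Date Time,X accel,Y accel,Z accel",
               "2021-06-01 05:01:00,0.0,0.1,0.5",
               "2021-06-01 05:00:00,0.0,0.1,-1.0",
               "2021-06-01 05:00:30,0.0,0.1,0.0"), f)
  s <- read_logger_csv(f, cow_id = "c7")
  expect_equal(nrow(s), 3L)
  expect_equal(s$az, c(-1, 0, 0.5))  # sorted by time
  expect_true(!is.unsorted(s$timestamp))
  expect_identical(attr(s, "units"), "g")

  # missing mapped column is a format error naming the column
  expect_error(
    read_logger_csv(f, column_map = list(timestamp = "Date Time",
                                         tilt_deg = "Z tilt")),
    "Z tilt", class = "calanmeals_format_error"
  )

  # duplicate timestamps are rejected
  writeLines(c("Date Time,X accel,Y accel,Z accel",
               "2021-06-01 05:00:00,0,0,0",
               "2021-06-01 05:00:00,0,0,1"), f)
  expect_error(read_logger_csv(f), class = "calanmeals_data_error")
})

test_that("tilt CSV write-then-read round-trips a simulated series", {
  cfg <- sim_config(n_cows = 1, n_days = 1, seed = 42)
  tilt <- simulate_tilt(simulate_visits(cfg), cfg)[seq_len(1000), ]
  tilt <- tilt[, c("cow_id", "timestamp", "tilt_deg")]
  f <- withr::local_tempfile(fileext = ".csv")
  write_tilt_csv(tilt, f)
  back <- read_tilt_csv(f)
  expect_equal(back$timestamp, tilt$timestamp)
  expect_equal(back$tilt_deg, tilt$tilt_deg, tolerance = 1e-12)
  expect_equal(back$cow_id, tilt$cow_id)
})

test_that("tilt formula maps acceleration endpoints and interior values", {
  acc <- make_tilt(0)[, c("cow_id", "timestamp")]
  acc <- tibble::tibble(cow_id = "c1",
                        timestamp = t_origin + c(0, 30, 60, 90),
                        ax = 0, ay = 0,
                        az = c(-1, 0, 1, cos(120 * pi / 180)))
  tilt <- compute_tilt(acc, axis = "Z")
  expect_equal(tilt$tilt_deg, c(0, 90, 180, 60), tolerance = 1e-10)
})

test_that("tilt is monotone in acceleration and clipping is counted", {
  a <- sort(runif(200, -1, 1))
  acc <- tibble::tibble(cow_id = "c1",
                        timestamp = t_origin + 30 * (seq_along(a) - 1L),
                        ax = 0, ay = 0, az = a)
  tilt <- compute_tilt(acc)
  expect_true(all(diff(tilt$tilt_deg) >= 0))
  expect_true(all(tilt$tilt_deg >= 0 & tilt$tilt_deg <= 180))

  acc$az[1] <- -1.03  # within tolerance: clipped, counted
  t2 <- compute_tilt(acc)
  expect_equal(attr(t2, "n_clipped"), 1L)
  expect_equal(t2$tilt_deg[1], 0)

  acc$az[1] <- -1.2  # beyond tolerance: mis-scaled units
  expect_error(compute_tilt(acc), class = "calanmeals_data_error")
})

test_that("day segmentation partitions samples and flags partial days", {
  # 48 h starting exactly at the boundary -> 2 full days
  tilt <- make_tilt(rep(0, 48 * 120), epoch_s = 30)
  seg <- segment_days(tilt)
  expect_equal(sort(unique(seg$day)), c(1L, 2L))
  expect_false(any(seg$partial))

  # 36 h starting at 17:00 with a midnight boundary -> 1 full day flanked
  # by 2 partials (7 h + 24 h + 5 h)
  tilt2 <- make_tilt(rep(0, 36 * 120), epoch_s = 30,
                     start = as.POSIXct("2021-06-01 17:00:00", tz = "UTC"))
  seg2 <- segment_days(tilt2, boundary = "00:00")
  dt <- attr(seg2, "day_table")
  expect_equal(nrow(dt), 3L)
  expect_equal(dt$partial, c(TRUE, FALSE, TRUE))

  # conservation on a simulated 7-d record: every sample in exactly one day
  cfg <- sim_config(n_cows = 1, n_days = 7, seed = 5)
  tilt7 <- simulate_tilt(simulate_visits(cfg), cfg)
  seg7 <- segment_days(tilt7)
  expect_equal(nrow(seg7), nrow(tilt7))
  expect_equal(sum(attr(seg7, "day_table")$n_samples), nrow(tilt7))
  expect_equal(length(unique(seg7$day)), 7L)

  # empty series: empty result, not an error
  expect_equal(nrow(segment_days(make_tilt(numeric(0)))), 0L)
})

test_that("sag report counts sub-threshold nonzero tilt", {
  expect_equal(sag_report(make_tilt(rep(0, 10)))$sag_fraction, 0)

  tilt <- make_tilt(c(rep(15, 5), rep(0, 55), rep(70, 40)))
  r <- sag_report(tilt, open_threshold = 30)
  expect_equal(r$n_sag, 5L)
  expect_equal(r$sag_fraction, 0.05)
})

test_that("sag report matches the fraction planted by the simulator", {
  cfg <- sim_config(n_cows = 6, n_days = 4, seed = 31)
  ev <- simulate_visits(cfg)
  tilt <- simulate_tilt(ev, cfg)
  planted <- mean(!is.na(tilt$sag_deg) & tilt$sag_deg > 0 &
                    tilt$sag_deg < 30)
  measured <- sag_report(tilt, 30)$sag_fraction
  expect_equal(measured, planted, tolerance = 0.01)
  # slack resets keep the drift capped below the threshold
  expect_true(all(tilt$sag_deg < 30, na.rm = TRUE))
})
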