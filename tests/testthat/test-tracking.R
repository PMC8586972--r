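test_that("track initialization follows the stated window rule", {
  frame <- array(0.5, c(200, 200, 3))
  st <- init_track(frame, c(100, 100, 50, 40), margin = 2)
  expect_equal(unname(st$center), c(125, 120))
  expect_equal(st$w0, 100)
  expect_error(init_track(frame, c(10, 10, 0, 5)), "positive")
  expect_error(init_track(frame, c(190, 190, 20, 20)), "inside")
})

test_that("the scale ladder spans x1.0 to x0.5 in 11 uniform steps", {
  s <- scale_ladder()
  expect_length(s, 11)
  expect_equal(s[1], 1.0)
  expect_equal(s[11], 0.5)
  expect_equal(unique(round(diff(s), 10)), -0.05)
})

test_that("windows at a frame corner are clamped, never out of bounds", {
  frame <- array(0.5, c(200, 200, 3))
  st <- init_track(frame, c(0, 0, 30, 30), margin = 2)  # corner box
  seg <- const_segmenter(matrix(1, 32, 32))
  m <- multiscale_measure(seg, frame, st)
  expect_true(all(is.finite(unlist(m$record[cropseg:::.area_cols()]))))
  expect_false(m$record$empty)
})

test_that("oracle measurement of a 50 px disk matches the analytic area", {
  spec <- growth_spec(canvas_side = 256, a_inf = pi * 50^2, rate = 1,
                      t0 = -20, nu = 1, days = 1, times = "12:00",
                      night_times = character(0), drift_sd = 0,
                      n_harmonics = 0, n_distractors = 0, seed = 5)
  series <- generate_growth_series(spec)
  expect_equal(series$truth$r[1], 50, tolerance = 1e-6)
  seg <- make_oracle_segmenter(series, input_side = 64)
  st <- init_track(series$frames[[1]],
                   c(series$truth$cx[1] - 60, series$truth$cy[1] - 60,
                     120, 120), margin = 1.2)
  m <- multiscale_measure(seg, series$frames[[1]], st)
  expect_lt(abs(m$record$median_area_px - pi * 50^2) / (pi * 50^2), 0.02)
  # the median is always one of the 11 measurements
  areas <- unlist(m$record[cropseg:::.area_cols()])
  expect_true(m$record$median_area_px %in% areas)
})

test_that("the median survives corruption of up to 5 of the 11 areas", {
  set.seed(8)
  clean <- runif(11, 90, 110)
  for (rep in 1:50) {
    k <- sample(0:5, 1)
    corrupt <- clean
    idx <- sample(11, k)
    corrupt[idx] <- runif(k, 0, 1e4)
    med <- sort(corrupt)[6]
    remaining <- clean[setdiff(1:11, idx)]
    expect_gte(med, min(remaining))
    expect_lte(med, max(remaining))
  }
})

test_that("a single-pixel mask maps its centre of mass to frame coords", {
  frame <- array(0.5, c(32, 32, 3))
  st <- init_track(frame, c(2, 2, 28, 28), margin = 3)  # W0 = 84, clamps to 32
  mask <- matrix(0, 32, 32); mask[10, 20] <- 1
  m <- multiscale_measure(const_segmenter(mask), frame, st)
  # all 11 windows clamp to the full 32 px frame, so window == frame
  expect_equal(m$record$center_x, 19.5)
  expect_equal(m$record$center_y, 9.5)
  expect_equal(m$record$chosen_scale, 1.0)
  expect_equal(m$record$median_area_px, 1)
})

test_that("identical frames give identical areas and zero CV", {
  frame <- array(0.5, c(32, 32, 3))
  st <- init_track(frame, c(2, 2, 28, 28), margin = 3)
  mask <- matrix(0, 32, 32); mask[10:20, 10:20] <- 1
  seg <- const_segmenter(mask)
  gs <- track_series(seg, list(frame, frame, frame), st)
  areas <- as.matrix(gs$records[cropseg:::.area_cols()])
  expect_equal(length(unique(as.numeric(areas))), 1)
  expect_equal(gs$records$cv, rep(0, 3))
})

test_that("tracking follows a drifting object within 3 px", {
  spec <- growth_spec(canvas_side = 128, a_inf = 1200, rate = 0.5, t0 = -2,
                      nu = 1, days = 4, drift_sd = 1.5, seed = 21)
  series <- generate_growth_series(spec)
  seg <- make_oracle_segmenter(series, input_side = 64)
  tr <- series$truth
  st <- init_track(series$frames[[1]],
                   c(tr$cx[1] - 1.2 * tr$r[1], tr$cy[1] - 1.2 * tr$r[1],
                     2.4 * tr$r[1], 2.4 * tr$r[1]))
  gs <- track_series(seg, series, st)
  expect_equal(nrow(gs$records), 32)   # count conservation: 4 days x 8
  err <- sqrt((gs$records$center_x - tr$cx)^2 +
                (gs$records$center_y - tr$cy)^2)
  expect_lt(max(err), 3)
})

test_that("daytime filtering keeps exactly the whitelisted times", {
  times <- generate_growth_series(
    growth_spec(canvas_side = 16, a_inf = 20, days = 63, n_distractors = 0,
                noise_sd = 0, seed = 2))$times
  gs <- fake_series(rep(100, length(times)), timestamps = times)
  expect_equal(nrow(gs$records), 504)
  day <- filter_daytime(gs)
  expect_equal(nrow(day$records), 315)   # 5 per day for 63 days
  expect_setequal(unique(format(day$records$timestamp, "%H:%M")),
                  c("08:00", "09:49", "11:49", "13:49", "15:49"))
  expect_equal(nrow(filter_daytime(gs, character(0))$records), 0)
  all_t <- unique(format(gs$records$timestamp, "%H:%M"))
  expect_equal(filter_daytime(gs, all_t)$records, gs$records)
})

test_that("the outlier count is the largest integer strictly below f*N", {
  oracle <- function(n, f) {     # brute force over integers
    k <- 0L
    while ((k + 1) < f * n - 1e-12) k <- k + 1L
    k
  }
  for (n in c(1:50, seq(60, 1000, by = 37), 315)) {
    expect_equal(cropseg:::.outlier_count(n, 0.05), oracle(n, 0.05),
                 info = paste("n =", n))
  }
  expect_equal(cropseg:::.outlier_count(315, 0.05), 15L)
  expect_equal(cropseg:::.outlier_count(20, 0.05), 0L)
})

test_that("flagged medians are replaced from the previous clean record", {
  gs <- fake_series(c(10, 10, 100, 10), cvs = c(0.01, 0.01, 0.9, 0.01))
  out <- flag_and_replace_outliers(gs, fraction = 0.3)  # K = 1
  expect_equal(out$records$outlier_flag, c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(out$records$median_area_px, c(10, 10, 10, 10))
  expect_equal(out$records$replaced_from[3], 2)
  # consecutive flags chain back to the nearest clean record
  gs2 <- fake_series(c(10, 80, 90, 11), cvs = c(0.01, 0.8, 0.9, 0.01))
  out2 <- flag_and_replace_outliers(gs2, fraction = 0.6)  # K = 2
  expect_equal(out2$records$median_area_px, c(10, 10, 10, 11))
  # a flagged first record is left alone with a warning
  gs3 <- fake_series(c(99, 10, 10), cvs = c(0.9, 0.01, 0.01))
  expect_warning(out3 <- flag_and_replace_outliers(gs3, fraction = 0.5),
                 "no earlier")
  expect_equal(out3$records$median_area_px[1], 99)
  # manual overrides flag by frame id
  out4 <- flag_and_replace_outliers(gs, fraction = 1e-6, manual_ids = 3)
  expect_true(out4$records$outlier_flag[3])
  expect_equal(out4$records$median_area_px[3], 10)
  # undefined CVs count as largest
  gs5 <- fake_series(c(10, 50, 10, 10), cvs = c(0.01, NA, 0.01, 0.01))
  out5 <- flag_and_replace_outliers(gs5, fraction = 0.3)
  expect_true(out5$records$outlier_flag[2])
})

test_that("polynomial fitting recovers nested and exact models", {
  t_h <- 0:40
  ts <- as.POSIXct("2020-08-13", tz = "UTC") + 3600 * t_h
  # noiseless degree-5 data: coefficients recovered
  beta <- c(3, 0.5, -0.02, 1e-3, -2e-5, 1e-7)
  y <- drop(outer(t_h, 0:5, `^`) %*% beta)
  fit <- fit_growth_curve(fake_series(y, timestamps = ts), degree = 5)
  expect_equal(fit$coefficients, beta, tolerance = 1e-6)
  # degree-2 data is inside the degree-5 class: residuals ~ 0
  y2 <- 5 + 2 * t_h + 0.3 * t_h^2
  fit2 <- fit_growth_curve(fake_series(y2, timestamps = ts))
  expect_lt(max(abs(fit2$fitted - y2)), 1e-6)
  # constant medians give a constant curve
  fitc <- fit_growth_curve(fake_series(rep(42, 41), timestamps = ts))
  expect_equal(fitc$fitted, rep(42, 41), tolerance = 1e-8)
  expect_error(fit_growth_curve(fake_series(1:4)), "at least")
})
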