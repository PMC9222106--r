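# Up/down segmentation and slow-wave metrics.

test_that("pure 1 Hz sine segments at ~0.5 duty, one state per cycle", {
  fs <- 500
  t <- seq(0, 120 - 1 / fs, by = 1 / fs)
  ts <- time_series(sin(2 * pi * 1 * t), fs)
  seg <- detect_updown(ts)
  expect_equal(duty_cycle(seg$us, 0, 120), 0.5, tolerance = 0.05)
  expect_equal(nrow(seg$us), 120, tolerance = 0.03)
})

test_that("min-duration constraints hold on white noise", {
  set.seed(51)
  ts <- time_series(rnorm(120 * 250), 250)
  p <- updown_params(min_us = 0.3)
  seg <- detect_updown(ts, p)
  if (nrow(seg$us)) expect_gte(min(seg$us$end - seg$us$start), 0.3)
})

test_that("flat signal raises a no-states error; segmentation is idempotent", {
  expect_error(detect_updown(time_series(rep(1, 70 * 100), 100)), "flat signal")
  sim <- shared_mosaic_sim()
  ctl <- sim$recording$channels$lfp_control
  s1 <- detect_updown(ctl)
  s2 <- detect_updown(ctl)
  expect_identical(s1$us, s2$us)
  expect_identical(s1$polarity, s2$polarity)
})

test_that("segmentation recovers ground truth (IoU, duty, mean duration)", {
  sim <- shared_mosaic_sim()
  ctl <- sim$recording$channels$lfp_control
  seg <- detect_updown(ctl)
  expect_gte(iv_iou(seg$us, sim$truth$us), 0.85)
  dur_det <- mean(seg$us$end - seg$us$start)
  expect_equal(dur_det, 0.5, tolerance = 0.1)
  # polarity auto-detection picks positive-up (the generated convention)
  expect_equal(seg$polarity, "positive_up")
  # a sign-flipped trace segments to the same up states
  flip <- ctl; flip$samples <- -flip$samples
  segf <- detect_updown(flip)
  expect_equal(segf$polarity, "negative_up")
  expect_gte(iv_iou(segf$us, seg$us), 0.95)
})

test_that("us_slopes: analytic sine slope and linearity", {
  fs <- 1000
  f0 <- 1; A <- 0.8
  t <- seq(0, 120 - 1 / fs, by = 1 / fs)
  ts <- time_series(A * sin(2 * pi * f0 * t), fs)
  seg <- detect_updown(ts)
  sl <- us_slopes(ts, seg)
  # delta-filtered 1 Hz sine: max |derivative| = 2*pi*f*A
  expect_equal(unname(sl$summary["slope1_max"]), 2 * pi * f0 * A,
               tolerance = 0.03)
  expect_equal(unname(sl$summary["slope2_max"]), 2 * pi * f0 * A,
               tolerance = 0.03)
  # doubling the amplitude doubles every slope
  ts2 <- time_series(2 * A * sin(2 * pi * f0 * t), fs)
  sl2 <- us_slopes(ts2, detect_updown(ts2))
  expect_equal(unname(sl2$summary / sl$summary), rep(2, 4), tolerance = 0.02)
})

test_that("slopes are invariant to time reversal up to segment swap", {
  sim <- shared_mosaic_sim()
  ctl <- sim$recording$channels$lfp_control
  seg <- detect_updown(ctl)
  sl <- us_slopes(ctl, seg)
  rev_ts <- ctl; rev_ts$samples <- rev(ctl$samples)
  seg_r <- detect_updown(rev_ts)
  sl_r <- us_slopes(rev_ts, seg_r)
  # time reversal maps DS->US transitions onto US->DS ones
  expect_equal(unname(sl_r$summary["slope2_max"]),
               unname(sl$summary["slope1_max"]), tolerance = 0.1)
  expect_equal(unname(sl_r$summary["slope1_max"]),
               unname(sl$summary["slope2_max"]), tolerance = 0.1)
})

test_that("swa_metrics: identical channels, DC invariance, pairing", {
  sim <- shared_mosaic_sim()
  ctl <- sim$recording$channels$lfp_control
  rec_same <- recording(list(a = ctl, b = ctl), animal_id = "same",
                        hemisphere_map = c(a = "injected",
                                           b = "control_hemisphere"))
  tab <- swa_metrics(rec_same)
  expect_equal(tab$value_injected, tab$value_control, tolerance = 1e-9)
  # adding a DC offset leaves every metric unchanged
  shifted <- ctl; shifted$samples <- ctl$samples + 5
  rec_dc <- recording(list(a = shifted, b = ctl), animal_id = "dc",
                      hemisphere_map = c(a = "injected",
                                         b = "control_hemisphere"))
  tab_dc <- swa_metrics(rec_dc)
  expect_equal(tab_dc$value_injected, tab_dc$value_control, tolerance = 1e-6)
})

test_that("swa_metrics warns and degrades to unpaired with one hemisphere", {
  sim <- shared_mosaic_sim()
  ctl <- sim$recording$channels$lfp_control
  rec <- recording(list(a = ctl), animal_id = "half", group = "mosaic_pup",
                   hemisphere_map = c(a = "injected"))
  expect_warning(tab <- swa_metrics(rec), "missing hemisphere")
  expect_true(is.null(tab$value_injected))
  expect_true(all(is.finite(tab$value)))
})

test_that("mosaic injected hemisphere shows the SWA phenotype", {
  sim <- shared_mosaic_sim()
  tab <- swa_metrics(sim$recording)
  get <- function(m) tab[tab$metric == m, ]
  expect_lt(get("delta_rms")$value_injected, get("delta_rms")$value_control)
  expect_lt(get("slope2_max")$value_injected, get("slope2_max")$value_control)
  expect_lt(get("slope1_max")$value_injected, get("slope1_max")$value_control)
})
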