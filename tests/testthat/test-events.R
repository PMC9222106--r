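# Epileptiform event detection: beta bursts, hypersynchronous spikes,
# rates, phase locking and phenotype calls.

test_that("no injected events means no detections", {
  sim <- generate_lfp_pair(synth_config("control", seed = 2, duration = 120,
                                        fs_lfp = 500))
  inj <- sim$recording$channels$lfp_injected
  expect_equal(nrow(detect_beta_bursts(inj)), 0L)
  expect_equal(nrow(detect_hypersync_spikes(inj)), 0L)
})

test_that("injected 15 Hz bursts are recovered with durations within 20%", {
  cfg <- synth_config("mosaic", seed = 5, duration = 600, fs_lfp = 500,
                      mosaic = list(burst_rate_per_h = 120,
                                    hypersync_rate_per_h = 0))
  sim <- generate_lfp_pair(cfg)
  ev <- detect_beta_bursts(sim$recording$channels$lfp_injected)
  truth <- sim$truth$bursts
  expect_gte(nrow(truth), 15)
  # interval-overlap matching: overlapping injected bursts merge into one
  # detection, which still covers both
  covered <- vapply(seq_len(nrow(truth)), function(i) {
    any(ev$t_start < truth$t_end[i] & ev$t_end > truth$t_start[i])
  }, logical(1))
  expect_gte(mean(covered), 0.95)
  fp <- vapply(seq_len(nrow(ev)), function(i) {
    !any(truth$t_start - 0.5 < ev$t_end[i] & truth$t_end + 0.5 > ev$t_start[i])
  }, logical(1))
  expect_equal(sum(fp), 0L)
  expect_equal(mean(ev$duration) / mean(truth$duration), 1, tolerance = 0.2)
})

test_that("burst detection is invariant to polarity flip and DC offset", {
  cfg <- synth_config("mosaic", seed = 6, duration = 300, fs_lfp = 500,
                      mosaic = list(burst_rate_per_h = 60,
                                    hypersync_rate_per_h = 0))
  sim <- generate_lfp_pair(cfg)
  inj <- sim$recording$channels$lfp_injected
  ev <- detect_beta_bursts(inj)
  flip <- inj; flip$samples <- -inj$samples + 3
  ev2 <- detect_beta_bursts(flip)
  expect_equal(ev$t_peak, ev2$t_peak, tolerance = 1e-6)
})

test_that("hypersync morphology recovery and bound checks", {
  sim <- shared_mosaic_sim()
  inj <- sim$recording$channels$lfp_injected
  ev <- detect_hypersync_spikes(inj)
  truth <- sim$truth$spikes
  m <- match_events(ev$t_peak, truth$t_peak, tol = 0.1)
  expect_gte(m$matched / nrow(truth), 0.9)
  expect_lte(m$fp, 1L)
  expect_equal(mean(ev$duration), 0.23, tolerance = 0.1)
  expect_equal(mean(ev$amplitude), 0.49, tolerance = 0.1)
  # no overlapping events of the same type (dead-time guarantee)
  if (nrow(ev) > 1) expect_gte(min(diff(ev$t_peak)), 0.5)
  # DC offset invariance
  shifted <- inj; shifted$samples <- inj$samples + 2
  ev_dc <- detect_hypersync_spikes(shifted)
  expect_equal(nrow(ev_dc), nrow(ev))
})

test_that("a slow high-amplitude wave is rejected by the duration bound", {
  fs <- 500
  t <- seq(0, 120 - 1 / fs, by = 1 / fs)
  x <- 0.02 * rnorm(length(t))
  # 3 s wide, 1 mV half-sine bump at t = 60
  sel <- t >= 60 & t < 63
  x[sel] <- x[sel] + sin(pi * (t[sel] - 60) / 3)
  ev <- detect_hypersync_spikes(time_series(x, fs))
  expect_equal(nrow(ev), 0L)
})

test_that("event_rate is exact and unbiased for Poisson injections", {
  expect_equal(event_rate(event_table(runif(10, 0, 3600)), 3600), 10)
  expect_equal(event_rate(event_table(1000), 1800), 2)
  expect_error(event_rate(event_table(), 0), "> 0")
  set.seed(61)
  lambda <- 40  # per hour over 2 h
  errs <- vapply(1:50, function(i) {
    n <- rpois(1, lambda * 2)
    event_rate(event_table(sort(runif(n, 0, 7200))), 7200) - lambda
  }, numeric(1))
  expect_lt(abs(mean(errs)), 3 * sqrt(lambda / 2) / sqrt(50))
})

test_that("phase locking: perfect coupling, uniform placement, flags", {
  set.seed(62)
  us <- random_interval_set(40, 200, label = "US")
  inside <- us$start + runif(nrow(us)) * (us$end - us$start)
  pl1 <- phase_locking(event_table(sort(inside)), us, c(0, 200))
  expect_equal(pl1$fraction, 1)
  unif <- event_table(sort(runif(3000, 0, 200)))
  pl0 <- phase_locking(unif, us, c(0, 200))
  se <- sqrt(pl0$chance * (1 - pl0$chance) / 3000)
  expect_lt(abs(pl0$fraction - pl0$chance), 3 * se + 1e-6)
  few <- phase_locking(event_table(c(1, 2)), us, c(0, 200))
  expect_true(few$insufficient)
  expect_true(is.na(few$fraction))
})

test_that("phase_locking_test runs a one-sample t against chance", {
  r <- phase_locking_test(c(0.8, 0.85, 0.9, 0.75, 0.82), rep(0.6, 5))
  expect_lt(r$p_value, 0.01)
  expect_gt(r$statistic, 0)
  expect_error(phase_locking_test(c(0.8, 0.9), c(0.5, 0.5)), ">= 3")
})

test_that("phenotype thresholds are strict", {
  expect_false(classify_phenotype(3.0)$frequent_bursts)
  expect_true(classify_phenotype(3.1)$frequent_bursts)
  expect_true(classify_phenotype(4)$frequent_bursts)
  expect_false(classify_phenotype(4)$hyperexcitable)
  expect_false(classify_phenotype(5.0)$hyperexcitable)
  expect_true(classify_phenotype(5.1)$hyperexcitable)
  expect_error(classify_phenotype(-1), ">= 0")
})
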