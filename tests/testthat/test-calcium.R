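# Calcium analysis: dF/F, transient detection against ground truth,
# population statistics with the strict hyperactive criterion, field-of-view
# activity and up-state synchronization.

test_that("compute_dff: constant trace ~ 0, step ~ 1, gain invariance", {
  fs <- 30
  const <- time_series(rep(100, 90 * fs), fs, units = "au")
  d0 <- compute_dff(const)
  expect_lt(max(abs(d0$samples)), 1e-9)
  x <- rep(100, 90 * fs)
  x[1351:1360] <- 200   # brief step to 2x baseline
  d1 <- compute_dff(time_series(x, fs, units = "au"))
  expect_equal(max(d1$samples), 1, tolerance = 0.05)
  # multiplying raw F by a gain leaves dF/F unchanged
  d2 <- compute_dff(time_series(7.3 * x, fs, units = "au"))
  expect_equal(d2$samples, d1$samples, tolerance = 1e-9)
  expect_error(compute_dff(time_series(rep(1, 100), 30)), "baseline window")
})

test_that("slow drift barely affects detected transient amplitudes", {
  set.seed(81)
  cfgd <- synth_config("control", seed = 15, duration = 300,
                       calcium = list(n_neurons = 20, median_hz = 0.05,
                                      drift_amp = 4))
  cfg0 <- synth_config("control", seed = 15, duration = 300,
                       calcium = list(n_neurons = 20, median_hz = 0.05,
                                      drift_amp = 0))
  amp_of <- function(cfg) {
    sim <- generate_calcium(cfg)
    unlist(lapply(seq_len(20), function(i) {
      detect_transients(compute_dff(time_series(sim$F[, i], fs = sim$fs,
                                                units = "au")))$amplitudes
    }))
  }
  a_d <- amp_of(cfgd); a_0 <- amp_of(cfg0)
  expect_equal(mean(a_d), mean(a_0), tolerance = 0.1)
})

test_that("noise-only traces yield no transients in >= 95/100 runs", {
  set.seed(82)
  params <- transient_params(k = 3, sustain_s = 0.4)
  hits <- vapply(1:100, function(i) {
    dff <- time_series(rnorm(90 * 30) * 0.06, 30, units = "dF/F")
    length(detect_transients(dff, params)$times) > 0
  }, logical(1))
  expect_lte(sum(hits), 5)
})

test_that("transients at ~2/min, SNR 5: recall and precision >= 0.9", {
  cfg <- synth_config("control", seed = 16, duration = 600,
                      calcium = list(n_neurons = 30, median_hz = 2 / 60,
                                     tail_control = 1e-6))
  sim <- generate_calcium(cfg)
  tt <- score_transients(sim)
  tot <- c(matched = 0, fp = 0, fn = 0)
  for (i in seq_len(30)) {
    m <- match_events(attr(tt, "times")[[i]], sim$truth$times[[i]], tol = 0.3)
    tot <- tot + unlist(m)
  }
  expect_gte(tot["matched"] / (tot["matched"] + tot["fn"]), 0.9)
  expect_gte(tot["matched"] / (tot["matched"] + tot["fp"]), 0.9)
})

test_that("frequency estimates are unbiased at 2/min (Poisson truth)", {
  # mean relative error across neurons at a fixed 2/min rate
  cfg <- synth_config("control", seed = 17, duration = 600,
                      calcium = list(n_neurons = 60, median_hz = 2 / 60,
                                     tail_control = 1e-6))
  sim <- generate_calcium(cfg)
  tt <- score_transients(sim)
  expect_equal(mean(tt$n_events) / mean(lengths(sim$truth$times)), 1,
               tolerance = 0.05)
})

test_that("two kernels 0.5 s apart merge into one event (refractory rule)", {
  fs <- 30
  kern <- swaepi:::calcium_kernel(fs, 0.1, 1)
  x <- rep(0, 120 * fs)
  add_at <- function(x, t0) {
    i <- round(t0 * fs) + 1
    j <- i:min(length(x), i + length(kern) - 1)
    x[j] <- x[j] + 0.3 * kern[seq_along(j)]
    x
  }
  x <- add_at(add_at(x, 60), 60.5)
  x <- add_at(x, 90)  # isolated reference event
  set.seed(83)
  dff <- time_series(x + rnorm(length(x)) * 0.01, fs, units = "dF/F")
  det <- detect_transients(dff)
  expect_equal(sum(det$times > 55 & det$times < 65), 1L)
  expect_equal(sum(det$times > 85 & det$times < 95), 1L)
})

test_that("population_stats: strict boundary, sample-size guard, bartlett", {
  mk_tab <- function(freq_min) {
    tt <- data.frame(roi_id = paste0("r", seq_along(freq_min)),
                     genotype = "red_wildtype",
                     n_events = pmax(1, round(freq_min * 10)),
                     frequency_hz = freq_min / 60,
                     frequency_per_min = freq_min,
                     active = freq_min > 0,
                     hyperactive = freq_min > 4)
    attr(tt, "times") <- replicate(nrow(tt), numeric(0), simplify = FALSE)
    attr(tt, "duration") <- 600
    class(tt) <- c("transient_table", "data.frame")
    tt
  }
  all4 <- mk_tab(rep(4.0, 30))
  ps <- population_stats(c1 = all4)
  expect_equal(ps$conditions$c1$hyperactive_pct, 0)
  expect_error(population_stats(c1 = mk_tab(rep(1, 5))), "active neurons")
  set.seed(84)
  a <- mk_tab(exp(rnorm(100, 0, 0.5)))
  b <- mk_tab(exp(rnorm(100, 0, 1.5)))
  ps2 <- population_stats(narrow = a, wide = b)
  expect_lt(ps2$bartlett$p_value, 0.01)
})

test_that("hyperactive classification is monotone in the event count", {
  # more detected events never un-flags a neuron: direct property of the
  # strict > 4/min rule applied to count / duration
  f <- c(3.9, 4.0, 4.1, 10) / 60
  flags <- f * 60 > 4
  expect_equal(flags, c(FALSE, FALSE, TRUE, TRUE))
})

test_that("fov_activity: zero stack, flashing ROI, US phase locking", {
  expect_error(fov_activity(matrix(numeric(0), 0, 3), fs = 30), "empty")
  # single ROI flashing in known frames (3D pixel stack)
  stack <- array(0, dim = c(300, 5, 5))
  set.seed(85)
  stack[, , ] <- rnorm(length(stack)) * 0.01
  on_frames <- c(50:55, 150:155)
  stack[on_frames, 2:3, 2:3] <- 1
  fa <- fov_activity(stack, fs = 10, smooth_s = 0)
  expect_gte(max(fa$counts[on_frames]), 4)   # the 4 ROI pixels (+ rare noise)
  expect_lte(median(fa$counts[on_frames]), 6)
  expect_lte(median(fa$counts[-on_frames]), 1)
  # population counts peak near zero lag against the up-state indicator
  sim <- generate_calcium(synth_config("control", seed = 18, duration = 300,
                                       calcium = list(n_neurons = 60)))
  fa2 <- fov_activity(sim, k = 3)
  tt_frames <- (seq_along(fa2$counts) - 1) / fa2$fs
  us_ind <- as.numeric(iv_contains(tt_frames, sim$truth$us))
  cc <- ccf(fa2$counts, us_ind, lag.max = 30, plot = FALSE)
  # indicator decay (~1 s) delays the count trace slightly past the US
  lag_s <- cc$lag[which.max(cc$acf)] / fa2$fs
  expect_gte(lag_s, -0.2)
  expect_lte(lag_s, 0.6)
})

test_that("transients_in_us: perfect coupling, chance, condition ordering", {
  sim <- generate_calcium(synth_config("control", seed = 19, duration = 300,
                                       calcium = list(n_neurons = 40,
                                                      p_us_control = 1)))
  # on the true transient times the coupled fraction is exactly 1
  truth_tab <- structure(data.frame(roi_id = "all"), class = c("transient_table",
                                                               "data.frame"))
  attr(truth_tab, "times") <- sim$truth$times
  r_true <- transients_in_us(truth_tab, list(us = sim$truth$us, duration = 300))
  expect_equal(r_true$percent, 100)
  tt <- score_transients(sim)
  r <- transients_in_us(tt, list(us = sim$truth$us, duration = 300))
  expect_gt(r$percent, 90)   # detection timing jitter only
  sim_u <- generate_calcium(synth_config("control", seed = 19, duration = 300,
                                         calcium = list(n_neurons = 40,
                                                        p_us_control = NA)))
  tt_u <- score_transients(sim_u)
  r_u <- transients_in_us(tt_u, list(us = sim_u$truth$us, duration = 300))
  se <- 100 * sqrt(r_u$chance / 100 * (1 - r_u$chance / 100) / r_u$n)
  expect_lt(abs(r_u$percent - r_u$chance), 3 * se + 2)
  # mosaic (lower coupling) < control in the same seeds
  ok <- vapply(1:5, function(s) {
    sc <- generate_calcium(synth_config("control", seed = s, duration = 300,
                                        calcium = list(n_neurons = 50)))
    sm <- generate_calcium(synth_config("mosaic", seed = s, duration = 300,
                                        calcium = list(n_neurons = 50)))
    pc <- transients_in_us(score_transients(sc),
                           list(us = sc$truth$us, duration = 300))$percent
    pm <- transients_in_us(score_transients(sm),
                           list(us = sm$truth$us, duration = 300))$percent
    pm < pc
  }, logical(1))
  expect_true(all(ok))
})
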