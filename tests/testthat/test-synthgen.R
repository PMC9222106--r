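# Synthetic-data generator: determinism, renewal expectations, ground-truth
# consistency, and component-level oracles.

test_that("state sequence matches renewal expectations and determinism", {
  cfg <- synth_config("control", seed = 3, duration = 600)
  st <- generate_state_sequence(cfg)
  # duty cycle ~ mean_us / (mean_us + mean_ds) = 0.5 / 0.8
  duty <- duty_cycle(st$us, 0, 600)
  n_cyc <- nrow(st$us)
  se <- sqrt(duty * (1 - duty) / n_cyc)   # conservative renewal SE
  expect_lt(abs(duty - 0.625), 3 * se + 0.01)
  # determinism
  st2 <- generate_state_sequence(cfg)
  expect_identical(st$us, st2$us)
  # us and ds partition the record
  expect_equal(iv_total(st$us) + iv_total(st$ds), 600, tolerance = 1e-9)
  expect_equal(nrow(iv_intersect(st$us, st$ds)), 0L)
})

test_that("zero-variance dwells give a strictly periodic alternation", {
  cfg <- synth_config("control", seed = 1, duration = 60,
                      state = list(us_shape = Inf, ds_shape = Inf,
                                   us_mean = 0.5, ds_mean = 0.3))
  st <- generate_state_sequence(cfg)
  expect_equal(diff(st$us$start), rep(0.8, nrow(st$us) - 1), tolerance = 1e-9)
  expect_equal(st$us$end - st$us$start, rep(0.5, nrow(st$us)), tolerance = 1e-9)
})

test_that("duration shorter than 10 cycles is a config error", {
  expect_error(synth_config("control", duration = 5), "10x the mean")
})

test_that("lfp pair: determinism, empty truth at zero rates, lag only", {
  cfg <- synth_config("control", seed = 9, duration = 80)
  a <- generate_lfp_pair(cfg)
  b <- generate_lfp_pair(cfg)
  expect_identical(a$recording$channels$lfp_injected$samples,
                   b$recording$channels$lfp_injected$samples)
  expect_equal(nrow(a$truth$bursts), 0L)
  expect_equal(nrow(a$truth$spikes), 0L)
  # control profile: channels share the state sequence, so their delta-band
  # signals are strongly correlated at (approximately) the configured lag
  d_i <- bandpass(a$recording$channels$lfp_injected, "delta")$samples
  d_c <- bandpass(a$recording$channels$lfp_control, "delta")$samples
  cc <- ccf(d_c, d_i, lag.max = 50, plot = FALSE)
  expect_gt(max(cc$acf), 0.9)
  best_lag <- cc$lag[which.max(cc$acf)]
  expect_lte(abs(best_lag), 15)   # near-synchronous, lag on the ms scale
})

test_that("delta RMS of the control channel matches the component oracle", {
  cfg <- synth_config("control", seed = 5, duration = 120)
  sim <- generate_lfp_pair(cfg, return_components = TRUE)
  ctl <- sim$recording$channels$lfp_control
  # oracle: RMS of delta-filtered noiseless component sum, plus the
  # delta-band share of the stochastic background, combined in quadrature
  clean <- time_series(sim$truth$components$control_clean, ctl$fs)
  rms_clean <- band_rms(clean, "delta")
  bg <- time_series(ctl$samples - clean$samples, ctl$fs)
  rms_bg <- band_rms(bg, "delta")
  oracle <- sqrt(rms_clean^2 + rms_bg^2)
  expect_equal(band_rms(ctl, "delta"), oracle, tolerance = 0.1)
})

test_that("ground truth is consistent with the coupling draws", {
  cfg <- synth_config("mosaic", seed = 12, duration = 300)
  sim <- generate_lfp_pair(cfg)
  sp <- sim$truth$spikes
  expect_true(all(sp$t_peak >= 0 & sp$t_peak <= 300))
  inside <- iv_contains(sp$t_peak, sim$truth$us)
  expect_equal(inside, sim$truth$spike_coupled)
  # coupled fraction is binomially consistent with p_us = 0.81
  n <- nrow(sp)
  expect_lt(abs(mean(inside) - 0.81), 3 * sqrt(0.81 * 0.19 / n))
})

test_that("mosaic injected channel has lower delta RMS than control", {
  # direction per the paired-hemisphere phenotype; a fuller 100-seed suite
  # runs in the acceptance tests
  ok <- vapply(1:10, function(s) {
    sim <- generate_lfp_pair(synth_config("mosaic", seed = s, duration = 80,
                                          fs_lfp = 500))
    band_rms(sim$recording$channels$lfp_injected, "delta") <
      band_rms(sim$recording$channels$lfp_control, "delta")
  }, logical(1))
  expect_true(all(ok))
})

test_that("eeg/emg generator: NREM placement, occupancy, determinism", {
  cfg <- synth_config("mosaic", seed = 4, duration = 2400,
                      burst = list(p_nrem = 1), eeg = list(burst_rate_per_h = 60))
  sim <- generate_eeg_emg(cfg)
  expect_gt(nrow(sim$truth$bursts), 10)
  expect_true(all(iv_contains(sim$truth$bursts$t_peak, sim$truth$hypnogram$NREM)))
  # occupancy vs dwell-time expectation (240/300/60 of a 600 s cycle)
  occ <- vapply(sim$truth$hypnogram, iv_total, numeric(1)) / 2400
  exp_occ <- c(Wake = 240, NREM = 300, REM = 60) / 600
  n_bouts <- vapply(sim$truth$hypnogram, nrow, integer(1))
  for (s in names(exp_occ)) {
    se <- exp_occ[[s]] * (1 / sqrt(max(n_bouts[[s]], 1)))  # coarse renewal SE
    expect_lt(abs(occ[[s]] - exp_occ[[s]]), 3 * se + 0.02)
  }
  sim2 <- generate_eeg_emg(cfg)
  expect_identical(sim$recording$channels$eeg_injected$samples,
                   sim2$recording$channels$eeg_injected$samples)
})

test_that("calcium generator: Poisson counts, zero-rate flatness, dispersion", {
  cfg <- synth_config("control", seed = 6, duration = 600,
                      calcium = list(n_neurons = 100, median_hz = 0.03,
                                     tail_control = 0.05))
  sim <- generate_calcium(cfg)
  # chi-square goodness of fit of per-neuron counts vs Poisson(rate * T)
  counts <- lengths(sim$truth$times)
  lam <- sim$truth$rates * 600
  z <- (counts - lam) / sqrt(lam)
  # z^2 sums to ~ chi-square with 100 df under Poisson dispersion
  p <- pchisq(sum(z^2), df = 100, lower.tail = FALSE)
  expect_gt(p, 0.01)

  cfg0 <- synth_config("control", seed = 6, duration = 120,
                       calcium = list(n_neurons = 5, median_hz = 1e-9,
                                      tail_control = 1e-6, noise_dff = 0.01))
  sim0 <- generate_calcium(cfg0)
  expect_equal(sum(lengths(sim0$truth$times)), 0)
  expect_lt(max(apply(sim0$F, 2, sd)), 3)   # baseline + noise + drift only

  # mosaic dispersion exceeds control on the true rates (Bartlett)
  ok <- vapply(1:10, function(s) {
    rc <- generate_calcium(synth_config("control", seed = s, duration = 60,
                                        calcium = list(n_neurons = 150)))$truth$rates
    rm_ <- generate_calcium(synth_config("mosaic", seed = s + 500, duration = 60,
                                         calcium = list(n_neurons = 150)))$truth$rates
    stats::bartlett.test(list(rc, rm_))$p.value < 0.01 && var(rm_) > var(rc)
  }, logical(1))
  expect_gte(sum(ok), 9)
})

test_that("calcium sdlog calibration inverts the lognormal tail exactly", {
  sdl <- calcium_sdlog(0.018, 0.078)
  expect_equal(plnorm(4 / 60, log(0.018), sdl, lower.tail = FALSE), 0.078)
  expect_equal(qlnorm(0.5, log(0.018), sdl), 0.018)
})

test_that("yaml config round trip preserves the generator world", {
  cfg <- synth_config("mosaic", seed = 77, duration = 100,
                      burst = list(rate_per_h = 7))
  p <- tempfile(fileext = ".yaml")
  write_synth_config(cfg, p)
  cfg2 <- read_synth_config(p)
  expect_equal(unclass(cfg2), unclass(cfg), tolerance = 1e-6)
})
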