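# Band filtering, Welch spectra, cross spectra and the exponent fit.

test_that("bandpass preserves in-band tones and rejects stop-band tones", {
  fs <- 500
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  s2 <- time_series(sin(2 * pi * 2 * t), fs)
  out <- bandpass(s2, "delta")$samples
  expect_equal(sd(out[1000:28000]), sd(s2$samples) , tolerance = 0.02)
  s30 <- time_series(sin(2 * pi * 30 * t), fs)
  out30 <- bandpass(s30, "delta")$samples
  expect_lt(sqrt(mean(out30^2)), 0.01 * sqrt(mean(s30$samples^2)))
  expect_error(bandpass(time_series(rnorm(1000), 50), "gamma"), "Nyquist")
})

test_that("white-noise band variance matches the flat-spectrum integral", {
  set.seed(41)
  fs <- 1000
  x <- time_series(rnorm(120 * fs), fs)
  v <- var(bandpass(x, band_def("custom", 50, 150))$samples)
  expect_lt(abs(v - var(x$samples) * 0.2), 0.1 * var(x$samples) * 0.2)
})

test_that("zero-phase: band-passed sine has zero lag", {
  fs <- 500
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 2 * t)
  y <- bandpass(time_series(x, fs), "delta")$samples
  cc <- ccf(x[2000:13000], y[2000:13000], lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("band_rms matches analytic values and the PSD integral", {
  fs <- 500
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  a <- 0.7
  s <- time_series(a * sin(2 * pi * 2 * t), fs)
  expect_equal(band_rms(s, "delta"), a / sqrt(2), tolerance = 0.02)
  expect_equal(band_rms(time_series(rep(0, 30 * fs) + 1e-12 * rnorm(30 * fs), fs),
                        "delta"), 0, tolerance = 1e-10)
  expect_error(band_rms(time_series(rnorm(fs), fs), "delta"), "too short")
  # agreement with the integral of the PSD over the band
  set.seed(42)
  sim <- generate_lfp_pair(synth_config("control", seed = 5, duration = 120,
                                        fs_lfp = 500))
  ctl <- sim$recording$channels$lfp_control
  sp <- welch_psd(ctl, segment_s = 8)
  df <- diff(sp$freq[1:2])
  in_band <- sp$freq >= 0.5 & sp$freq <= 4
  rms_psd <- sqrt(sum(sp$power[in_band]) * df)
  expect_equal(band_rms(ctl, "delta"), rms_psd, tolerance = 0.1)
})

test_that("welch_psd is flat for white noise, peaked for a tone, Parseval", {
  set.seed(43)
  fs <- 200
  x <- time_series(rnorm(240 * fs), fs)
  sp <- welch_psd(x)
  # flat density ~ 1/(fs/2) per Hz, averaged over coarse bands
  for (b in list(c(1, 20), c(30, 60), c(70, 95))) {
    sel <- sp$freq >= b[1] & sp$freq <= b[2]
    expect_equal(mean(sp$power[sel]), 1 / (fs / 2), tolerance = 0.1)
  }
  tone <- time_series(sin(2 * pi * 10 * seq(0, 120, by = 1 / fs)), fs)
  spt <- welch_psd(tone)
  expect_equal(spt$freq[which.max(spt$power)], 10, tolerance = 0.26)
  # Parseval on synthetic LFP
  sim <- shared_mosaic_sim()
  ctl <- sim$recording$channels$lfp_control
  # 16 s segments: the slow-wave record carries real power below the
  # reciprocal of a 4 s segment, which per-segment demeaning would discard
  spc <- welch_psd(ctl, segment_s = 16)
  expect_equal(sum(spc$power) * diff(spc$freq[1:2]), var(ctl$samples),
               tolerance = 0.05)
  expect_error(welch_psd(time_series(rnorm(100), 10)), "64 samples")
  expect_error(welch_psd(time_series(rnorm(200), 100), segment_s = 100),
               "longer than the record")
})

test_that("cross_spectrum: identity, incoherent decay, burst coherence", {
  set.seed(44)
  fs <- 200
  x <- time_series(rnorm(120 * fs), fs)
  w <- interval_set(0, 120)
  cs <- cross_spectrum(x, x, w)
  au <- welch_psd(x, segment_s = 1)
  expect_equal(cs$power, au$power, tolerance = 1e-8)

  # independent noises: magnitude decreases as segments accumulate
  y <- time_series(rnorm(120 * fs), fs)
  m4 <- mean(cross_spectrum(x, y, interval_set(0, 2.5))$power)
  m64 <- mean(cross_spectrum(x, y, interval_set(0, 40))$power)
  expect_lt(m64, m4)

  # shared 15 Hz carrier only inside "burst" windows
  t <- seq(0, 120 - 1 / fs, by = 1 / fs)
  carrier <- sin(2 * pi * 15 * t)
  bw <- interval_set(seq(10, 100, by = 10), seq(12, 102, by = 10))
  gate <- iv_contains(t, bw)
  a <- time_series(rnorm(length(t)) * 0.5 + carrier * gate, fs)
  b <- time_series(rnorm(length(t)) * 0.5 + carrier * gate, fs)
  in_burst <- cross_spectrum(a, b, bw)
  out_burst <- cross_spectrum(a, b, iv_complement(bw, 0, 120))
  pk <- function(cs) cs$power[which.min(abs(cs$freq - 15))]
  flank <- function(cs) mean(cs$power[cs$freq > 20 & cs$freq < 40])
  expect_gt(pk(in_burst) / flank(in_burst), 10)
  expect_lt(pk(out_burst) / flank(out_burst), 3)
  expect_error(cross_spectrum(a, b, interval_set(0, 0.5)), "shorter than one segment")
})

test_that("spectral exponent: white ~ 0, 1/f^2 recovered, scale-invariant", {
  set.seed(45)
  fs <- 200
  wn <- welch_psd(time_series(rnorm(300 * fs), fs))
  for (model in c("semilog_exponential", "loglog_powerlaw")) {
    f <- fit_spectral_exponent(wn, model = model)
    expect_lt(abs(f$exponent), 2 * f$exponent_se + 0.02)
  }
  # synthesized 1/f^2 noise via the shaping-filter construction
  pink <- swaepi:::one_over_f_noise(600 * fs, fs, 2, 1, f_min = 0.5)
  sp <- welch_psd(time_series(pink, fs), segment_s = 8)
  f2 <- fit_spectral_exponent(sp, 1, 50, model = "loglog_powerlaw")
  expect_equal(f2$exponent, 2, tolerance = 0.15)
  # scale invariance: gain changes the intercept, not the exponent
  sp10 <- sp; sp10$power <- sp$power * 100
  f10 <- fit_spectral_exponent(sp10, 1, 50, model = "loglog_powerlaw")
  expect_equal(f10$exponent, f2$exponent, tolerance = 1e-10)
  expect_equal(f10$intercept - f2$intercept, 2, tolerance = 1e-10)
  # nonpositive bins rejected
  bad <- sp; bad$power[10] <- 0
  expect_error(fit_spectral_exponent(bad, 1, 50), "nonpositive")
  expect_error(fit_spectral_exponent(wn, 1, 1.05), "8 frequency bins")
})

test_that("extra steep low-frequency power raises the fitted exponent", {
  # inhibition surrogate: adding a steep 1/f^3 component below 50 Hz
  set.seed(46)
  fs <- 200
  base <- swaepi:::one_over_f_noise(300 * fs, fs, 1.6, 0.05, f_min = 0.5)
  gaba <- swaepi:::one_over_f_noise(300 * fs, fs, 3.0, 0.08, f_min = 0.5)
  f_b <- fit_spectral_exponent(welch_psd(time_series(base + 1e-3 * rnorm(300 * fs), fs)))
  f_g <- fit_spectral_exponent(welch_psd(time_series(base + gaba + 1e-3 * rnorm(300 * fs), fs)))
  expect_gt(f_g$exponent, f_b$exponent)
})
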