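# Synthetic chronic EEG/EMG with a ground-truth hypnogram.
#
# Vigilance states cycle Wake -> NREM -> REM with gamma dwell times.
# Per-stage EEG content: NREM has strong delta (0.5-4 Hz), REM is
# theta-dominant (6-9 Hz), Wake is low-amplitude broadband; EMG variance is
# high in Wake only. Beta bursts are injected into the "injected" EEG
# channel, landing inside NREM with probability p_nrem and uniformly
# outside NREM otherwise.

gen_hypnogram <- function(hyp, duration) {
  stages <- c("Wake", "NREM", "REM")
  means <- c(hyp$wake_mean, hyp$nrem_mean, hyp$rem_mean)
  shapes <- c(hyp$wake_shape, hyp$nrem_shape, hyp$rem_shape)
  t <- 0; k <- 1L
  s_out <- character(0); t0 <- numeric(0); t1 <- numeric(0)
  while (t < duration) {
    d <- gen_dwell(1L, shapes[k], means[k])
    s_out <- c(s_out, stages[k]); t0 <- c(t0, t); t1 <- c(t1, min(t + d, duration))
    t <- t + d
    k <- if (k == 3L) 1L else k + 1L
  }
  lapply(stats::setNames(stages, stages), function(s) {
    sel <- s_out == s
    if (!any(sel)) interval_set(label = s)
    else interval_set(t0[sel], t1[sel], label = s)
  })
}

#' Generate a synthetic EEG/EMG recording with hypnogram ground truth
#'
#' @param cfg a [synth_config()]; `cfg$eeg$burst_rate_per_h` beta bursts
#'   are injected into the injected-hemisphere EEG channel with NREM
#'   coupling `cfg$burst$p_nrem` (only under `profile = "mosaic"`, or when
#'   `force_bursts = TRUE`).
#' @param force_bursts inject bursts regardless of profile.
#' @return list with `recording` (channels `eeg_injected`, `eeg_control`,
#'   `emg`), and `truth` (per-stage [interval_set()]s, `bursts`
#'   [event_table()], `burst_coupled` flags).
#' @export
generate_eeg_emg <- function(cfg, force_bursts = FALSE) {
  validate_synth_config(cfg)
  fs <- cfg$eeg$fs
  dur <- cfg$duration
  n <- as.integer(round(dur * fs))
  e <- cfg$eeg

  with_seed(cfg$seed + 11L, {
    hyp <- gen_hypnogram(cfg$hypnogram, dur)
    tt <- (seq_len(n) - 1) / fs
    ind <- lapply(hyp, function(iv) {
      w <- as.numeric(iv_contains(tt, iv))
      moving_average(w, 0.5 * fs)          # soft 0.5 s stage transitions
    })

    make_eeg <- function() {
      delta_amp <- ind$NREM * e$nrem_delta_rms + ind$REM * e$rem_delta_rms +
        ind$Wake * e$wake_delta_rms
      theta_amp <- ind$REM * e$rem_theta_rms
      broad_amp <- ind$Wake * e$wake_broadband_rms +
        (ind$NREM + ind$REM) * e$sleep_broadband_rms
      band_noise(n, fs, 0.5, 4) * delta_amp +
        band_noise(n, fs, 6, 9) * theta_amp +
        one_over_f_noise(n, fs, 1.5, 1) * broad_amp
    }
    eeg_inj <- make_eeg()
    eeg_ctl <- make_eeg()
    emg <- rnorm(n) * (ind$Wake * e$emg_wake_rms +
                       (ind$NREM + ind$REM) * e$emg_sleep_rms)

    bursts <- event_table(channel = "eeg_injected", type = "beta_burst")
    coupled <- logical(0)
    if (cfg$profile == "mosaic" || force_bursts) {
      n_b <- rpois(1L, e$burst_rate_per_h * dur / 3600)
      pl <- place_event_times(n_b, hyp$NREM, dur, cfg$burst$p_nrem, margin = 3)
      if (n_b > 0L) {
        d_b <- rlnorm(n_b, cfg$burst$dur_meanlog, cfg$burst$dur_sdlog)
        ph <- runif(n_b, 0, 2 * pi)
        for (k in seq_len(n_b)) {
          i0 <- max(1L, as.integer(round((pl$times[k] - d_b[k] / 2) * fs)) + 1L)
          i1 <- min(n, as.integer(round((pl$times[k] + d_b[k] / 2) * fs)))
          if (i1 <= i0) next
          seg <- i0:i1
          eeg_inj[seg] <- eeg_inj[seg] + e$burst_amp * hann_window(length(seg)) *
            sin(2 * pi * cfg$burst$carrier * tt[seg] + ph[k])
        }
        bursts <- event_table(pl$times, pl$times - d_b / 2, pl$times + d_b / 2,
                              amplitude = rep(e$burst_amp, n_b),
                              channel = "eeg_injected", type = "beta_burst")
        coupled <- pl$coupled
      }
    }

    rec <- recording(
      list(eeg_injected = time_series(eeg_inj, fs, label = "eeg_injected"),
           eeg_control = time_series(eeg_ctl, fs, label = "eeg_control"),
           emg = time_series(emg, fs, label = "emg")),
      animal_id = sprintf("sim%04d", cfg$seed),
      group = if (cfg$profile == "mosaic") "mosaic_pup" else "control",
      hemisphere_map = c(eeg_injected = "injected",
                         eeg_control = "control_hemisphere", emg = "none"))
    list(recording = rec,
         truth = structure(list(hypnogram = hyp, bursts = bursts,
                                burst_coupled = coupled),
                           class = "ground_truth"))
  })
}
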