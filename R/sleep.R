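# Threshold-based Wake/NREM/REM scoring of chronic EEG/EMG, and coupling
# of beta bursts to NREM sleep.
#
# Per epoch: Wake when EMG RMS exceeds a per-record percentile threshold;
# otherwise NREM when the delta/total power ratio is high; otherwise REM
# when theta dominates delta; otherwise NREM. A 3-epoch majority filter
# removes isolated flips. Ratio features make the scorer invariant to EEG
# gain; the percentile-based EMG threshold makes it scale-equivariant in
# the EMG.

#' Score sleep stages from EEG and EMG
#'
#' @param eeg,emg simultaneous [time_series()] of at least 10 min, equal
#'   duration.
#' @param epoch_s scoring epoch length in seconds (default 4).
#' @param theta_delta_min REM when theta(6-9)/delta(0.5-4) RMS ratio
#'   exceeds this (default 1.0).
#' @param delta_ratio_min NREM when delta/total(0.5-30) RMS ratio exceeds
#'   this (default 0.45).
#' @param emg_percentile retained for configuration compatibility; the
#'   effective EMG threshold is the midpoint of the 10th and 90th
#'   per-epoch RMS percentiles (occupancy-robust), with a flat-EMG guard
#'   that scores everything as sleep when no wake cluster exists.
#' @param smooth apply the 3-epoch majority filter (default TRUE).
#' @return object of class `hypnogram`: data.frame `epochs` with columns
#'   `t_start`, `label`, `delta_ratio`, `theta_delta`, `emg_rms`, plus
#'   `epoch_s` and `duration`.
#' @export
score_sleep <- function(eeg, emg, epoch_s = 4, theta_delta_min = 1.0,
                        delta_ratio_min = 0.45, emg_percentile = 0.6,
                        smooth = TRUE) {
  if (abs(ts_duration(eeg) - ts_duration(emg)) > epoch_s)
    stopf("EEG and EMG durations differ by more than one epoch")
  if (ts_duration(eeg) < 600) stopf("need at least 10 min for sleep scoring")
  fs <- eeg$fs
  L <- as.integer(round(epoch_s * fs))
  n_ep <- length(eeg$samples) %/% L

  ep_rms <- function(x, fs_x) {
    Lx <- as.integer(round(epoch_s * fs_x))
    nx <- min(length(x) %/% Lx, n_ep)
    m <- matrix(x[seq_len(nx * Lx)]^2, nrow = Lx)
    sqrt(colMeans(m))[seq_len(n_ep)]
  }
  d <- bandpass(eeg, "delta")$samples
  th <- bandpass(eeg, band_def("custom", 6, 9))$samples
  tot <- bandpass(eeg, band_def("custom", 0.5, 30))$samples
  r_delta <- ep_rms(d, fs) / pmax(ep_rms(tot, fs), 1e-12)
  r_theta <- ep_rms(th, fs) / pmax(ep_rms(d, fs), 1e-12)
  emg_rms <- ep_rms(emg$samples, emg$fs)

  # EMG threshold: midpoint of the 10th/90th percentiles separates the
  # sleep and wake clusters regardless of their occupancy; a flat EMG
  # (spread below 3x) means no wake epochs at all
  q <- stats::quantile(emg_rms, c(0.1, emg_percentile, 0.9), names = FALSE)
  thr_emg <- if (q[3] < 3 * max(q[1], 1e-12)) Inf else (q[1] + q[3]) / 2
  lab <- ifelse(emg_rms > thr_emg, "Wake",
                ifelse(r_delta > delta_ratio_min, "NREM",
                       ifelse(r_theta > theta_delta_min, "REM", "NREM")))
  if (smooth && n_ep >= 3L) {
    sm <- lab
    for (i in 2:(n_ep - 1L)) {
      w <- lab[(i - 1L):(i + 1L)]
      tb <- table(w)
      if (max(tb) >= 2L) sm[i] <- names(tb)[which.max(tb)]
    }
    lab <- sm
  }
  structure(list(
    epochs = data.frame(t_start = (seq_len(n_ep) - 1L) * epoch_s, label = lab,
                        delta_ratio = r_delta, theta_delta = r_theta,
                        emg_rms = emg_rms, stringsAsFactors = FALSE),
    epoch_s = epoch_s, duration = n_ep * epoch_s,
    emg_threshold = thr_emg), class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  tb <- table(x$epochs$label)
  cat(sprintf("<hypnogram> %d epochs of %g s: %s\n", nrow(x$epochs), x$epoch_s,
              paste(sprintf("%s %.1f%%", names(tb), 100 * tb / sum(tb)),
                    collapse = ", ")))
  invisible(x)
}

#' Interval set of a hypnogram stage
#' @param hyp a `hypnogram`.
#' @param stage `"Wake"`, `"NREM"` or `"REM"`.
#' @export
hypnogram_intervals <- function(hyp, stage = c("NREM", "REM", "Wake")) {
  stage <- match.arg(stage)
  sel <- hyp$epochs$label == stage
  if (!any(sel)) return(interval_set(label = stage))
  interval_set(hyp$epochs$t_start[sel], hyp$epochs$t_start[sel] + hyp$epoch_s,
               label = stage)
}

#' Coupling of beta bursts to NREM sleep
#'
#' Percentage of burst peaks inside NREM-labeled epochs; the chance level
#' is the NREM time fraction.
#'
#' @param ev an [event_table()] of bursts (>= 5 for a defined result).
#' @param hyp a `hypnogram` (or an [interval_set()] of NREM epochs plus
#'   `duration`).
#' @return list with `percent_in_nrem`, `chance`, `n`, `insufficient`.
#' @export
burst_state_coupling <- function(ev, hyp) {
  nrem <- if (inherits(hyp, "hypnogram")) hypnogram_intervals(hyp, "NREM") else hyp
  dur <- if (inherits(hyp, "hypnogram")) hyp$duration else max(nrem$end)
  chance <- 100 * duty_cycle(nrem, 0, dur)
  if (nrow(ev) < 5L) {
    return(list(percent_in_nrem = NA_real_, chance = chance, n = nrow(ev),
                insufficient = TRUE))
  }
  r <- events_in_intervals(ev, nrem)
  list(percent_in_nrem = 100 * r$fraction, chance = chance, n = r$n,
       insufficient = FALSE)
}
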