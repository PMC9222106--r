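# Detection of the two hyperexcitability signatures: sustained beta-band
# (9-25 Hz) bursts and brief large-amplitude hypersynchronous spikes
# (interictal-like events), plus rates, phenotype classification, and
# phase locking to contralateral up states.

#' Parameters for beta-burst detection
#' @param band detection band in Hz (default 9-25).
#' @param smooth_s envelope smoothing window (s).
#' @param threshold_mad envelope threshold in MAD units above the
#'   (running) median (default 5; an envelope has heavier-than-Gaussian
#'   tails, so 3 MAD admits noise runs).
#' @param min_duration minimal burst duration (s); "sustained" oscillations
#'   only, not single cycles.
#' @param boundary_mad after detection, burst boundaries are extended
#'   outward to this lower envelope threshold (two-threshold scheme; the
#'   high threshold decides, the low one delimits).
#' @param merge_gap supra-threshold runs closer than this are merged (s).
#' @param adaptive_s window (s) of the running-median envelope baseline;
#'   makes the threshold follow slow background changes (e.g. across
#'   vigilance states in chronic EEG). `NULL` uses the global median.
#' @param order Butterworth order of the band filter (default 8: a steep
#'   edge keeps strong REM theta, just below 9 Hz, out of the band).
#' @param theta_guard reject candidate bursts whose theta-band
#'   (`guard_band`) envelope at the peak exceeds `guard_ratio` times the
#'   beta envelope: REM theta rides the lower band edge and otherwise
#'   masquerades as beta bursts, while genuine bursts carry little theta.
#' @param guard_band,guard_ratio theta-guard parameters.
#' @export
burst_params <- function(band = c(9, 25), smooth_s = 0.1, threshold_mad = 5,
                         boundary_mad = 1, min_duration = 0.5,
                         merge_gap = 0.2, adaptive_s = 60, order = 8L,
                         theta_guard = TRUE, guard_band = c(5, 9),
                         guard_ratio = 0.5) {
  if (min_duration <= 0) stopf("min_duration must be > 0")
  if (boundary_mad > threshold_mad) stopf("boundary_mad must be <= threshold_mad")
  list(band = band, smooth_s = smooth_s, threshold_mad = threshold_mad,
       boundary_mad = boundary_mad, min_duration = min_duration,
       merge_gap = merge_gap, adaptive_s = adaptive_s, order = order,
       theta_guard = theta_guard, guard_band = guard_band,
       guard_ratio = guard_ratio)
}

hilbert_envelope <- function(x) {
  n <- length(x)
  np <- stats::nextn(n, c(2, 3, 5))
  xp <- c(x, rep(0, np - n))
  X <- stats::fft(xp)
  h <- rep(0, np)
  h[1L] <- 1
  if (np %% 2L == 0L) { h[np / 2 + 1L] <- 1; h[2:(np / 2)] <- 2 }
  else h[2:((np + 1L) / 2)] <- 2
  Mod(stats::fft(X * h, inverse = TRUE) / np)[seq_len(n)]
}

runs_above <- function(above) {
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Detect beta-band bursts
#'
#' The envelope is the smoothed magnitude of the analytic signal of the
#' band-passed trace; a burst is a supra-threshold run of at least
#' `min_duration` after merging gaps shorter than `merge_gap`. The
#' threshold is `median + threshold_mad * MAD` of the envelope of the same
#' recording, making detection invariant to overall gain and polarity.
#'
#' @param ts a [time_series()] of at least 60 s.
#' @param params a [burst_params()] list.
#' @return an [event_table()] of type `"beta_burst"`; amplitude is the
#'   peak envelope (mV).
#' @export
detect_beta_bursts <- function(ts, params = burst_params()) {
  if (ts_duration(ts) < 60) stopf("need at least 60 s of signal")
  band <- as_band(params$band)
  bp <- bandpass(ts, band, order = params$order %||% 8L)$samples
  env <- hilbert_envelope(bp)
  env <- moving_average(env, params$smooth_s * ts$fs)
  med <- if (is.null(params$adaptive_s)) stats::median(env)
         else running_median(env, ts$fs, params$adaptive_s)
  # normalize by the (running) median: for an envelope, background scale is
  # proportional to its local median, so both location and spread adapt
  ratio <- env / pmax(med, .Machine$double.eps)
  madv <- stats::mad(ratio)
  thr <- med * (1 + params$threshold_mad * madv)
  thr_lo <- med * (1 + params$boundary_mad * madv)
  rr <- runs_above(env > thr)
  if (!nrow(rr)) return(event_table(channel = ts$label, type = "beta_burst"))
  # the high threshold decides: merge runs and apply the duration criterion
  m <- merge_gaps((rr[, "start"] - 1L) / ts$fs, (rr[, "end"] - 1L) / ts$fs,
                  params$merge_gap)
  keep <- (m$end - m$start) >= params$min_duration
  s <- m$start[keep]; e <- m$end[keep]
  if (!length(s)) return(event_table(channel = ts$label, type = "beta_burst"))
  # the low threshold delimits: extend boundaries to the envelope tails
  below <- env <= thr_lo
  n <- length(env)
  w_max <- as.integer(round(5 * ts$fs))
  for (k in seq_along(s)) {
    i <- as.integer(round(s[k] * ts$fs)) + 1L
    lo <- max(1L, i - w_max)
    j <- which(below[lo:i])
    s[k] <- if (length(j)) (lo + j[length(j)] - 1L) / ts$fs else (lo - 1L) / ts$fs
    i <- as.integer(round(e[k] * ts$fs)) + 1L
    hi <- min(n, i + w_max)
    j <- which(below[i:hi])
    e[k] <- if (length(j)) (i + j[1L] - 3L) / ts$fs else (hi - 1L) / ts$fs
  }
  m <- merge_gaps(s, e, params$merge_gap)
  s <- m$start; e <- m$end
  pk_t <- amp <- numeric(length(s))
  for (k in seq_along(s)) {
    i0 <- as.integer(s[k] * ts$fs) + 1L
    i1 <- min(length(env), as.integer(e[k] * ts$fs) + 1L)
    j <- which.max(env[i0:i1])
    pk_t[k] <- (i0 + j - 2L) / ts$fs
    amp[k] <- env[i0 + j - 1L]
  }
  if (isTRUE(params$theta_guard) && length(s)) {
    gb <- params$guard_band
    env_th <- moving_average(
      hilbert_envelope(bandpass(ts, band_def("custom", gb[1], gb[2]),
                                order = params$order %||% 8L)$samples),
      params$smooth_s * ts$fs)
    # excess theta over the record median: REM theta is a sustained
    # elevation, whereas slow-wave harmonics set the baseline level
    excess <- env_th - stats::median(env_th)
    pk_i <- pmin(length(env_th), as.integer(round(pk_t * ts$fs)) + 1L)
    keep <- excess[pk_i] <= params$guard_ratio * amp
    s <- s[keep]; e <- e[keep]; pk_t <- pk_t[keep]; amp <- amp[keep]
  }
  event_table(pk_t, s, e, amplitude = amp, channel = ts$label,
              type = "beta_burst")
}

#' Parameters for hypersynchronous-spike detection
#'
#' The default detection band has a 0.1 Hz lower corner: a brief (~0.2 s)
#' monophasic discharge has substantial spectral content below 1 Hz, and a
#' higher corner visibly erodes its peak and width.
#'
#' @param band detection band in Hz (default 0.05-40).
#' @param abs_threshold absolute amplitude threshold in mV.
#' @param z_threshold robust-z alternative; the effective threshold is the
#'   larger of the two. The robust scale is estimated on the `sigma_band`
#'   (default 4-40 Hz) trace, above the slow-wave band, so that ongoing
#'   slow-oscillation amplitude does not inflate it.
#' @param sigma_band reference band for the robust noise scale (Hz).
#' @param dur_bounds accepted event durations `c(lo, hi)` in seconds.
#' @param boundary_frac event boundaries at this fraction of peak amplitude.
#' @param dead_time minimal separation between event peaks (s).
#' @param smooth_s smoothing applied before boundary placement (s).
#' @param boundary_run_s minimal below-level run accepted as a boundary (s).
#' @param min_sharpness minimal max-slope-to-amplitude ratio (1/s): a
#'   hypersynchronous discharge rises within tens of milliseconds, whereas
#'   deep down states of comparable amplitude evolve on the slow-wave time
#'   scale and are rejected by this criterion.
#' @export
spike_event_params <- function(band = c(0.05, 40), abs_threshold = 0.3,
                               z_threshold = 6, sigma_band = c(4, 40),
                               dur_bounds = c(0.05, 0.5),
                               boundary_frac = 0.25, dead_time = 0.5,
                               smooth_s = 0.02, boundary_run_s = 0.02,
                               min_sharpness = 20) {
  if (dur_bounds[1] >= dur_bounds[2]) stopf("dur_bounds must be ordered")
  if (boundary_frac <= 0 || boundary_frac >= 1)
    stopf("boundary_frac must lie in (0, 1)")
  list(band = band, abs_threshold = abs_threshold, z_threshold = z_threshold,
       sigma_band = sigma_band, dur_bounds = dur_bounds,
       boundary_frac = boundary_frac, dead_time = dead_time,
       smooth_s = smooth_s, boundary_run_s = boundary_run_s,
       min_sharpness = min_sharpness)
}

#' Detect hypersynchronous spikes (interictal-like events)
#'
#' Candidates are supra-threshold excursions of the band-passed trace
#' (either polarity); the amplitude is the signed peak value, boundaries
#' sit at `boundary_frac` of the peak, events outside the duration bounds
#' are rejected, and a dead time is enforced between peaks.
#'
#' @param ts a [time_series()] of at least 60 s.
#' @param params a [spike_event_params()] list.
#' @return an [event_table()] of type `"hypersync_spike"`.
#' @export
detect_hypersync_spikes <- function(ts, params = spike_event_params()) {
  if (ts_duration(ts) < 60) stopf("need at least 60 s of signal")
  fs <- ts$fs
  bp <- bandpass(ts, as_band(params$band))$samples
  sig <- robust_sigma(bandpass(ts, as_band(params$sigma_band))$samples)
  thr <- max(params$abs_threshold, params$z_threshold * sig)
  sm <- moving_average(bp, params$smooth_s * fs)

  rr <- runs_above(abs(bp) > thr)
  if (!nrow(rr)) return(event_table(channel = ts$label, type = "hypersync_spike"))
  max_half <- as.integer(round(params$dur_bounds[2] * 1.5 * fs))

  out <- list()
  last_pk <- -Inf
  for (k in seq_len(nrow(rr))) {
    i0 <- rr[k, "start"]; i1 <- rr[k, "end"]
    j <- which.max(abs(bp[i0:i1]))
    pk <- i0 + j - 1L
    t_pk <- (pk - 1L) / fs
    if (t_pk - last_pk < params$dead_time) next
    sgn <- sign(bp[pk])
    ss <- sm * sgn
    lo_lim <- max(1L, pk - max_half)
    hi_lim <- min(length(ss), pk + max_half)
    m_run <- max(1L, as.integer(round(params$boundary_run_s * fs)))
    # boundary walk: innermost run of >= boundary_run_s consecutive
    # below-level samples, so brief noise dips do not stop prematurely
    walk <- function(lev) {
      rl <- rle(ss[lo_lim:pk] < lev)
      cum <- cumsum(rl$lengths)
      okl <- rl$values & rl$lengths >= m_run
      rr_ <- rle(ss[pk:hi_lim] < lev)
      cum_r <- cumsum(rr_$lengths)
      okr <- rr_$values & rr_$lengths >= m_run
      if (!any(okl) || !any(okr)) return(NULL)
      c(lo_lim + cum[max(which(okl))],
        pk + (cum_r[min(which(okr))] - rr_$lengths[min(which(okr))]) - 1L)
    }
    # amplitude and level are taken relative to the local flank baseline
    # (high-pass filtering re-centers the trace, so the pre/post-event
    # level, not zero, is the physiological reference); one refinement pass
    amp0 <- ss[pk]
    b <- walk(amp0 * params$boundary_frac)
    if (is.null(b)) next
    # pre-event flank only: the discharge rises fast but decays slowly, so
    # the post-event tail would contaminate a right-hand flank
    w_fl <- max(2L, as.integer(round(0.08 * fs)))
    off <- as.integer(round(0.02 * fs))
    flank <- ss[max(1L, b[1L] - off - w_fl):max(1L, b[1L] - off)]
    base <- stats::median(flank)
    amp_c <- amp0 - base
    b <- walk(base + amp_c * params$boundary_frac)
    if (is.null(b)) next
    if (amp_c < thr) next    # slow-baseline excursion, not a discharge
    sharp <- max(abs(diff(ss[b[1L]:b[2L]]))) * fs / amp_c
    if (sharp < params$min_sharpness) next
    dur <- (b[2L] - b[1L]) / fs
    if (dur < params$dur_bounds[1] || dur > params$dur_bounds[2]) next
    last_pk <- t_pk
    out[[length(out) + 1L]] <- c(t_pk, (b[1L] - 1L) / fs, (b[2L] - 1L) / fs,
                                 sgn * amp_c)
  }
  if (!length(out)) return(event_table(channel = ts$label, type = "hypersync_spike"))
  m <- do.call(rbind, out)
  event_table(m[, 1L], m[, 2L], m[, 3L], amplitude = m[, 4L],
              channel = ts$label, type = "hypersync_spike")
}

#' Phase locking of events to (contralateral) up states
#'
#' Fraction of event peaks inside the up-state set, with the chance level
#' given by the up-state duty cycle of the analysis window.
#'
#' @param ev an [event_table()] (at least 5 events for a defined result).
#' @param contralateral_us [interval_set()] of up states on the opposite
#'   hemisphere.
#' @param window analysis window `c(t_lo, t_hi)` in seconds.
#' @return list with `fraction`, `chance`, `n`, and `insufficient` flag.
#' @export
phase_locking <- function(ev, contralateral_us, window) {
  chance <- duty_cycle(contralateral_us, window[1], window[2])
  if (nrow(ev) < 5L) {
    return(list(fraction = NA_real_, chance = chance, n = nrow(ev),
                insufficient = TRUE))
  }
  r <- events_in_intervals(ev, contralateral_us)
  list(fraction = r$fraction, chance = chance, n = r$n, insufficient = FALSE)
}

#' Cohort-level phase-locking test
#'
#' One-sample t test of per-animal in-up-state fractions against their
#' chance levels (two-sided, on the per-animal differences).
#'
#' @param fractions per-animal fractions.
#' @param chances per-animal chance levels (up-state duty cycles).
#' @return list with `mean_fraction`, `mean_chance`, `statistic`,
#'   `p_value`, `n`.
#' @export
phase_locking_test <- function(fractions, chances) {
  ok <- is.finite(fractions) & is.finite(chances)
  x <- fractions[ok] - chances[ok]
  if (length(x) < 3L) stopf("phase_locking_test needs >= 3 animals")
  ht <- stats::t.test(x, mu = 0)
  list(mean_fraction = mean(fractions[ok]), mean_chance = mean(chances[ok]),
       statistic = unname(ht$statistic), p_value = ht$p.value, n = length(x))
}

#' Classify the hyperexcitability phenotype from event rates
#'
#' Strict thresholds: frequent bursts means more than 3 beta bursts per
#' hour; hyperexcitable means more than 5 per hour.
#'
#' @param beta_rate beta bursts per hour.
#' @param hypersync_rate hypersynchronous spikes per hour.
#' @return object of class `phenotype_call`.
#' @export
classify_phenotype <- function(beta_rate, hypersync_rate = 0) {
  if (beta_rate < 0 || hypersync_rate < 0) stopf("rates must be >= 0")
  structure(list(beta_rate = beta_rate, hypersync_rate = hypersync_rate,
                 frequent_bursts = beta_rate > 3,
                 hyperexcitable = beta_rate > 5),
            class = "phenotype_call")
}

#' @export
print.phenotype_call <- function(x, ...) {
  cat(sprintf(
    "<phenotype_call> beta %.2f/h, hypersync %.2f/h: frequent_bursts=%s, hyperexcitable=%s\n",
    x$beta_rate, x$hypersync_rate, x$frequent_bursts, x$hyperexcitable))
  invisible(x)
}
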