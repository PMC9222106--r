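# Up/down-state segmentation of LFP and slow-wave metrics.
#
# Segmentation runs on the z-scored delta-band (0.5-4 Hz) signal with
# hysteresis thresholds: an up state opens at the upward crossing of th_hi
# and closes at the downward crossing of th_lo. Electrode depth and
# referencing can flip LFP sign, so polarity is auto-selected by gamma-band
# power: up states carry high-frequency activity, so the polarity whose
# candidate up states hold more 40-100 Hz power wins.

#' Parameters for up/down-state detection
#' @param th_hi,th_lo hysteresis thresholds in z-units of the state-band
#'   signal (defaults +0.3 / -0.3).
#' @param min_us,min_ds minimal up-/down-state durations in seconds.
#' @param merge_gap up states separated by less than this are merged (s).
#' @param polarity `"auto"`, `"positive_up"` or `"negative_up"`.
#' @param state_band band used for boundary placement, in Hz. The default
#'   0.1-4 Hz keeps the sub-delta content that encodes the up/down duty
#'   asymmetry: a 0.5 Hz high-pass symmetrizes the oscillation around zero
#'   and biases the detected duty cycle towards 0.5.
#' @export
updown_params <- function(th_hi = 0.3, th_lo = -0.3, min_us = 0.15,
                          min_ds = 0.05, merge_gap = 0.05,
                          polarity = c("auto", "positive_up", "negative_up"),
                          state_band = c(0.1, 4)) {
  polarity <- match.arg(polarity)
  if (th_lo >= th_hi) stopf("need th_lo < th_hi")
  list(th_hi = th_hi, th_lo = th_lo, min_us = min_us, min_ds = min_ds,
       merge_gap = merge_gap, polarity = polarity, state_band = state_band)
}

segment_hysteresis <- function(z, fs, th_hi, th_lo, min_us, min_ds, merge_gap) {
  up <- which(diff(z >= th_hi) == 1L) + 1L
  dn <- which(diff(z <= th_lo) == 1L) + 1L
  if (!length(up)) return(interval_set(label = "US"))
  # pair each upward crossing with the next downward crossing; upward
  # crossings inside an already-open up state are absorbed
  nxt <- findInterval(up, dn) + 1L
  ends <- ifelse(nxt <= length(dn), dn[nxt], length(z))
  keep <- !duplicated(ends)
  starts <- up[keep]; ends <- ends[keep]
  # refine each boundary to the preceding midpoint (zero) crossing, then to
  # the inflection point (extremum of the smoothed derivative) nearby: the
  # hysteresis levels only confirm a transition and fire late on the
  # smoothed ramp, whereas the maximum-slope point of a zero-phase-filtered
  # ramp sits at the true transition regardless of level asymmetries
  zc_up <- which(diff(z >= 0) == 1L) + 1L
  zc_dn <- which(diff(z < 0) == 1L) + 1L
  if (length(zc_up)) {
    j <- findInterval(starts, zc_up)
    starts <- ifelse(j > 0L, zc_up[pmax(j, 1L)], starts)
  }
  if (length(zc_dn)) {
    j <- findInterval(ends, zc_dn)
    ends_ref <- ifelse(j > 0L, zc_dn[pmax(j, 1L)], ends)
    ends <- ifelse(ends_ref > starts, ends_ref, ends)
  }
  dz <- moving_average(c(0, diff(z)) * fs, max(1L, as.integer(0.03 * fs)))
  w_inf <- max(2L, as.integer(round(0.12 * fs)))
  refine_inf <- function(i, sgn) {
    w <- max(1L, i - w_inf):min(length(dz), i + w_inf)
    w[which.max(sgn * dz[w])]
  }
  starts <- vapply(starts, refine_inf, integer(1), sgn = 1)
  ends <- vapply(ends, refine_inf, integer(1), sgn = -1)
  ok0 <- ends > starts
  starts <- starts[ok0]; ends <- ends[ok0]
  s <- (starts - 1L) / fs
  e <- (ends - 1L) / fs
  m <- merge_gaps(s, e, max(merge_gap, min_ds))
  ok <- (m$end - m$start) >= min_us
  interval_set(m$start[ok], m$end[ok], label = "US")
}

#' Detect up and down states from an LFP trace
#'
#' @param ts a [time_series()] of at least 60 s of LFP.
#' @param params an [updown_params()] list.
#' @return object of class `state_segmentation`: list with `us`, `ds`
#'   ([interval_set()]s), `polarity`, `thresholds`, `channel`, `fs`.
#' @export
detect_updown <- function(ts, params = updown_params()) {
  if (ts_duration(ts) < 60) stopf("need at least 60 s of LFP")
  d <- bandpass(ts, as_band(params$state_band))$samples
  if (stats::sd(d) < 1e-9) stopf("no states: flat signal (SD < 1e-9)")
  # normalize by the midpoint and half-spread of the amplitude distribution
  # (10th/90th percentiles): for a bimodal up/down signal this centers the
  # thresholds between the two modes regardless of the duty cycle, which a
  # mean/SD z-score does not
  q <- stats::quantile(d, c(0.1, 0.9), names = FALSE)
  half <- (q[2] - q[1]) / 2
  if (half < 1e-9) stopf("no states: flat signal (SD < 1e-9)")
  z <- (d - (q[1] + q[2]) / 2) / half
  dur <- ts_duration(ts)

  seg_for <- function(pol_sign) {
    segment_hysteresis(pol_sign * z, ts$fs, params$th_hi, params$th_lo,
                       params$min_us, params$min_ds, params$merge_gap)
  }
  polarity <- params$polarity
  if (polarity == "auto") {
    if (ts$fs / 2 > 45) {
      g <- bandpass(ts, band_def("custom", 40, min(100, 0.45 * ts$fs)))$samples
      tt <- ts_times(ts) - ts$t0
      pow_in <- function(iv) {
        inside <- iv_contains(tt, iv)
        if (!any(inside)) return(-Inf)
        mean(g[inside]^2)
      }
      cand_pos <- seg_for(1); cand_neg <- seg_for(-1)
      polarity <- if (pow_in(cand_neg) > pow_in(cand_pos)) "negative_up" else "positive_up"
    } else {
      polarity <- "positive_up"
    }
  }
  us <- seg_for(if (polarity == "positive_up") 1 else -1)
  structure(list(us = us, ds = iv_complement(us, 0, dur, label = "DS"),
                 polarity = polarity,
                 thresholds = c(hi = params$th_hi, lo = params$th_lo),
                 params = params, channel = ts$label, fs = ts$fs,
                 duration = dur),
            class = "state_segmentation")
}

#' @export
print.state_segmentation <- function(x, ...) {
  cat(sprintf(
    "<state_segmentation> '%s': %d USs (%.1f/min, mean %.3f s), polarity %s\n",
    x$channel, nrow(x$us), nrow(x$us) / x$duration * 60,
    if (nrow(x$us)) mean(x$us$end - x$us$start) else NA, x$polarity))
  invisible(x)
}

#' Up-state transition slopes
#'
#' Per up state, segment 1 runs from the US onset to the first local
#' extremum of the delta-filtered trace inside the US (recruitment,
#' DS to US), segment 2 from the last local extremum to the US offset
#' (de-recruitment, US to DS). Slopes are the maximum and mean of
#' `|d(delta signal)/dt|` over each segment, in mV/s. Up states without an
#' interior extremum are flagged and excluded from the summary.
#'
#' @param ts the [time_series()] the segmentation was derived from.
#' @param seg a `state_segmentation`.
#' @return object of class `slope_stats`: data.frame `per_us` plus a
#'   `summary` of per-animal means.
#' @export
us_slopes <- function(ts, seg) {
  d <- bandpass(ts, "delta")$samples
  fs <- ts$fs
  us <- seg$us
  rows <- vector("list", nrow(us))
  for (k in seq_len(nrow(us))) {
    i0 <- max(1L, as.integer(floor(us$start[k] * fs)) + 1L)
    i1 <- min(length(d), as.integer(ceiling(us$end[k] * fs)) + 1L)
    seg_d <- d[i0:i1]
    if (length(seg_d) < 5L) next
    dd <- diff(seg_d)
    flips <- which(dd[-1L] * dd[-length(dd)] < 0) + 1L
    if (!length(flips)) {
      rows[[k]] <- data.frame(us_index = k, slope1_max = NA, slope1_avg = NA,
                              slope2_max = NA, slope2_avg = NA, flagged = TRUE)
      next
    }
    e1 <- flips[1L]; e2 <- flips[length(flips)]
    sl1 <- abs(dd[seq_len(max(e1 - 1L, 1L))]) * fs
    sl2 <- abs(dd[e2:length(dd)]) * fs
    rows[[k]] <- data.frame(us_index = k,
                            slope1_max = max(sl1), slope1_avg = mean(sl1),
                            slope2_max = max(sl2), slope2_avg = mean(sl2),
                            flagged = FALSE)
  }
  per_us <- do.call(rbind, rows)
  ok <- per_us[!per_us$flagged, , drop = FALSE]
  structure(list(
    per_us = per_us,
    summary = c(slope1_max = mean(ok$slope1_max), slope1_avg = mean(ok$slope1_avg),
                slope2_max = mean(ok$slope2_max), slope2_avg = mean(ok$slope2_avg)),
    n_flagged = sum(per_us$flagged)),
    class = "slope_stats")
}

#' Paired slow-wave metrics for a dual-hemisphere recording
#'
#' Emits one paired row per metric: delta RMS, the four transition-slope
#' summaries, up-state rate per minute and mean up-state duration, for the
#' injected versus the control hemisphere.
#'
#' @param rec a [recording()] with hemisphere labels `"injected"` and
#'   `"control_hemisphere"`.
#' @param segs named list of `state_segmentation`s (one per channel label);
#'   computed with default parameters when omitted.
#' @return a [paired_table()] (paired form). With a hemisphere missing, an
#'   unpaired table is returned with a warning.
#' @export
swa_metrics <- function(rec, segs = NULL) {
  lab_inj <- names(rec$hemisphere_map)[rec$hemisphere_map == "injected"][1]
  lab_ctl <- names(rec$hemisphere_map)[rec$hemisphere_map == "control_hemisphere"][1]

  metrics_for <- function(lab) {
    ts <- rec$channels[[lab]]
    seg <- if (!is.null(segs) && lab %in% names(segs)) segs[[lab]] else detect_updown(ts)
    sl <- us_slopes(ts, seg)
    c(delta_rms = band_rms(ts, "delta"),
      sl$summary,
      us_rate_per_min = nrow(seg$us) / seg$duration * 60,
      us_mean_duration = if (nrow(seg$us)) mean(seg$us$end - seg$us$start) else NA_real_)
  }

  if (is.na(lab_inj) || is.na(lab_ctl) ||
      is.null(rec$channels[[lab_inj]]) || is.null(rec$channels[[lab_ctl]])) {
    warnf("recording '%s': missing hemisphere channel, emitting unpaired metrics",
          rec$animal_id)
    lab <- if (!is.na(lab_inj) && !is.null(rec$channels[[lab_inj]])) lab_inj else lab_ctl
    m <- metrics_for(lab)
    return(paired_table(rep(rec$animal_id, length(m)), names(m),
                        group = rep(rec$group, length(m)), value = m))
  }
  mi <- metrics_for(lab_inj)
  mc <- metrics_for(lab_ctl)
  paired_table(rep(rec$animal_id, length(mi)), names(mi),
               value_injected = mi, value_control = mc)
}
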