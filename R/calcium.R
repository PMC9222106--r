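# Calcium-imaging analysis: dF/F, transient detection, per-neuron
# frequency statistics with the hyperactive criterion (> 4 transients per
# minute, strict), population dispersion, field-of-view activity, and
# synchronization of transients to up states.

#' Baseline-normalized fluorescence (dF/F)
#'
#' F0 is a running percentile (default 10th over a 30 s window, evaluated
#' on a coarse grid and interpolated); dF/F = (F - F0) / F0 with F0 floored
#' at a small positive constant. A low percentile keeps the baseline from
#' absorbing the sustained dF/F pedestal of very active neurons.
#'
#' @param tr a [time_series()] of raw fluorescence (or a numeric vector
#'   with `fs` supplied).
#' @param baseline_s baseline window in seconds (default 30).
#' @param percentile baseline percentile in `[0, 1]` (default 0.1).
#' @param fs sampling rate when `tr` is a plain vector.
#' @return a [time_series()] of dF/F (unitless).
#' @export
compute_dff <- function(tr, baseline_s = 30, percentile = 0.1, fs = NULL) {
  if (!inherits(tr, "time_series")) tr <- time_series(tr, fs = fs, units = "dF/F")
  x <- tr$samples
  n <- length(x)
  if (n < 2 * baseline_s * tr$fs) stopf("trace must be >= 2x the baseline window")
  grid_step <- max(1L, as.integer(round(tr$fs)))       # one support point per second
  half <- as.integer(round(baseline_s * tr$fs / 2))
  idx <- seq(1L, n, by = grid_step)
  q <- vapply(idx, function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    stats::quantile(x[lo:hi], percentile, names = FALSE)
  }, numeric(1))
  f0 <- stats::approx(idx, q, xout = seq_len(n), rule = 2)$y
  floor_c <- max(1e-6, 0.01 * stats::median(abs(x)))
  f0 <- pmax(f0, floor_c)
  if (all(f0 <= floor_c)) stopf("nonpositive baseline after flooring")
  out <- tr
  out$samples <- (x - f0) / f0
  out$units <- "dF/F"
  out
}

#' Parameters for calcium-transient detection
#' @param k onset threshold in robust noise units (default 3).
#' @param sustain_s minimal time above threshold to accept an onset (s).
#' @param end_k event end when dF/F decays below `end_k` noise units ...
#' @param end_frac ... or below this fraction of the event peak, whichever
#'   is larger; detection is refractory until then. A purely noise-level
#'   end criterion holds the detector refractory for the full indicator
#'   decay and merges closely spaced transients, halving high rates.
#' @export
transient_params <- function(k = 3, sustain_s = 0.2, end_k = 1,
                             end_frac = 0.5) {
  list(k = k, sustain_s = sustain_s, end_k = end_k, end_frac = end_frac)
}

#' Detect calcium transients on a dF/F trace
#'
#' @param dff a [time_series()] of dF/F, at least 60 s.
#' @param params a [transient_params()] list.
#' @return list with `times` (onset times, s), `amplitudes` (peak dF/F),
#'   `frequency_hz`, `frequency_per_min`, `active`, `hyperactive`
#'   (strict > 4/min), `sigma`.
#' @export
detect_transients <- function(dff, params = transient_params()) {
  if (ts_duration(dff) < 60) stopf("need >= 60 s to estimate the noise scale")
  x <- dff$samples
  x <- x - stats::median(x)      # thresholds are relative to the central level
  fs <- dff$fs
  # noise scale from the first difference: transient kernels vary slowly
  # frame-to-frame, so differencing isolates the white measurement noise
  # even on traces with a heavy signal load
  sig <- robust_sigma(diff(x)) / sqrt(2)
  n_sus <- max(1L, as.integer(round(params$sustain_s * fs)))
  onsets <- integer(0); amps <- numeric(0)
  n <- length(x)
  thr_on <- params$k * sig
  w_max <- as.integer(round(10 * fs))
  g <- 1L
  while (g <= n - n_sus) {
    # onset: exceed k*sigma AND rise k*sigma above the running minimum
    # since the last event end (hysteresis: the decaying tail of the
    # previous transient must not re-trigger on noise)
    w <- x[g:n]
    rise <- pmax(thr_on, cummin(w) + thr_on)
    cand <- which(w > rise)
    i0 <- NA_integer_
    for (c0 in cand) {
      j <- g + c0 - 1L
      if (j + n_sus - 1L > n) break
      # the sustain requirement holds at the local rise level: a noise
      # blip above the decaying tail of the previous event is not
      # followed by a sustained elevation above that level
      if (all(x[j:(j + n_sus - 1L)] > rise[c0])) { i0 <- j; break }
    }
    if (is.na(i0)) break
    # end: decay below end_k * sigma, or below end_frac of the event peak,
    # whichever is reached first; refractory until then
    hi_lim <- min(n, i0 + w_max)
    w2 <- x[i0:hi_lim]
    pk <- cummax(w2)
    lev <- pmax(params$end_k * sig, params$end_frac * pk)
    after <- which(w2 < lev & seq_along(w2) > n_sus)[1L]
    iend <- if (is.na(after)) hi_lim else i0 + after - 1L
    # refine the onset back to the start of the rise (last sample below
    # end_k * sigma within half a second), so event times mark the kernel
    # onset rather than the later threshold crossing
    back <- as.integer(round(0.5 * fs))
    j0 <- max(1L, i0 - back)
    below0 <- which(x[j0:i0] < params$end_k * sig)
    i_on <- if (length(below0)) j0 + below0[length(below0)] - 1L else i0
    onsets <- c(onsets, i_on)
    amps <- c(amps, max(x[i0:iend]))
    g <- iend + 1L
  }
  dur <- ts_duration(dff)
  f_hz <- length(onsets) / dur
  list(times = (onsets - 1L) / fs + dff$t0, amplitudes = amps,
       frequency_hz = f_hz, frequency_per_min = f_hz * 60,
       active = length(onsets) >= 1L, hyperactive = f_hz * 60 > 4,
       sigma = sig)
}

#' Score every neuron of a trace set
#'
#' @param nts a `neuron_trace_set` (see [generate_calcium()] /
#'   [read_roi_csv()]).
#' @param params a [transient_params()] list.
#' @param baseline_s,percentile dF/F baseline parameters.
#' @return a `transient_table` data.frame: one row per neuron with
#'   `roi_id`, `genotype`, `n_events`, `frequency_hz`, `frequency_per_min`,
#'   `active`, `hyperactive`, plus the per-neuron event times as the
#'   `times` attribute.
#' @export
score_transients <- function(nts, params = transient_params(),
                             baseline_s = 30, percentile = 0.1) {
  n <- ncol(nts$F)
  times <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    dff <- compute_dff(time_series(nts$F[, i], fs = nts$fs, units = "au"),
                       baseline_s, percentile)
    det <- detect_transients(dff, params)
    times[[i]] <- det$times
    rows[[i]] <- data.frame(roi_id = nts$roi_ids[i], genotype = nts$genotype[i],
                            n_events = length(det$times),
                            frequency_hz = det$frequency_hz,
                            frequency_per_min = det$frequency_per_min,
                            active = det$active, hyperactive = det$hyperactive,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "times") <- times
  attr(out, "duration") <- nts$duration
  class(out) <- c("transient_table", "data.frame")
  out
}

#' Population statistics of calcium-transient frequencies
#'
#' Median frequency and variance are computed over active neurons
#' (mirroring per-active-neuron reporting); the hyperactive fraction uses
#' all analyzed neurons with the strict > 4/min criterion. With two
#' conditions, dispersion is compared with Bartlett's test on the
#' per-neuron frequencies.
#'
#' @param ... named `transient_table`s, one per condition (at least one;
#'   two for the dispersion test).
#' @param min_active minimal number of active neurons per condition.
#' @return list with per-condition `median_hz`, `variance`,
#'   `hyperactive_pct`, `n`, `n_active`, and `bartlett` (when two
#'   conditions are given).
#' @export
population_stats <- function(..., min_active = 20L) {
  tabs <- list(...)
  if (is.null(names(tabs)) || any(names(tabs) == ""))
    names(tabs) <- paste0("condition", seq_along(tabs))
  per <- lapply(tabs, function(tt) {
    act <- tt[tt$active, , drop = FALSE]
    if (nrow(act) < min_active)
      stopf("need >= %d active neurons per condition, got %d", min_active, nrow(act))
    list(median_hz = stats::median(act$frequency_hz),
         variance = stats::var(act$frequency_hz),
         hyperactive_pct = 100 * mean(tt$hyperactive),
         n = nrow(tt), n_active = nrow(act))
  })
  out <- list(conditions = per)
  if (length(tabs) == 2L) {
    v <- unlist(lapply(tabs, function(tt) tt$frequency_hz[tt$active]))
    g <- rep(names(tabs), vapply(tabs, function(tt) sum(tt$active), integer(1)))
    bt <- stats::bartlett.test(v, factor(g))
    out$bartlett <- list(statistic = unname(bt$statistic), p_value = bt$p.value)
  }
  out
}

#' Field-of-view activity trace
#'
#' Per frame, the count of ROIs (or pixels, for a 3D stack array) whose
#' dF/F exceeds `k` robust noise units, optionally smoothed.
#'
#' @param x a `neuron_trace_set`, a frames-x-ROIs dF/F matrix, or a 3D
#'   array `[frame, y, x]`.
#' @param fs frame rate (taken from the trace set when available).
#' @param k threshold in robust noise units (default 3).
#' @param smooth_s smoothing window in seconds (default 0.2).
#' @return object of class `fov_activity`: list with `counts`, `fs`.
#' @export
fov_activity <- function(x, fs = NULL, k = 3, smooth_s = 0.2) {
  if (inherits(x, "neuron_trace_set")) {
    fs <- x$fs
    m <- apply(x$F, 2L, function(col) {
      dff <- compute_dff(time_series(col, fs = fs, units = "au"))
      dff$samples
    })
  } else if (is.array(x) && length(dim(x)) == 3L) {
    m <- matrix(x, nrow = dim(x)[1L])
  } else if (is.matrix(x)) {
    m <- x
  } else stopf("empty or unsupported input")
  if (is.null(fs)) stopf("fs required")
  if (!nrow(m)) stopf("empty stack")
  sig <- apply(m, 2L, robust_sigma)
  thr <- ifelse(sig > 0, k * sig, Inf)
  counts <- rowSums(sweep(m, 2L, thr, ">"))
  counts <- moving_average(counts, smooth_s * fs)
  structure(list(counts = counts, fs = fs, k = k), class = "fov_activity")
}

#' Percentage of calcium transients occurring within up states
#'
#' Pooled over all neurons of an imaging field (per-neuron percentages are
#' also returned).
#'
#' @param tt a `transient_table` (from [score_transients()]).
#' @param seg a `state_segmentation` (or a list with an `us`
#'   [interval_set()]), aligned to the imaging clock.
#' @param offset_s constant clock offset added to transient times (s).
#' @return list with `percent` (pooled), `chance` (duty cycle x 100),
#'   `per_neuron`, `n`, `undefined`.
#' @export
transients_in_us <- function(tt, seg, offset_s = 0) {
  us <- if (inherits(seg, "state_segmentation")) seg$us else seg$us
  dur <- if (!is.null(seg$duration)) seg$duration else attr(tt, "duration")
  chance <- 100 * duty_cycle(us, 0, dur)
  times <- attr(tt, "times")
  all_t <- unlist(times) + offset_s
  if (!length(all_t)) {
    return(list(percent = NA_real_, chance = chance, per_neuron = numeric(0),
                n = 0L, undefined = TRUE))
  }
  pooled <- 100 * mean(iv_contains(all_t, us))
  per_neuron <- vapply(times, function(tv) {
    if (!length(tv)) return(NA_real_)
    100 * mean(iv_contains(tv + offset_s, us))
  }, numeric(1))
  list(percent = pooled, chance = chance, per_neuron = per_neuron,
       n = length(all_t), undefined = FALSE)
}
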