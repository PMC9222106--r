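# Zero-phase band filtering and band RMS.
#
# Filtering is done in the frequency domain by applying the magnitude
# response of an order-n Butterworth filter (-3 dB corners) with zero
# phase: a real, symmetric transfer function gives exactly no phase
# distortion, which the up-state slope metrics require, while keeping the
# standard -3 dB equivalent noise bandwidth of a single Butterworth pass.
# Signals are reflect-padded to suppress circular edge effects.

#' Frequency band definition
#'
#' Presets follow the bands used for cortical LFP analysis:
#' delta = 0.5-4 Hz, beta = 9-25 Hz, gamma = 40-100 Hz.
#'
#' @param name `"delta"`, `"beta"`, `"gamma"` or `"custom"`.
#' @param f_lo,f_hi band edges in Hz (required for `"custom"`).
#' @return object of class `band_definition`.
#' @export
band_def <- function(name = c("delta", "beta", "gamma", "custom"),
                     f_lo = NULL, f_hi = NULL) {
  name <- match.arg(name)
  preset <- switch(name,
    delta = c(0.5, 4), beta = c(9, 25), gamma = c(40, 100), custom = NULL)
  if (!is.null(preset)) { f_lo <- f_lo %||% preset[1]; f_hi <- f_hi %||% preset[2] }
  if (is.null(f_lo) || is.null(f_hi)) stopf("custom bands need f_lo and f_hi")
  if (!(f_lo > 0 && f_lo < f_hi)) stopf("need 0 < f_lo < f_hi")
  structure(list(name = name, f_lo = f_lo, f_hi = f_hi),
            class = "band_definition")
}

as_band <- function(band) {
  if (inherits(band, "band_definition")) return(band)
  if (is.character(band)) return(band_def(band))
  if (is.numeric(band) && length(band) == 2L)
    return(band_def("custom", band[1], band[2]))
  stopf("cannot interpret band specification")
}

# power response of an order-`ord` Butterworth band-pass
butter_fb_response <- function(f, f_lo, f_hi, ord = 4L) {
  lo <- 1 / (1 + (f / f_hi)^(2 * ord))
  hi <- ifelse(f <= 0, 0, 1 / (1 + (f_lo / f)^(2 * ord)))
  lo * hi
}

# amplitude response (|H|, -3 dB at the corners)
butter_mag_response <- function(f, f_lo, f_hi, ord = 4L) {
  sqrt(butter_fb_response(f, f_lo, f_hi, ord))
}

# apply a real frequency response H(f) with reflect padding
fft_filter <- function(x, fs, resp_fun, pad_s = NULL) {
  n <- length(x)
  pad <- if (is.null(pad_s)) 0L else min(n - 1L, as.integer(round(pad_s * fs)))
  xp <- if (pad > 0L) c(rev(x[seq_len(pad)]), x, rev(x[(n - pad + 1L):n])) else x
  np <- stats::nextn(length(xp), c(2, 3, 5))
  if (np > length(xp)) xp <- c(xp, rev(xp)[seq_len(np - length(xp))])
  k <- 0:(np - 1L)
  freq <- pmin(k, np - k) * fs / np
  y <- Re(stats::fft(stats::fft(xp) * resp_fun(freq), inverse = TRUE)) / np
  y[(pad + 1L):(pad + n)]
}

#' Zero-phase band-pass filter
#'
#' @param ts a [time_series()].
#' @param band a [band_def()], a preset name, or a numeric `c(f_lo, f_hi)`.
#' @param order Butterworth order applied forward-backward (default 4).
#' @return a [time_series()] of equal length.
#' @export
bandpass <- function(ts, band, order = 4L) {
  band <- as_band(band)
  if (band$f_hi >= ts$fs / 2)
    stopf("band (%g, %g) Hz outside Nyquist range for fs = %g Hz",
          band$f_lo, band$f_hi, ts$fs)
  y <- fft_filter(ts$samples, ts$fs,
                  function(f) butter_mag_response(f, band$f_lo, band$f_hi, order),
                  pad_s = 3 / band$f_lo)
  out <- ts
  out$samples <- y
  out
}

#' Zero-phase low/high-pass helpers
#' @noRd
highpass <- function(ts, f_lo, order = 4L) {
  if (f_lo >= ts$fs / 2) stopf("high-pass corner above Nyquist")
  y <- fft_filter(ts$samples, ts$fs,
                  function(f) ifelse(f <= 0, 0, sqrt(1 / (1 + (f_lo / f)^(2 * order)))),
                  pad_s = 3 / f_lo)
  out <- ts; out$samples <- y; out
}

#' Band RMS of a signal
#'
#' Root mean square of the band-passed signal, the standard quantification
#' of slow-wave strength when applied to the delta (0.5-4 Hz) band.
#'
#' @param ts a [time_series()].
#' @param band band specification, see [bandpass()].
#' @param window optional `c(t_lo, t_hi)` restricting the RMS window
#'   (seconds, relative to `t0`), or an [interval_set()] mask.
#' @return RMS in the units of the input (mV).
#' @export
band_rms <- function(ts, band, window = NULL) {
  band <- as_band(band)
  if (ts_duration(ts) < 10 / band$f_lo)
    stopf("input too short: need >= %g s for f_lo = %g Hz",
          10 / band$f_lo, band$f_lo)
  y <- bandpass(ts, band)$samples
  if (!is.null(window)) {
    tt <- ts_times(ts)
    keep <- if (inherits(window, "interval_set")) iv_contains(tt, window)
            else tt >= window[1] & tt < window[2]
    y <- y[keep]
    if (!length(y)) stopf("empty RMS window")
  }
  sqrt(mean(y^2))
}
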