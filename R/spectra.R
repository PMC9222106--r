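# Welch power spectra, interhemispheric cross spectra, and the
# power-spectrum exponent fit used as an excitation:inhibition proxy.
# A flatter spectrum below 50 Hz indicates relatively more excitation; a
# steeper one relatively more inhibition.

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))

welch_segments <- function(n, L, hop) {
  if (L > n) return(integer(0))
  seq(1L, n - L + 1L, by = max(1L, hop))
}

#' Welch power spectral density
#'
#' One-sided density with Hann taper and per-segment mean removal. With the
#' default 4 s segments the 0.5 Hz lower edge of the delta band is resolved.
#' Satisfies Parseval: `sum(power) * df` approximates the signal variance.
#'
#' @param ts a [time_series()].
#' @param segment_s segment length in seconds (default 4; at least 64
#'   samples).
#' @param overlap overlap fraction in `[0, 1)` (default 0.5).
#' @return object of class `welch_spectrum`: list with `freq` (Hz), `power`
#'   (units^2/Hz), `segment_s`, `overlap`, `n_segments`, `fs`.
#' @export
welch_psd <- function(ts, segment_s = 4, overlap = 0.5) {
  fs <- ts$fs
  L <- as.integer(round(segment_s * fs))
  if (L < 64L) stopf("segment too short: segment_s * fs must be >= 64 samples")
  n <- length(ts$samples)
  if (L > n) stopf("segment longer than the record")
  hop <- as.integer(round(L * (1 - overlap)))
  starts <- welch_segments(n, L, hop)
  w <- hann_window(L)
  U <- sum(w^2)
  nf <- L %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    d <- ts$samples[s:(s + L - 1L)]
    d <- (d - mean(d)) * w
    X <- stats::fft(d)[seq_len(nf)]
    acc <- acc + (Mod(X)^2) / (fs * U)
  }
  p <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist when L even)
  dbl <- rep(2, nf); dbl[1L] <- 1
  if (L %% 2L == 0L) dbl[nf] <- 1
  structure(list(freq = (0:(nf - 1L)) * fs / L, power = p * dbl,
                 segment_s = segment_s, overlap = overlap,
                 n_segments = length(starts), fs = fs),
            class = "welch_spectrum")
}

#' @export
print.welch_spectrum <- function(x, ...) {
  cat(sprintf("<welch_spectrum> %d bins up to %.1f Hz, %d segments of %g s\n",
              length(x$freq), max(x$freq), x$n_segments, x$segment_s))
  invisible(x)
}

#' Magnitude of the Welch cross spectral density restricted to windows
#'
#' Used to compare interhemispheric coupling during epileptiform bursts
#' versus ordinary slow-wave activity: segments are taken only from the
#' supplied windows, the complex cross density is averaged coherently and
#' its magnitude returned (incoherent channels average towards zero).
#'
#' @param a,b [time_series()] objects with equal sampling rate.
#' @param windows an [interval_set()] of analysis windows (seconds,
#'   same clock as the signals).
#' @param segment_s,overlap Welch parameters, as in [welch_psd()].
#' @return a `welch_spectrum` whose `power` is the cross-density magnitude.
#' @export
cross_spectrum <- function(a, b, windows, segment_s = 1, overlap = 0.5) {
  if (a$fs != b$fs) stopf("cross_spectrum needs equal sampling rates")
  if (!nrow(windows)) stopf("windows must be nonempty")
  fs <- a$fs
  L <- as.integer(round(segment_s * fs))
  hop <- as.integer(round(L * (1 - overlap)))
  w <- hann_window(L)
  U <- sum(w^2)
  nf <- L %/% 2L + 1L
  acc <- complex(real = numeric(nf), imaginary = numeric(nf))
  n_seg <- 0L
  n <- min(length(a$samples), length(b$samples))
  for (k in seq_len(nrow(windows))) {
    i0 <- max(1L, as.integer(floor((windows$start[k] - a$t0) * fs)) + 1L)
    i1 <- min(n, as.integer(floor((windows$end[k] - a$t0) * fs)))
    len <- i1 - i0 + 1L
    if (len < L) next
    for (s in welch_segments(len, L, hop)) {
      ia <- (i0 + s - 1L):(i0 + s + L - 2L)
      da <- a$samples[ia]; db <- b$samples[ia]
      Xa <- stats::fft((da - mean(da)) * w)[seq_len(nf)]
      Xb <- stats::fft((db - mean(db)) * w)[seq_len(nf)]
      acc <- acc + Conj(Xa) * Xb / (fs * U)
      n_seg <- n_seg + 1L
    }
  }
  if (n_seg == 0L) stopf("windows shorter than one segment (%g s)", segment_s)
  dbl <- rep(2, nf); dbl[1L] <- 1
  if (L %% 2L == 0L) dbl[nf] <- 1
  structure(list(freq = (0:(nf - 1L)) * fs / L,
                 power = Mod(acc / n_seg) * dbl,
                 segment_s = segment_s, overlap = overlap,
                 n_segments = n_seg, fs = fs),
            class = "welch_spectrum")
}

#' Fit the decay exponent of an LFP power spectrum
#'
#' Least-squares fit of `log10(power)` against frequency
#' (`semilog_exponential`, the exponential-decay model: power ~ exp(-chi f),
#' `exponent` in 1/Hz) or against `log10(frequency)`
#' (`loglog_powerlaw`, power ~ f^-chi, dimensionless `exponent`), over
#' `[f_lo, f_hi]` with a configurable exclusion notch around the 50 Hz line
#' frequency. Positive exponents mean decaying spectra; a smaller exponent
#' (flatter spectrum) indicates a higher excitation:inhibition ratio.
#'
#' @param spec a `welch_spectrum`.
#' @param f_lo,f_hi fit band in Hz (default 1-50).
#' @param model `"semilog_exponential"` (default) or `"loglog_powerlaw"`.
#' @param notch numeric `c(lo, hi)` band to exclude (default `c(45, 55)`),
#'   or `NULL`.
#' @return object of class `exponent_fit`: list with `exponent`,
#'   `intercept`, `band`, `model`, `r_squared`, `n_bins`.
#' @export
fit_spectral_exponent <- function(spec, f_lo = 1, f_hi = 50,
                                  model = c("semilog_exponential",
                                            "loglog_powerlaw"),
                                  notch = c(45, 55)) {
  model <- match.arg(model)
  keep <- spec$freq >= f_lo & spec$freq <= f_hi
  if (!is.null(notch)) keep <- keep & !(spec$freq >= notch[1] & spec$freq <= notch[2])
  f <- spec$freq[keep]; p <- spec$power[keep]
  if (length(f) < 8L) stopf("need >= 8 frequency bins within the fit band")
  if (any(p <= 0))
    stopf("nonpositive power in fit band at bins: %s",
          paste(utils::head(round(f[p <= 0], 2), 5), collapse = ", "))
  x <- if (model == "semilog_exponential") f else log10(f)
  fit <- stats::lm(log10(p) ~ x)
  slope <- unname(stats::coef(fit)[2L])
  expo <- if (model == "semilog_exponential") -slope * log(10) else -slope
  structure(list(exponent = expo,
                 intercept = unname(stats::coef(fit)[1L]),
                 band = c(f_lo, f_hi), model = model,
                 r_squared = summary(fit)$r.squared,
                 n_bins = length(f),
                 exponent_se = summary(fit)$coefficients[2L, 2L] *
                   (if (model == "semilog_exponential") log(10) else 1)),
            class = "exponent_fit")
}

#' @export
print.exponent_fit <- function(x, ...) {
  cat(sprintf("<exponent_fit> %s over %g-%g Hz: exponent %.3f (R^2 = %.3f)\n",
              x$model, x$band[1], x$band[2], x$exponent, x$r_squared))
  invisible(x)
}
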