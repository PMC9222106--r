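# Internal helpers shared across modules.

#' Evaluate an expression under a fixed RNG seed, restoring RNG state afterwards
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Moving-average smoothing with edge shrinkage (window in samples)
#' @noRd
moving_average <- function(x, w) {
  w <- max(1L, as.integer(round(w)))
  if (w <= 1L) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  half <- w %/% 2L
  lo <- pmax(0L, seq_len(n) - half - 1L)
  hi <- pmin(n, seq_len(n) + (w - half - 1L))
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

#' Robust noise scale: median absolute deviation / 0.6745 (Gaussian-consistent)
#' @noRd
robust_sigma <- function(x) stats::median(abs(x - stats::median(x))) / 0.6745

#' Running median on a coarse grid (1 s), linearly interpolated
#' @noRd
running_median <- function(x, fs, win_s) {
  n <- length(x)
  step <- max(1L, as.integer(round(fs)))
  half <- as.integer(round(win_s * fs / 2))
  idx <- unique(c(seq(1L, n, by = step), n))
  med <- vapply(idx, function(i) {
    stats::median(x[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
  stats::approx(idx, med, xout = seq_len(n), rule = 2)$y
}
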