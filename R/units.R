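# Multi-unit activity: thresholded extracellular spikes from the >300 Hz
# band of the LFP electrode, without sorting into single neurons.

#' Parameters for multi-unit extraction
#' @param hp_corner high-pass corner in Hz (default 300).
#' @param k threshold in robust noise units; the automatic threshold is
#'   `-k * median(|x|)/0.6745` (classic extracellular practice).
#' @param dead_time minimal inter-spike interval (s).
#' @param bipolar also detect positive-going crossings (default FALSE:
#'   extracellular spikes are negative at the electrode).
#' @export
unit_params <- function(hp_corner = 300, k = 4, dead_time = 0.001,
                        bipolar = FALSE) {
  list(hp_corner = hp_corner, k = k, dead_time = dead_time, bipolar = bipolar)
}

#' Extract multi-unit activity from an LFP trace
#'
#' High-pass filters above 300 Hz, estimates the noise scale as
#' `median(|x|)/0.6745`, and takes negative threshold crossings (with dead
#' time) as spike times placed at the local trough.
#'
#' @param ts a [time_series()] with `fs >= 1000` Hz.
#' @param params a [unit_params()] list.
#' @param exclude optional [interval_set()] of epochs to mask out (e.g.
#'   detected burst intervals).
#' @return object of class `spike_train`: list with sorted `times` (s),
#'   `threshold` (mV), `noise_sigma` (mV), `channel`, `duration`,
#'   `flat` flag.
#' @export
extract_units <- function(ts, params = unit_params(), exclude = NULL) {
  if (ts$fs < 1000)
    stopf("fs = %g Hz too low: the %g Hz high-pass needs fs >= 1000",
          ts$fs, params$hp_corner)
  x <- highpass(ts, params$hp_corner)$samples
  sig <- robust_sigma(x)
  if (sig < 1e-12) {
    return(structure(list(times = numeric(0), threshold = 0, noise_sigma = 0,
                          channel = ts$label, duration = ts_duration(ts),
                          flat = TRUE), class = "spike_train"))
  }
  thr <- -params$k * sig
  hit <- x < thr
  if (params$bipolar) hit <- hit | (x > -thr)
  rr <- runs_above(hit)
  times <- numeric(0)
  if (nrow(rr)) {
    pk <- integer(nrow(rr))
    for (i in seq_len(nrow(rr))) {
      j <- rr[i, "start"]:rr[i, "end"]
      pk[i] <- j[which.max(abs(x[j]))]
    }
    times <- (pk - 1L) / ts$fs
    keep <- c(TRUE, diff(times) >= params$dead_time)
    times <- times[keep]
  }
  if (!is.null(exclude) && length(times)) times <- times[!iv_contains(times, exclude)]
  structure(list(times = times, threshold = thr, noise_sigma = sig,
                 channel = ts$label, duration = ts_duration(ts), flat = FALSE),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> '%s': %d spikes (%.2f Hz), threshold %.4f mV\n",
              x$channel, length(x$times), length(x$times) / x$duration,
              x$threshold))
  invisible(x)
}

#' Mean unit firing rate
#' @param st a `spike_train`.
#' @param duration analyzed duration in seconds (defaults to the train's).
#' @return rate in Hz.
#' @export
unit_rate <- function(st, duration = st$duration) {
  if (!is_number(duration) || duration <= 0) stopf("duration must be > 0")
  length(st$times) / duration
}

#' Percentage of units occurring within up states
#'
#' @param st a `spike_train`.
#' @param seg a `state_segmentation` sharing the train's clock.
#' @return list with `percent` (100 x fraction of spikes inside up states,
#'   `NA` for an empty train), `chance` (up-state duty cycle x 100), `n`,
#'   `undefined`.
#' @export
units_in_us <- function(st, seg) {
  chance <- 100 * duty_cycle(seg$us, 0, seg$duration)
  if (!length(st$times)) {
    return(list(percent = NA_real_, chance = chance, n = 0L, undefined = TRUE))
  }
  inside <- iv_contains(st$times, seg$us)
  list(percent = 100 * mean(inside), chance = chance, n = length(st$times),
       undefined = FALSE)
}
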