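# Core containers: sampled time series and multi-channel recordings.
#
# All times are continuous seconds from recording start; intervals elsewhere
# in the package are half-open [t_start, t_end).

#' Sampled time series
#'
#' Container for one regularly sampled channel (LFP, EEG, EMG or a
#' fluorescence trace).
#'
#' @param samples numeric vector of amplitudes (mV for electrophysiology,
#'   arbitrary units for fluorescence).
#' @param fs sampling rate in Hz (> 0).
#' @param t0 start time in seconds (default 0).
#' @param label channel name.
#' @param units unit string, default `"mV"`.
#' @return An object of class `time_series` with fields `samples`, `fs`,
#'   `t0`, `label`, `units`.
#' @export
time_series <- function(samples, fs, t0 = 0, label = "", units = "mV") {
  samples <- as.numeric(samples)
  if (!is_number(fs) || fs <= 0) stopf("fs must be a positive number, got %s", format(fs))
  if (length(samples) < 2L) stopf("a time series needs at least 2 samples")
  if (anyNA(samples) || any(!is.finite(samples))) stopf("samples must be finite")
  structure(
    list(samples = samples, fs = fs, t0 = t0, label = as.character(label),
         units = as.character(units)),
    class = "time_series"
  )
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf("<time_series> '%s': %d samples @ %g Hz (%.2f s), units %s\n",
              x$label, length(x$samples), x$fs, ts_duration(x), x$units))
  invisible(x)
}

#' Duration of a time series in seconds
#' @param ts a [time_series()].
#' @export
ts_duration <- function(ts) length(ts$samples) / ts$fs

#' Sample times of a time series (seconds)
#' @param ts a [time_series()].
#' @export
ts_times <- function(ts) ts$t0 + (seq_along(ts$samples) - 1) / ts$fs

#' Multi-channel recording
#'
#' Bundles channels sharing a common start time with animal metadata. The
#' hemisphere map assigns each channel to the virally injected hemisphere,
#' the contralateral (internal control) hemisphere, or neither.
#'
#' @param channels named list of [time_series()] objects.
#' @param animal_id animal identifier.
#' @param group one of `"control"`, `"mosaic_pup"`, `"mosaic_P25"`,
#'   `"mosaic_adult"`.
#' @param hemisphere_map named character vector mapping channel labels to
#'   `"injected"`, `"control_hemisphere"` or `"none"`.
#' @return An object of class `recording`.
#' @export
recording <- function(channels, animal_id = "animal", group = "control",
                      hemisphere_map = NULL) {
  if (is.null(names(channels)) || any(names(channels) == ""))
    stopf("channels must be a named list")
  if (anyDuplicated(names(channels))) stopf("channel labels must be unique")
  for (ch in channels) {
    if (!inherits(ch, "time_series")) stopf("all channels must be time_series objects")
  }
  t0s <- vapply(channels, function(ch) ch$t0, numeric(1))
  if (length(unique(t0s)) > 1L) stopf("all channels must share the same t0")
  group <- match.arg(group, c("control", "mosaic_pup", "mosaic_P25", "mosaic_adult"))
  if (is.null(hemisphere_map)) {
    hemisphere_map <- stats::setNames(rep("none", length(channels)), names(channels))
  }
  bad <- setdiff(unique(hemisphere_map), c("injected", "control_hemisphere", "none"))
  if (length(bad)) stopf("invalid hemisphere labels: %s", paste(bad, collapse = ", "))
  structure(
    list(channels = channels, animal_id = as.character(animal_id), group = group,
         hemisphere_map = hemisphere_map),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> animal '%s' (%s), %d channels\n",
              x$animal_id, x$group, length(x$channels)))
  for (nm in names(x$channels)) {
    ch <- x$channels[[nm]]
    side <- if (nm %in% names(x$hemisphere_map)) x$hemisphere_map[[nm]] else "none"
    cat(sprintf("  %-14s %8d samples @ %6g Hz  [%s]\n",
                nm, length(ch$samples), ch$fs, side))
  }
  invisible(x)
}

#' Pick the channel of a recording assigned to a hemisphere
#' @param rec a [recording()].
#' @param side `"injected"` or `"control_hemisphere"`.
#' @return a [time_series()] or `NULL` if absent.
#' @export
hemisphere_channel <- function(rec, side) {
  hit <- names(rec$hemisphere_map)[rec$hemisphere_map == side]
  if (!length(hit)) return(NULL)
  rec$channels[[hit[1L]]]
}
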