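# Discrete detected events (beta bursts, hypersynchronous spikes, calcium
# transients) and their relation to interval sets.

EVENT_TYPES <- c("beta_burst", "hypersync_spike", "ca_transient")

#' Table of detected discrete events
#'
#' @param t_peak,t_start,t_end event times in seconds with
#'   `t_start <= t_peak <= t_end`.
#' @param amplitude peak amplitude (mV, or dF/F for calcium transients).
#' @param channel channel label.
#' @param type one of `"beta_burst"`, `"hypersync_spike"`, `"ca_transient"`.
#' @return An `event_table`: a data.frame with columns `t_peak`, `t_start`,
#'   `t_end`, `amplitude`, `duration`, `channel`, `type`, sorted by `t_peak`.
#' @export
event_table <- function(t_peak = numeric(0), t_start = t_peak, t_end = t_peak,
                        amplitude = rep(NA_real_, length(t_peak)),
                        channel = "", type = "beta_burst") {
  type <- match.arg(type, EVENT_TYPES)
  n <- length(t_peak)
  if (length(t_start) != n || length(t_end) != n)
    stopf("t_peak, t_start, t_end must have equal length")
  if (any(t_start > t_peak + 1e-12) || any(t_peak > t_end + 1e-12))
    stopf("need t_start <= t_peak <= t_end for every event")
  df <- data.frame(
    t_peak = as.numeric(t_peak), t_start = as.numeric(t_start),
    t_end = as.numeric(t_end), amplitude = as.numeric(amplitude),
    duration = as.numeric(t_end) - as.numeric(t_start),
    channel = rep_len(as.character(channel), n),
    type = rep_len(type, n), stringsAsFactors = FALSE
  )
  df <- df[order(df$t_peak), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("event_table", "data.frame"))
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("<event_table> %d events (%s)\n", nrow(x),
              paste(unique(x$type), collapse = ", ")))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 6))
  invisible(x)
}

#' Which events fall inside a set of intervals
#'
#' Membership is decided by the event peak time only (half-open intervals).
#' For an empty event table the fraction is undefined and flagged as such
#' rather than reported as 0.
#'
#' @param ev an [event_table()].
#' @param iv an [interval_set()].
#' @return list with `in_interval` (logical per event), `fraction`
#'   (mean of the booleans, `NA` when undefined), `n` and `undefined`.
#' @export
events_in_intervals <- function(ev, iv) {
  if (!nrow(ev)) {
    return(list(in_interval = logical(0), fraction = NA_real_, n = 0L,
                undefined = TRUE))
  }
  inside <- iv_contains(ev$t_peak, iv)
  list(in_interval = inside, fraction = mean(inside), n = nrow(ev),
       undefined = FALSE)
}

#' Event rate in events per hour
#' @param ev an [event_table()].
#' @param duration analyzed duration in seconds (> 0).
#' @export
event_rate <- function(ev, duration) {
  if (!is_number(duration) || duration <= 0) stopf("duration must be > 0")
  nrow(ev) * 3600 / duration
}

#' Write / read event tables as CSV
#' @param ev an [event_table()].
#' @param path file path.
#' @export
write_event_csv <- function(ev, path) {
  utils::write.csv(as.data.frame(ev), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_event_csv
#' @export
read_event_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  event_table(df$t_peak, df$t_start, df$t_end, df$amplitude,
              channel = df$channel, type = df$type[1] %||% "beta_burst")
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a
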