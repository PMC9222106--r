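# Interval algebra on labeled, sorted, pairwise-disjoint half-open intervals.
# This underlies every "% of events within up states" style statistic.

IV_LABELS <- c("US", "DS", "burst", "NREM", "REM", "Wake", "custom")

#' Labeled set of disjoint time intervals
#'
#' Intervals are half-open `[t_start, t_end)`, sorted by start and pairwise
#' disjoint. Abutting intervals are merged on construction.
#'
#' @param start,end numeric vectors of interval bounds in seconds.
#' @param label one of `"US"`, `"DS"`, `"burst"`, `"NREM"`, `"REM"`,
#'   `"Wake"`, `"custom"`.
#' @return An object of class `interval_set`: a data.frame with columns
#'   `start` and `end` plus a `label` attribute.
#' @export
interval_set <- function(start = numeric(0), end = numeric(0), label = "custom") {
  label <- match.arg(label, IV_LABELS)
  start <- as.numeric(start); end <- as.numeric(end)
  if (length(start) != length(end)) stopf("start and end must have equal length")
  if (anyNA(start) || anyNA(end)) stopf("interval bounds must be finite")
  if (any(end <= start)) stopf("every interval needs t_start < t_end")
  o <- order(start)
  start <- start[o]; end <- end[o]
  # merge overlapping/abutting intervals so invariants hold by construction
  if (length(start) > 1L) {
    cme <- cummax(end)
    new_grp <- c(TRUE, start[-1L] > cme[-length(cme)])
    grp <- cumsum(new_grp)
    start <- start[new_grp]
    last_of_grp <- c(which(new_grp)[-1L] - 1L, length(end))
    end <- cme[last_of_grp]
  }
  structure(data.frame(start = start, end = end),
            label = label, class = c("interval_set", "data.frame"))
}

#' @export
print.interval_set <- function(x, ...) {
  cat(sprintf("<interval_set> label '%s', %d intervals, total %.3f s\n",
              attr(x, "label"), nrow(x), iv_total(x)))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("  ... %d more\n", nrow(x) - 6))
  invisible(x)
}

iv_label <- function(iv) attr(iv, "label")

#' Total covered duration of an interval set (seconds)
#' @param iv an [interval_set()].
#' @export
iv_total <- function(iv) if (nrow(iv)) sum(iv$end - iv$start) else 0

#' Intersection of two interval sets
#'
#' Exact point-set intersection, returned merged and sorted. Empty inputs
#' are allowed and yield an empty set.
#'
#' @param a,b [interval_set()] objects.
#' @param label label for the result (default `"custom"`).
#' @export
iv_intersect <- function(a, b, label = "custom") {
  if (!nrow(a) || !nrow(b)) return(interval_set(label = label))
  # boundary sweep: membership of inter-boundary midpoints in both sets
  bounds <- sort(unique(c(a$start, a$end, b$start, b$end)))
  if (length(bounds) < 2L) return(interval_set(label = label))
  mids <- (bounds[-1L] + bounds[-length(bounds)]) / 2
  keep <- iv_contains(mids, a) & iv_contains(mids, b)
  if (!any(keep)) return(interval_set(label = label))
  interval_set(bounds[-length(bounds)][keep], bounds[-1L][keep], label = label)
}

#' Complement of an interval set within a window
#' @param iv an [interval_set()].
#' @param t_lo,t_hi window bounds in seconds.
#' @param label label for the result.
#' @export
iv_complement <- function(iv, t_lo, t_hi, label = "custom") {
  if (t_lo >= t_hi) stopf("t_lo must be < t_hi")
  clip <- iv_intersect(iv, interval_set(t_lo, t_hi))
  if (!nrow(clip)) return(interval_set(t_lo, t_hi, label = label))
  starts <- c(t_lo, clip$end)
  ends <- c(clip$start, t_hi)
  keep <- ends > starts
  interval_set(starts[keep], ends[keep], label = label)
}

#' Shift all intervals by a constant offset
#' @param iv an [interval_set()].
#' @param dt shift in seconds.
#' @export
iv_shift <- function(iv, dt) {
  interval_set(iv$start + dt, iv$end + dt, label = iv_label(iv))
}

#' Fraction of a window covered by an interval set (duty cycle)
#'
#' For phase-locking statistics this is the chance level: the probability
#' that a uniformly placed event falls inside the set.
#'
#' @param iv an [interval_set()].
#' @param t_lo,t_hi analysis window in seconds; `t_lo < t_hi` required.
#' @return fraction in `[0, 1]`.
#' @export
duty_cycle <- function(iv, t_lo, t_hi) {
  if (!is_number(t_lo) || !is_number(t_hi) || t_lo >= t_hi)
    stopf("duty_cycle needs t_lo < t_hi")
  iv_total(iv_intersect(iv, interval_set(t_lo, t_hi))) / (t_hi - t_lo)
}

# merge sorted disjoint intervals separated by gaps smaller than `gap`
merge_gaps <- function(s, e, gap) {
  if (length(s) <= 1L) return(list(start = s, end = e))
  grp <- cumsum(c(TRUE, s[-1L] - e[-length(e)] >= gap))
  first <- !duplicated(grp)
  last <- !duplicated(grp, fromLast = TRUE)
  list(start = s[first], end = e[last])
}

#' Membership of points in an interval set
#'
#' Half-open convention: a point `t` is inside iff `start <= t < end` for
#' some interval.
#'
#' @param t numeric vector of times (seconds).
#' @param iv an [interval_set()].
#' @return logical vector.
#' @export
iv_contains <- function(t, iv) {
  if (!nrow(iv)) return(rep(FALSE, length(t)))
  idx <- findInterval(t, iv$start)
  idx > 0L & t < iv$end[pmax(idx, 1L)]
}
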