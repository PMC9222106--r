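# Shared fixtures and oracles for the test suite. Everything is generated
# in code; no binary fixtures.

# 1 ms boolean-grid oracle for interval algebra: marks each millisecond
# midpoint of [0, t_hi] as covered/uncovered
grid_cover <- function(iv, t_hi, dt = 1e-3) {
  mids <- seq(dt / 2, t_hi - dt / 2, by = dt)
  iv_contains(mids, iv)
}

random_interval_set <- function(n, t_hi, label = "custom") {
  s <- sort(runif(n, 0, t_hi))
  e <- s + runif(n, 0.01, (t_hi / n))
  interval_set(s, pmin(e, t_hi), label = label)
}

# intersection-over-union of two interval sets
iv_iou <- function(a, b) {
  ab <- iv_total(iv_intersect(a, b))
  ab / (iv_total(a) + iv_total(b) - ab)
}

# short mosaic LFP pair used by several detector tests (cached per session)
shared_mosaic_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_lfp_pair(synth_config("mosaic", seed = 42,
                                               duration = 300))
    }
    cache
  }
})

# greedy one-to-one matching of detected vs true event times
match_events <- function(det, truth, tol) {
  used <- rep(FALSE, length(truth))
  hits <- 0L
  for (t in det) {
    j <- which(!used & abs(truth - t) <= tol)
    if (length(j)) { used[j[1L]] <- TRUE; hits <- hits + 1L }
  }
  list(matched = hits, fp = length(det) - hits, fn = length(truth) - hits)
}
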