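# Paired and group statistics used throughout the pipeline.
# Conventions: two-sided p-values; paired Wilcoxon drops zero differences
# and reports the effective n.

#' Paired per-animal metric table
#'
#' One row per animal per metric. The paired form holds the value measured
#' in the injected hemisphere and in the contralateral (internal control)
#' hemisphere; the unpaired form holds one value per animal with a group
#' label.
#'
#' @param animal_id character vector.
#' @param metric metric name(s).
#' @param value_injected,value_control paired values (paired form).
#' @param group,value group labels and values (unpaired form).
#' @return a data.frame of class `paired_table`.
#' @export
paired_table <- function(animal_id, metric,
                         value_injected = NULL, value_control = NULL,
                         group = NULL, value = NULL) {
  if (!is.null(value_injected)) {
    df <- data.frame(animal_id = animal_id, metric = metric,
                     value_injected = as.numeric(value_injected),
                     value_control = as.numeric(value_control),
                     stringsAsFactors = FALSE)
    vals <- c(df$value_injected, df$value_control)
  } else {
    df <- data.frame(animal_id = animal_id, metric = metric,
                     group = group, value = as.numeric(value),
                     stringsAsFactors = FALSE)
    vals <- df$value
  }
  if (anyNA(vals) || any(!is.finite(vals))) stopf("paired_table values must be finite")
  if (anyDuplicated(df[c("animal_id", "metric")]))
    stopf("one row per animal per metric required")
  structure(df, class = c("paired_table", "data.frame"))
}

#' Group statistical test
#'
#' Dispatches the tests used for cohort comparisons: paired Wilcoxon
#' signed-rank for injected-vs-control hemisphere values, Mann-Whitney for
#' unpaired group comparisons, Bartlett's test for dispersion differences,
#' and a one-sample t test against a fixed chance level.
#'
#' @param values a [paired_table()] (paired form for `wilcoxon_paired`;
#'   unpaired form with exactly two groups for `mann_whitney` / `bartlett`;
#'   either form with a single value column for `one_sample_t`), or for
#'   convenience a plain numeric vector for `one_sample_t`.
#' @param method one of `"wilcoxon_paired"`, `"mann_whitney"`, `"bartlett"`,
#'   `"one_sample_t"`.
#' @param mu0 null value, required for (and only for) `one_sample_t`.
#' @return list with `statistic`, `p_value`, `n` (effective sample size)
#'   and `method`.
#' @export
group_test <- function(values,
                       method = c("wilcoxon_paired", "mann_whitney",
                                  "bartlett", "one_sample_t"),
                       mu0 = NULL) {
  method <- match.arg(method)
  if (method == "one_sample_t") {
    if (is.null(mu0)) stopf("mu0 is required for one_sample_t")
    x <- if (is.numeric(values)) values else values$value
    if (length(x) < 3L) stopf("one_sample_t needs n >= 3")
    if (stats::sd(x) < .Machine$double.eps^0.5)
      stopf("degenerate input: zero variance under one_sample_t")
    ht <- stats::t.test(x, mu = mu0)
    return(list(statistic = unname(ht$statistic), p_value = ht$p.value,
                n = length(x), method = method))
  }
  if (!is.null(mu0)) stopf("mu0 is only meaningful for one_sample_t")

  if (method == "wilcoxon_paired") {
    if (is.null(values$value_injected)) stopf("wilcoxon_paired needs the paired form")
    x <- values$value_injected; y <- values$value_control
    if (length(x) < 3L) stopf("wilcoxon_paired needs n >= 3 pairs")
    d <- x - y
    n_eff <- sum(d != 0)
    if (n_eff == 0L) stopf("degenerate input: all paired differences are zero")
    ht <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE, exact = TRUE))
    return(list(statistic = unname(ht$statistic), p_value = ht$p.value,
                n = n_eff, method = method))
  }

  if (is.null(values$group)) stopf("%s needs the unpaired form with a group column", method)
  groups <- split(values$value, values$group)
  if (length(groups) != 2L) stopf("%s needs exactly two groups", method)
  if (any(lengths(groups) < 3L)) stopf("%s needs n >= 3 per group", method)

  if (method == "mann_whitney") {
    ht <- suppressWarnings(stats::wilcox.test(groups[[1L]], groups[[2L]]))
    return(list(statistic = unname(ht$statistic), p_value = ht$p.value,
                n = nrow(values), method = method))
  }
  # bartlett
  if (any(vapply(groups, stats::sd, numeric(1)) < .Machine$double.eps^0.5))
    stopf("degenerate input: zero variance within a group under bartlett")
  ht <- stats::bartlett.test(values$value, factor(values$group))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       n = nrow(values), method = method)
}
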