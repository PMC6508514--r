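# Two-group comparison: Mann-Whitney rank-sum test with the two-tier star
# convention (** p < .01, * .01 <= p < .05).

#' Mann-Whitney comparison of a metric between two groups
#'
#' Two-sided rank-sum test: exact when both groups have at most 20
#' observations and the pooled values carry no ties, otherwise the normal
#' approximation with tie and continuity correction. Non-finite values are
#' dropped. When every pooled value is identical the test is degenerate and
#' p = 1 is returned with a warning.
#'
#' @param group_a,group_b numeric metric values.
#' @param labels character vector of length 2 naming the groups.
#' @param metric name of the compared metric (bookkeeping only).
#' @return an object of class `fq_comparison`: list with `metric`, `labels`,
#'   `n` (per-group sizes), `medians`, `U` (the rank-sum statistic for group
#'   A), `p_value`, and `stars` (`"**"` if p < .01, `"*"` if .01 <= p < .05,
#'   `""` otherwise).
#' @export
mann_whitney <- function(group_a, group_b, labels = c("A", "B"),
                         metric = "value") {
  a <- group_a[is.finite(group_a)]
  b <- group_b[is.finite(group_b)]
  if (!length(a) || !length(b))
    stop("both groups must contain at least one finite value")
  if (length(unique(c(a, b))) == 1L) {
    warning("all values tied across both groups; p = 1")
    U <- length(a) * length(b) / 2
    p <- 1
  } else {
    exact <- max(length(a), length(b)) <= 20L && !anyDuplicated(c(a, b))
    wt <- suppressWarnings(
      stats::wilcox.test(a, b, alternative = "two.sided",
                         exact = exact, correct = TRUE))
    U <- unname(wt$statistic)
    p <- min(1, wt$p.value)
  }
  structure(list(metric = metric, labels = labels,
                 n = c(length(a), length(b)),
                 medians = c(stats::median(a), stats::median(b)),
                 U = U, p_value = p,
                 stars = significance_stars(p)),
            class = "fq_comparison")
}

#' Two-tier significance stars
#'
#' `"**"` iff p < .01, `"*"` iff .01 <= p < .05, otherwise `""` (so p = .01
#' earns one star and p = .05 none, exactly at the boundaries).
#'
#' @param p p-value(s) in `[0, 1]`.
#' @return character vector of star annotations.
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))
}

#' @export
print.fq_comparison <- function(x, ...) {
  cat(sprintf("<fq_comparison> %s: %s (n=%d, median %.4g) vs %s (n=%d, median %.4g)\n",
              x$metric, x$labels[1], x$n[1], x$medians[1],
              x$labels[2], x$n[2], x$medians[2]))
  cat(sprintf("  U = %.1f, p = %.4g %s\n", x$U, x$p_value, x$stars))
  invisible(x)
}

#' Compare every shared metric column between two groups
#'
#' Runs [mann_whitney()] per metric column of two per-cell metric tables and
#' collects a tidy comparison table. A Holm-adjusted p-value column is
#' included alongside the unadjusted per-metric tests.
#'
#' @param df_a,df_b per-cell metric data frames (as from [run_pipeline()]).
#' @param metrics metric columns to compare; defaults to the five headline
#'   metrics.
#' @param labels group labels.
#' @return data frame with one row per metric: group medians, n, U, p_value,
#'   p_holm, stars.
#' @export
compare_groups <- function(df_a, df_b,
                           metrics = c("total_length_mm", "i_mean",
                                       "i_skewness", "a_normAvgRad",
                                       "delta_theta_deg"),
                           labels = c("A", "B")) {
  metrics <- intersect(metrics, intersect(names(df_a), names(df_b)))
  rows <- lapply(metrics, function(m) {
    cmp <- mann_whitney(df_a[[m]], df_b[[m]], labels = labels, metric = m)
    data.frame(metric = m,
               median_a = cmp$medians[1], median_b = cmp$medians[2],
               n_a = cmp$n[1], n_b = cmp$n[2],
               U = cmp$U, p_value = cmp$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_holm <- stats::p.adjust(out$p_value, method = "holm")
  out$stars <- significance_stars(out$p_value)
  out
}
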