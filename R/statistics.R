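# Paired comparison of model performance distributions: two-tailed paired t
# tests and the Holm-Bonferroni step-down procedure for family-wise error
# control.

#' Two-tailed paired t test
#'
#' Classical paired t statistic on the differences `a - b`, with
#' `df = n - 1` and a two-tailed P value from the t distribution.  Pairs with
#' an undefined (NA) member are removed first (pairwise-complete deletion).
#' If every difference is exactly zero the comparison is null by
#' construction and P = 1 is reported; nonzero constant differences have no
#' within-pair variance and are rejected as degenerate.
#'
#' @param a,b Paired numeric vectors (per-iteration metric values of two
#'   models over the same test units).
#' @return A `paired_comparison` list: `n` complete pairs, `mean_diff`, `t`,
#'   `df`, `p`.
#' @export
paired_ttest <- function(a, b) {
  if (length(a) != length(b)) stopf("paired sequences differ in length")
  ok <- !(is.na(a) | is.na(b))
  d <- a[ok] - b[ok]
  n <- length(d)
  if (n < 2L) stopf("need >= 2 complete pairs (have %d)", n)
  m <- mean(d)
  s <- stats::sd(d)
  if (s == 0) {
    if (all(d == 0))
      return(structure(list(n = n, mean_diff = 0, t = 0, df = n - 1L, p = 1),
                       class = "paired_comparison"))
    stopf("degenerate paired test: constant nonzero differences")
  }
  t_stat <- m / (s / sqrt(n))
  structure(list(n = n, mean_diff = m, t = t_stat, df = n - 1L,
                 p = 2 * stats::pt(-abs(t_stat), df = n - 1L)),
            class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("paired t: n = %d, mean diff = %.4g, t = %.4g (df = %d), P = %.4g\n",
              x$n, x$mean_diff, x$t, x$df, x$p))
  invisible(x)
}

#' Holm-Bonferroni step-down correction
#'
#' P values are sorted ascending (stable for ties) and the k-th smallest is
#' compared against `alpha / (m + 1 - k)`.  Rejection proceeds sequentially
#' from the smallest P value and stops at the first failure (step-down), so
#' the rejection set is always a prefix of the sorted order and the
#' family-wise error rate is controlled at `alpha`.
#'
#' @param p Numeric vector of P values in `[0, 1]`.
#' @param alpha Family-wise significance level (default 0.05).
#' @return A `holm_result`: data frame `comparisons` in the input order with
#'   `p`, `rank`, `threshold` (`alpha / (m + 1 - rank)`) and `reject`, plus
#'   `m` and `alpha`.
#' @export
holm_bonferroni <- function(p, alpha = 0.05) {
  if (!length(p)) stopf("need at least one P value")
  if (anyNA(p) || any(p < 0 | p > 1)) stopf("P values must lie in [0, 1]")
  m <- length(p)
  ord <- order(p)                       # stable: ties keep input order
  thresholds <- alpha / (m + 1 - seq_len(m))
  sorted_reject <- p[ord] < thresholds
  first_fail <- match(FALSE, sorted_reject)
  if (!is.na(first_fail) && first_fail <= m)
    sorted_reject[first_fail:m] <- FALSE
  reject <- logical(m); reject[ord] <- sorted_reject
  rank <- integer(m); rank[ord] <- seq_len(m)
  structure(list(comparisons = data.frame(p = p, rank = rank,
                                          threshold = thresholds[rank],
                                          reject = reject),
                 m = m, alpha = alpha),
            class = "holm_result")
}

#' @export
print.holm_result <- function(x, ...) {
  cat(sprintf("<holm_result: m = %d, alpha = %g, %d rejection(s)>\n",
              x$m, x$alpha, sum(x$comparisons$reject)))
  print(x$comparisons, row.names = FALSE)
  invisible(x)
}

report_metric_vector <- function(report, metric) {
  stats::setNames(report$iterations[[metric]], report$iterations$test_unit)
}

#' Compare two models' evaluation reports across fall-type families
#'
#' For each metric, paired two-tailed t tests (model A minus model B) are run
#' in each fall-type family, and the Holm-Bonferroni step-down is applied to
#' that metric's family of tests (m = number of families, 3 for
#' all/lateral/AP).  Iterations pair by test unit; pairs with an undefined
#' member are dropped (pairwise-complete).  A family whose paired differences
#' are constant and nonzero (possible with small discrete test sets) is
#' reported with `p = NA` and treated as non-significant.
#'
#' @param reports_a,reports_b Named lists of `fall_eval` reports over the
#'   same families (e.g. `list(all = ..., lateral = ..., ap = ...)`), or two
#'   single reports (treated as a one-family comparison).
#' @param metrics Metrics to compare.
#' @param alpha Family-wise level.
#' @return A `fall_model_comparison`: data frame with one row per
#'   family x metric: `n_pairs`, `mean_diff`, `t`, `df`, `p`,
#'   `holm_threshold`, `significant_raw`, `significant_holm`.
#' @export
compare_models <- function(reports_a, reports_b,
                           metrics = c("recall", "precision", "f1", "auc"),
                           alpha = 0.05) {
  if (inherits(reports_a, "fall_eval")) reports_a <- list(all = reports_a)
  if (inherits(reports_b, "fall_eval")) reports_b <- list(all = reports_b)
  if (!identical(sort(names(reports_a)), sort(names(reports_b))))
    stopf("reports_a and reports_b must cover the same families")
  families <- names(reports_a)
  for (f in families) {
    ia <- reports_a[[f]]$iterations$test_unit
    ib <- reports_b[[f]]$iterations$test_unit
    if (!identical(ia, ib))
      stopf("family '%s': iteration ids do not match between reports", f)
  }
  rows <- list()
  for (metric in metrics) {
    res <- lapply(families, function(f) {
      a <- report_metric_vector(reports_a[[f]], metric)
      b <- report_metric_vector(reports_b[[f]], metric)
      tryCatch(paired_ttest(a, b), error = function(e) NULL)
    })
    p_raw <- vapply(res, function(r) if (is.null(r)) NA_real_ else r$p,
                    numeric(1))
    usable <- !is.na(p_raw)
    holm_thr <- rep(NA_real_, length(families))
    holm_rej <- rep(FALSE, length(families))
    if (any(usable)) {
      h <- holm_bonferroni(p_raw[usable], alpha = alpha)
      holm_thr[usable] <- h$comparisons$threshold
      holm_rej[usable] <- h$comparisons$reject
    }
    for (i in seq_along(families)) {
      r <- res[[i]]
      rows[[length(rows) + 1L]] <- data.frame(
        family = families[i], metric = metric,
        n_pairs = if (is.null(r)) NA_integer_ else r$n,
        mean_diff = if (is.null(r)) NA_real_ else r$mean_diff,
        t = if (is.null(r)) NA_real_ else r$t,
        df = if (is.null(r)) NA_integer_ else r$df,
        p = p_raw[i], holm_threshold = holm_thr[i],
        significant_raw = !is.na(p_raw[i]) && p_raw[i] < alpha,
        significant_holm = holm_rej[i],
        stringsAsFactors = FALSE)
    }
  }
  structure(list(table = do.call(rbind, rows), alpha = alpha),
            class = "fall_model_comparison")
}

#' @export
print.fall_model_comparison <- function(x, ...) {
  cat(sprintf("<fall_model_comparison: alpha = %g>\n", x$alpha))
  t <- x$table
  t$p <- signif(t$p, 3)
  t$mean_diff <- signif(t$mean_diff, 3)
  t$t <- signif(t$t, 3)
  print(t, row.names = FALSE)
  invisible(x)
}
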