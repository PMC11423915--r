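# Group-comparison statistics for embryo phenotyping.
#
# Convention of the analysis: per-cell scalar metrics (area, rectangularity,
# elongation) are compared with Welch's unequal-variance t test; per-blade
# scalars (l/w ratio, blade area), with small group sizes (4-6 embryos),
# with the two-sample Mann-Whitney rank test; neighbour-count category
# distributions with Pearson's chi-square.  All tests are two-tailed and no
# multiple-testing correction is applied; reports carry the number of
# comparisons performed so readers can judge.

.comparison_row <- function(metric, group_a, group_b, test, statistic, df,
                            p_value) {
  data.frame(metric = metric, group_a = group_a, group_b = group_b,
             test = test, statistic = unname(statistic),
             df = unname(df), p_value = unname(p_value),
             stringsAsFactors = FALSE)
}

#' Welch's two-sample t test
#'
#' Mean comparison with Welch's correction for unequal variances
#' (Welch-Satterthwaite degrees of freedom), two-tailed.
#'
#' @param a,b numeric samples, each of size >= 2 with finite values.
#' @param metric,group_a,group_b labels carried into the output row.
#' @return A one-row data frame: metric, group labels, test name,
#'   statistic, df, p_value.
#' @export
welch_t <- function(a, b, metric = "", group_a = "a", group_b = "b") {
  if (length(a) < 2L || length(b) < 2L) {
    stop("Welch's t test needs at least 2 observations per group",
         call. = FALSE)
  }
  if (anyNA(a) || anyNA(b) || any(!is.finite(c(a, b)))) {
    stop("samples must be finite and non-missing", call. = FALSE)
  }
  ht <- stats::t.test(a, b, var.equal = FALSE, alternative = "two.sided")
  .comparison_row(metric, group_a, group_b, "welch_t",
                  ht$statistic, ht$parameter, ht$p.value)
}

#' Two-sample Mann-Whitney rank test
#'
#' Two-tailed.  The exact null distribution is enumerated when the combined
#' sample size is at most 12 and there are no ties; otherwise the normal
#' approximation with midranks and continuity correction is used (group
#' sizes in blade comparisons are small, so the exact branch is the common
#' one).
#'
#' @inheritParams welch_t
#' @return A one-row comparison data frame (statistic = U for sample a;
#'   df is NA).
#' @export
mann_whitney <- function(a, b, metric = "", group_a = "a", group_b = "b") {
  if (length(a) < 1L || length(b) < 1L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  if (anyNA(a) || anyNA(b) || any(!is.finite(c(a, b)))) {
    stop("samples must be finite and non-missing", call. = FALSE)
  }
  ties <- anyDuplicated(c(a, b)) > 0L
  use_exact <- (length(a) + length(b) <= 12L) && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided",
                       exact = use_exact, correct = TRUE)
  )
  .comparison_row(metric, group_a, group_b, "mann_whitney",
                  ht$statistic, NA_real_, ht$p.value)
}

#' Pearson chi-square test on a contingency table
#'
#' Compares count distributions over categories between groups (e.g.
#' neighbour-count bins per stage group), without Yates continuity
#' correction.  Categories empty in every group are dropped with a warning;
#' a zero expected count in a remaining category is an error advising
#' pooling.
#'
#' @param table matrix of counts, categories in rows, groups in columns.
#' @param metric,group_a,group_b labels carried into the output row (for a
#'   two-column table the group labels default to its column names).
#' @return A one-row comparison data frame.
#' @export
chi2_counts <- function(table, metric = "", group_a = NULL, group_b = NULL) {
  m <- as.matrix(table)
  if (any(m < 0) || anyNA(m)) {
    stop("contingency table must contain non-negative counts", call. = FALSE)
  }
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop("contingency table must be at least 2 x 2", call. = FALSE)
  }
  empty <- rowSums(m) == 0
  if (any(empty)) {
    warning("dropping empty categories: ",
            paste(rownames(m)[empty], collapse = ", "), call. = FALSE)
    m <- m[!empty, , drop = FALSE]
  }
  if (nrow(m) < 2L) {
    stop("fewer than 2 non-empty categories after dropping", call. = FALSE)
  }
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected <= 0)) {
    stop("zero expected count; pool sparse categories before testing",
         call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  if (is.null(group_a)) group_a <- colnames(m)[1L] %||% "a"
  if (is.null(group_b)) {
    group_b <- if (ncol(m) == 2L) colnames(m)[2L] %||% "b" else "all"
  }
  .comparison_row(metric, group_a, group_b, "chi2",
                  ht$statistic, ht$parameter, ht$p.value)
}

`%||%` <- function(x, y) if (is.null(x) || is.na(x)) y else x

#' Binomial sample-composition estimate
#'
#' Given the background frequency p of morphologically abnormal embryos in
#' the intact population, the probability that a sample of n embryos
#' contains only normal ones is (1 - p)^n, and the expected number of
#' abnormal embryos in the sample is n * p.  Used to rule out intrinsic
#' strain plasticity as the source of abnormal morphologies in small
#' microdissected samples.
#'
#' @param p_abnormal background abnormality frequency in [0, 1].
#' @param n sample size (positive integer).
#' @return An object of class \code{binomial_composition}: list with
#'   \code{p_abnormal}, \code{n}, \code{p_all_normal},
#'   \code{expected_abnormal}.
#' @examples
#' binomial_composition(0.04781, 5)
#' @export
binomial_composition <- function(p_abnormal, n) {
  if (!is.numeric(p_abnormal) || length(p_abnormal) != 1L ||
      is.na(p_abnormal) || p_abnormal < 0 || p_abnormal > 1) {
    stop("`p_abnormal` must be a frequency in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1 ||
      n != round(n)) {
    stop("`n` must be a positive integer", call. = FALSE)
  }
  structure(list(p_abnormal = p_abnormal,
                 n = as.integer(n),
                 p_all_normal = (1 - p_abnormal)^n,
                 expected_abnormal = n * p_abnormal),
            class = "binomial_composition")
}

#' @export
print.binomial_composition <- function(x, ...) {
  cat(sprintf(paste0("<binomial_composition> p = %.5f, n = %d: ",
                     "P(all normal) = %.4f, expected abnormal = %.4f\n"),
              x$p_abnormal, x$n, x$p_all_normal, x$expected_abnormal))
  invisible(x)
}
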