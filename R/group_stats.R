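flim_htest <- function(statistic, p_value, n1, n2, method) {
  structure(list(statistic = unname(statistic), p_value = unname(p_value),
                 n1 = n1, n2 = n2, method = method), class = "flim_htest")
}

#' @export
print.flim_htest <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n1 = %d, n2 = %d)\n",
              x$method, x$statistic, x$p_value, x$n1, x$n2))
  invisible(x)
}

#' Mann-Whitney U test (two independent samples)
#'
#' Two-sided rank-sum comparison of two independent groups, the test used
#' for the unpaired contrasts of the feature tables. Ties receive midranks.
#' The p-value is exact when \code{min(n1, n2) <= 8} and there are no ties,
#' and otherwise uses the normal approximation with tie-corrected variance
#' (no continuity correction).
#'
#' @param a,b Non-empty numeric samples.
#' @param exact Force the exact/approximate branch (default: automatic).
#' @return A \code{"flim_htest"}: U statistic (number of (a, b) pairs with
#'   a > b, ties counted half), two-sided p, sample sizes.
#' @export
mann_whitney_u <- function(a, b, exact = NULL) {
  if (length(a) == 0L || length(b) == 0L) stop("both samples must be non-empty")
  if (anyNA(c(a, b))) stop("samples contain NA")
  ties <- any(duplicated(c(a, b)))
  if (is.null(exact)) exact <- (min(length(a), length(b)) <= 8L) && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = FALSE))
  flim_htest(ht$statistic, min(ht$p.value, 1), length(a), length(b),
             if (exact) "Mann-Whitney U (exact)"
             else "Mann-Whitney U (normal approximation)")
}

#' Wilcoxon signed-rank test (paired differences)
#'
#' Two-sided signed-rank test of paired differences against a zero median,
#' the test used for the paired non-sickled vs sickled contrasts at patient
#' level. Zero differences are dropped before ranking (and reflected in the
#' reported n). Exact p for n <= 12 retained nonzero differences without
#' tied magnitudes; otherwise the tie-corrected normal approximation.
#'
#' @param paired_diffs Numeric vector of paired differences.
#' @param exact Force the exact/approximate branch (default: automatic).
#' @return A \code{"flim_htest"}: signed-rank statistic W (sum of positive
#'   ranks), two-sided p, n1 = n2 = retained pairs.
#' @export
wilcoxon_signed_rank <- function(paired_diffs, exact = NULL) {
  if (anyNA(paired_diffs)) stop("differences contain NA")
  d <- paired_diffs[paired_diffs != 0]
  if (length(d) == 0L) stop("all paired differences are zero")
  ties <- any(duplicated(abs(d)))
  if (is.null(exact)) exact <- (length(d) <= 12L) && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(d, mu = 0, exact = exact, correct = FALSE))
  flim_htest(ht$statistic, min(ht$p.value, 1), length(d), length(d),
             if (exact) "Wilcoxon signed-rank (exact)"
             else "Wilcoxon signed-rank (normal approximation)")
}

#' Kolmogorov-Smirnov normality screen
#'
#' One-sample KS test of composite normality with mean and SD estimated
#' from the data. Because the parameters are estimated, the default uses
#' the Lilliefors-corrected reference distribution
#' (\code{nortest::lillie.test}); \code{lilliefors = FALSE} gives the
#' uncorrected KS p-value (anti-conservative, provided for comparability
#' with legacy software output).
#'
#' @param x Numeric sample, n >= 5, non-constant.
#' @param lilliefors Use the Lilliefors correction (default TRUE).
#' @return A \code{"flim_htest"} with the D statistic and p-value.
#' @export
ks_normality <- function(x, lilliefors = TRUE) {
  if (anyNA(x)) stop("sample contains NA")
  if (length(x) < 5L) stop("need at least 5 observations")
  if (min(x) == max(x)) stop("constant sample: normality test undefined")
  if (lilliefors) {
    ht <- nortest::lillie.test(x)
    flim_htest(ht$statistic, ht$p.value, length(x), 0L,
               "Lilliefors (KS) normality test")
  } else {
    ht <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
    flim_htest(ht$statistic, ht$p.value, length(x), 0L,
               "Kolmogorov-Smirnov normality test (uncorrected)")
  }
}

#' Feature-wise two-group comparison table
#'
#' Builds a report shaped like the study's summary tables: one row per
#' feature with group means and the two-sided p-value of the appropriate
#' nonparametric test ([mann_whitney_u()] for independent groups,
#' [wilcoxon_signed_rank()] on paired differences when \code{paired =
#' TRUE}). No multiple-testing correction is applied by default.
#'
#' @param features Data frame of numeric feature columns.
#' @param group Two-level grouping vector (row-aligned with
#'   \code{features}).
#' @param feature_cols Which columns to compare (default: all numeric).
#' @param paired Treat rows as paired across groups (requires equal group
#'   sizes in matching order).
#' @param p_adjust Optional p-adjustment method passed to
#'   [stats::p.adjust()] (default \code{"none"}).
#' @return Data frame: feature, per-group means, statistic, p_value,
#'   method.
#' @export
compare_groups <- function(features, group, feature_cols = NULL,
                           paired = FALSE, p_adjust = "none") {
  group <- factor(group)
  if (nlevels(group) != 2L) stop("group must have exactly two levels")
  if (is.null(feature_cols))
    feature_cols <- names(features)[vapply(features, is.numeric, logical(1L))]
  lev <- levels(group)
  rows <- lapply(feature_cols, function(f) {
    a <- features[[f]][group == lev[1L]]
    b <- features[[f]][group == lev[2L]]
    ht <- if (paired) {
      if (length(a) != length(b)) stop("paired comparison needs equal group sizes")
      wilcoxon_signed_rank(a - b)
    } else mann_whitney_u(a, b)
    data.frame(feature = f, mean_1 = mean(a), mean_2 = mean(b),
               statistic = ht$statistic, p_value = ht$p_value,
               method = ht$method, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[2:3] <- paste0("mean_", lev)
  out$p_value <- stats::p.adjust(out$p_value, method = p_adjust)
  out
}
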