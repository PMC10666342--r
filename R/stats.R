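#' Wilcoxon tests for paired or independent score vectors
#'
#' Thin wrapper around [stats::wilcox.test()] returning the statistic,
#' p-value and the mean +- SD of each group formatted for reporting
#' (signed-rank for paired scores, rank-sum otherwise).
#'
#' @param scores_a,scores_b numeric score vectors; equal length when
#'   `paired = TRUE`.
#' @param paired use the signed-rank test (default) or the rank-sum test.
#' @param exact passed to [stats::wilcox.test()].
#' @return data.frame with `method`, `statistic`, `p_value`, `n_a`, `n_b`,
#'   `mean_a`, `sd_a`, `mean_b`, `sd_b`, `summary_a`, `summary_b`.
#' @export
paired_score_stats <- function(scores_a, scores_b, paired = TRUE, exact = NULL) {
  if (length(scores_a) < 2 || length(scores_b) < 2) stop("need n >= 2 per group")
  if (paired && length(scores_a) != length(scores_b)) {
    stop("paired vectors must have equal length")
  }
  wt <- suppressWarnings(stats::wilcox.test(scores_a, scores_b,
                                            paired = paired, exact = exact))
  fmt <- function(x) sprintf("%.2f ± %.2f", mean(x), stats::sd(x))
  data.frame(method = wt$method, statistic = unname(wt$statistic),
             p_value = wt$p.value, n_a = length(scores_a),
             n_b = length(scores_b),
             mean_a = mean(scores_a), sd_a = stats::sd(scores_a),
             mean_b = mean(scores_b), sd_b = stats::sd(scores_b),
             summary_a = fmt(scores_a), summary_b = fmt(scores_b),
             stringsAsFactors = FALSE)
}

#' Bland-Altman agreement analysis
#'
#' @param a,b paired measurement vectors.
#' @param conf multiplier for the limits of agreement (default 1.96).
#' @return list of class `bland_altman`: `bias`, `sd_diff`, `loa_lower`,
#'   `loa_upper`, `p_value` (paired t-test of the differences), `n`, and a
#'   per-pair data.frame `points` (`mean`, `diff`).
#' @export
bland_altman <- function(a, b, conf = 1.96) {
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  if (length(a) < 2) stop("need n >= 2")
  d <- a - b
  bias <- mean(d); s <- stats::sd(d)
  p <- if (s == 0) 1 else stats::pt(abs(bias / (s / sqrt(length(d)))),
                                    df = length(d) - 1, lower.tail = FALSE) * 2
  structure(list(bias = bias, sd_diff = s,
                 loa_lower = bias - conf * s, loa_upper = bias + conf * s,
                 p_value = p, n = length(d),
                 points = data.frame(mean = (a + b) / 2, diff = d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> bias = %.4g [LoA %.4g, %.4g], p = %.3g, n = %d\n",
              x$bias, x$loa_lower, x$loa_upper, x$p_value, x$n))
  invisible(x)
}

#' Intraclass correlation coefficient (two-way random, absolute agreement)
#'
#' Shrout-Fleiss ICC(2,1) (single rater) or ICC(2,k) (mean of k raters)
#' computed from the two-way ANOVA mean squares of a subjects x raters
#' score matrix.
#'
#' @param ratings numeric matrix, one row per subject, one column per
#'   rater.
#' @param unit `"single"` or `"average"`.
#' @return data.frame with `icc`, `type`, `n_subjects`, `n_raters`.
#' @export
icc_agreement <- function(ratings, unit = c("single", "average")) {
  unit <- match.arg(unit)
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2 || k < 2) stop("need at least 2 subjects and 2 raters")
  grand <- mean(ratings)
  row_m <- rowMeans(ratings); col_m <- colMeans(ratings)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((ratings - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- if (unit == "single") {
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  } else {
    (msr - mse) / (msr + (msc - mse) / n)
  }
  data.frame(icc = icc, type = if (unit == "single") "ICC(2,1)" else "ICC(2,k)",
             n_subjects = n, n_raters = k)
}
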