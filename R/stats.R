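#' Chi-square test of independence on a contingency table
#'
#' Pearson's chi-square with expected counts from the margins. For 2 x 2
#' tables the Yates continuity correction may be applied: 0.5 is subtracted
#' from each |observed - expected|, floored at zero so small deviations are
#' not over-corrected. The corrected statistic never exceeds the
#' uncorrected one.
#'
#' @param counts A matrix (at least 2 x 2) of non-negative integer counts,
#'   or anything coercible to one.
#' @param yates Apply the Yates continuity correction; allowed only for
#'   2 x 2 tables. Defaults to `TRUE` for 2 x 2 tables and `FALSE`
#'   otherwise.
#' @return A one-row tibble with `statistic`, `df` and `p_value`.
#' @examples
#' chi_square(matrix(c(16, 3, 32, 36), 2)) # ~6.85
#' @export
chi_square <- function(counts, yates = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2 || ncol(counts) < 2) {
    stop("`counts` must be at least 2 x 2", call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("`counts` must be non-negative integers", call. = FALSE)
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("`counts` has a zero margin", call. = FALSE)
  }
  is_2x2 <- all(dim(counts) == c(2, 2))
  if (is.null(yates)) yates <- is_2x2
  if (yates && !is_2x2) {
    stop("the Yates correction applies only to 2 x 2 tables", call. = FALSE)
  }
  res <- suppressWarnings(stats::chisq.test(counts, correct = yates))
  tibble::tibble(
    statistic = unname(res$statistic),
    df = unname(res$parameter),
    p_value = res$p.value
  )
}

#' Exact two-tailed binomial test p-value
#'
#' The exact two-tailed p-value for `k` successes in `n` trials against
#' success probability `p0`, computed as `min(1, 2 * min(P(X <= k),
#' P(X >= k)))`. For `p0 = 0.5` the distribution is symmetric and this
#' equals the probability of outcomes at least as extreme as `k`.
#'
#' @param k Number of successes, `0 <= k <= n`.
#' @param n Number of trials.
#' @param p0 Null success probability.
#' @return The p-value.
#' @examples
#' exact_binomial_two_tailed(52, 80) # < 0.01
#' exact_binomial_two_tailed(51, 80) # > 0.01
#' @export
exact_binomial_two_tailed <- function(k, n, p0 = 0.5) {
  stopifnot(k >= 0, k <= n, p0 > 0, p0 < 1)
  lower <- stats::pbinom(k, n, p0)
  upper <- stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
  min(1, 2 * min(lower, upper))
}

#' Two-sample t-test from summary statistics
#'
#' Computes a two-sample t-test from group means, standard deviations and
#' sizes, either with pooled variance (`df = n1 + n2 - 2`) or with Welch's
#' unequal-variance form and Satterthwaite degrees of freedom (possibly
#' fractional). Useful for reproducing tests from printed group summaries
#' when raw data are unavailable.
#'
#' @param mean1,sd1,n1 Summary statistics of group 1.
#' @param mean2,sd2,n2 Summary statistics of group 2.
#' @param variant `"pooled"` or `"welch"`.
#' @return A one-row tibble with `t`, `df` and `p_value` (two-sided).
#' @examples
#' two_sample_t_summary(21.1, 5.3, 48, 15.1, 4.5, 39) # t ~= 5.61, df 85
#' @export
two_sample_t_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                                 variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  stopifnot(n1 >= 2, n2 >= 2, sd1 > 0, sd2 > 0)
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  if (variant == "pooled") {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    t <- (mean1 - mean2) / sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  tibble::tibble(
    t = t, df = df,
    p_value = 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  )
}

#' Correlation with a two-sided p-value
#'
#' Pearson product-moment or Spearman rank correlation. The Spearman
#' p-value uses the large-sample approximation so tied ranks are handled.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param method `"pearson"` or `"spearman"`.
#' @return A one-row tibble with `r` and `p_value`.
#' @examples
#' correlation(1:6, c(2, 1, 4, 3, 6, 5), method = "spearman")
#' @export
correlation <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation is undefined for zero-variance input", call. = FALSE)
  }
  res <- suppressWarnings(
    stats::cor.test(x, y, method = method, exact = FALSE)
  )
  tibble::tibble(r = unname(res$estimate), p_value = res$p.value)
}

#' Bonferroni-corrected significance level
#'
#' @param alpha Family-wise significance level.
#' @param m Number of comparisons.
#' @return `alpha / m`.
#' @export
bonferroni_alpha <- function(alpha, m) {
  stopifnot(alpha > 0, alpha < 1, m >= 1)
  alpha / m
}
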