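# Exact nonparametric tests by complete enumeration of the null.
#
# At cohort sizes of a handful of subjects, asymptotic rank-test p-values are
# unreliable, so the null distributions here are enumerated in full: every
# sign assignment for the signed-rank test, every group assignment for the
# Mann-Whitney test. Ties get the standard conventions (mid-ranks; half-count
# of tied pairs in U), zero differences are dropped before ranking. Every
# exact p-value is a ratio of integer counts.
#
# Doubling all ranks makes the mid-rank statistics integer-valued, so the
# null counts accumulate exactly (the enumeration is a subset-sum count, not
# a floating-point tabulation).

#' Group comparison result
#'
#' Common container for the package's statistical tests.
#'
#' @param test test name.
#' @param statistic observed statistic (W, U or r).
#' @param estimate effect summary: median of paired differences, the two
#'   group medians, or the correlation.
#' @param p_value p-value in (0, 1].
#' @param sidedness `"one"` or `"two"`.
#' @param n sample size(s).
#' @param p_num,p_den for exact tests, the integer count and total making up
#'   `p_value = p_num / p_den` (possibly capped at 1 after doubling).
#' @return Object of class `group_comparison`.
#' @export
group_comparison <- function(test, statistic, estimate, p_value, sidedness,
                             n, p_num = NA_integer_, p_den = NA_integer_) {
  stopifnot(p_value > 0, p_value <= 1)
  structure(list(test = test, statistic = statistic, estimate = estimate,
                 p_value = p_value, sidedness = sidedness, n = n,
                 p_num = p_num, p_den = p_den),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  est <- paste(format(round_half_up(unlist(x$estimate), 3), nsmall = 3),
               collapse = " / ")
  cat(sprintf("%s: statistic = %s, estimate = %s, %s-sided p = %s (n = %s)\n",
              x$test, format(x$statistic), est, x$sidedness,
              sprintf("%.4f", round_half_up(x$p_value, 4)),
              paste(x$n, collapse = ", ")))
  invisible(x)
}

# Distribution of sum(chosen doubled ranks) over all 2^n sign assignments,
# as exact integer counts indexed by value 0..sum(r2).
signed_rank_null_counts <- function(r2) {
  total <- sum(r2)
  counts <- numeric(total + 1)
  counts[1] <- 1
  for (r in r2) {
    shifted <- c(rep(0, r), counts[seq_len(total + 1 - r)])
    counts <- counts + shifted
  }
  counts  # sums to 2^n
}

#' Exact Wilcoxon matched-pairs signed-rank test
#'
#' Computes `W`, the sum of ranks of the positive differences `d = x - y`
#' (mid-ranks for tied magnitudes, zero differences dropped), and its exact
#' p-value from the complete null distribution over all `2^n` equally likely
#' sign assignments. The two-sided p doubles the smaller tail (capped at 1);
#' the one-sided p takes the tail in the direction of the observed effect.
#'
#' @param x,y paired samples of equal length (n >= 2 after dropping zero
#'   differences; differences must not all be zero).
#' @param sidedness `"two"` (default) or `"one"`.
#' @return A [group_comparison()]; `estimate$median_of_differences` is the
#'   sample median of `x - y` (computed before dropping zeros).
#' @export
wilcoxon_signed_rank_exact <- function(x, y, sidedness = c("two", "one")) {
  sidedness <- match.arg(sidedness)
  if (length(x) != length(y)) stop_input("x and y must be paired (equal length)")
  if (length(x) < 2) stop_input("need at least 2 pairs")
  d <- x - y
  med <- stats::median(d)
  d <- d[d != 0]
  if (!length(d)) stop_estimation("all paired differences are zero")
  n <- length(d)
  r <- rank(abs(d))              # mid-ranks
  r2 <- as.integer(round(2 * r)) # doubled ranks are integers
  w2 <- sum(r2[d > 0])           # doubled W
  counts <- signed_rank_null_counts(r2)
  total <- sum(counts)           # 2^n
  ge <- sum(counts[(w2 + 1):length(counts)])
  le <- sum(counts[seq_len(w2 + 1)])
  if (sidedness == "two") {
    num <- min(2 * min(ge, le), total)
  } else {
    num <- min(ge, le)
  }
  group_comparison(test = "wilcoxon_signed_rank_exact",
                   statistic = c(W = w2 / 2),
                   estimate = list(median_of_differences = med),
                   p_value = num / total, sidedness = sidedness,
                   n = n, p_num = num, p_den = total)
}

#' Exact Mann-Whitney U test
#'
#' `U` counts the pairs where an A value exceeds a B value, plus half the
#' tied pairs. The exact p-value enumerates all `choose(na + nb, na)` ways of
#' assigning the pooled values to the groups (equivalently, all subsets of
#' the pooled mid-ranks). Sidedness conventions as in
#' [wilcoxon_signed_rank_exact()].
#'
#' @param a,b group samples (each nonempty).
#' @param sidedness `"two"` (default) or `"one"`.
#' @return A [group_comparison()]; `estimate` holds the two group medians.
#' @export
mann_whitney_exact <- function(a, b, sidedness = c("two", "one")) {
  sidedness <- match.arg(sidedness)
  na <- length(a); nb <- length(b)
  if (na < 1 || nb < 1) stop_input("both groups must be nonempty")
  if (choose(na + nb, na) > 2e6) {
    stop_estimation("group sizes too large for complete enumeration")
  }
  pooled <- c(a, b)
  r2 <- as.integer(round(2 * rank(pooled)))   # doubled mid-ranks
  # doubled U = sum of doubled A-ranks minus na(na+1)
  u2_obs <- sum(r2[seq_len(na)]) - na * (na + 1L)
  subsets <- utils::combn(length(pooled), na)
  ranksums <- colSums(matrix(r2[subsets], nrow = na))
  u2_null <- ranksums - na * (na + 1L)
  total <- ncol(subsets)
  ge <- sum(u2_null >= u2_obs)
  le <- sum(u2_null <= u2_obs)
  if (sidedness == "two") {
    num <- min(2 * min(ge, le), total)
  } else {
    num <- min(ge, le)
  }
  group_comparison(test = "mann_whitney_exact",
                   statistic = c(U = u2_obs / 2),
                   estimate = list(median_a = stats::median(a),
                                   median_b = stats::median(b)),
                   p_value = num / total, sidedness = sidedness,
                   n = c(na, nb), p_num = num, p_den = total)
}

#' Pearson correlation test
#'
#' Product-moment correlation with the classical t-based p-value
#' (`t = r sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom), via
#' [stats::cor.test()]. One-sided tests take the direction of the observed
#' correlation.
#'
#' @param x,y numeric vectors of equal length, n >= 3, nonzero variance.
#' @param sidedness `"two"` (default) or `"one"`.
#' @return A [group_comparison()] with `statistic = r`.
#' @export
pearson_correlation <- function(x, y, sidedness = c("two", "one")) {
  sidedness <- match.arg(sidedness)
  if (length(x) != length(y)) stop_input("x and y must have equal length")
  if (length(x) < 3) stop_input("need n >= 3 for a correlation test")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_estimation("zero variance: correlation undefined")
  }
  r <- stats::cor(x, y)
  alt <- if (sidedness == "two") "two.sided" else if (r >= 0) "greater" else "less"
  ct <- stats::cor.test(x, y, alternative = alt, method = "pearson")
  group_comparison(test = "pearson_correlation",
                   statistic = c(r = unname(ct$estimate)),
                   estimate = list(r = unname(ct$estimate)),
                   p_value = max(ct$p.value, .Machine$double.xmin),
                   sidedness = sidedness, n = length(x))
}
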