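#' Two-sided Mann-Whitney U test p-value
#'
#' Exact p-value from the permutation distribution of U when the samples
#' contain no ties (the relevant case for continuous measurements); with
#' ties, the mid-rank statistic with tie-corrected normal approximation is
#' used. Two samples that are completely identical in value give p = 1.
#'
#' @param x,y numeric samples, each of length >= 2.
#' @return p-value in `[0, 1]`.
#' @export
#' @examples
#' mann_whitney_two_sided(c(1, 2), c(3, 4))  # 1/3, full separation at n = 2
mann_whitney_two_sided <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop("each sample must contain at least 2 values")
  pooled <- c(x, y)
  if (all(pooled == pooled[1])) return(1)
  ties <- anyDuplicated(pooled) > 0
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = !ties, correct = TRUE)$p.value)
}

#' Pairwise VOI-size tests with Bonferroni correction
#'
#' Runs the two-sided Mann-Whitney test for the three VOI-size pairs of a
#' feature's measurement table and applies the Bonferroni correction for the
#' three comparisons.
#'
#' @param table numeric n x 3 matrix: rows = scans, columns = VOI sizes
#'   (smallest to largest).
#' @param alpha significance level for the adjusted p-values (default 0.05).
#' @return data.frame with one row per pair: `pair`, `p_raw`, `p_adj`
#'   (Bonferroni, capped at 1) and `significant` (`p_adj < alpha`).
#' @export
pairwise_voi_tests <- function(table, alpha = 0.05) {
  table <- as.matrix(table)
  if (ncol(table) != 3L) stop("`table` must have exactly 3 VOI-size columns")
  if (nrow(table) < 2L) stop("`table` must have at least 2 scans (rows)")
  pairs <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  labs <- if (!is.null(colnames(table)))
    vapply(pairs, function(p) paste(colnames(table)[p], collapse = "-"), "")
  else vapply(pairs, function(p) paste(p, collapse = "-"), "")
  p_raw <- vapply(pairs, function(p)
    mann_whitney_two_sided(table[, p[1]], table[, p[2]]), 0)
  p_adj <- stats::p.adjust(p_raw, method = "bonferroni")
  data.frame(pair = labs, p_raw = p_raw, p_adj = p_adj,
             significant = p_adj < alpha)
}

#' Overall concordance correlation coefficient
#'
#' Agreement of `J` measurement conditions (columns) over `n` subjects
#' (rows), the multi-rater generalization of Lin's concordance correlation
#' coefficient:
#' \deqn{OCCC = \frac{2 \sum_{j<k} \sigma_{jk}}{(J-1) \sum_j \sigma_j^2 +
#'   \sum_{j<k} (\mu_j - \mu_k)^2}}
#' with moments in the 1/n convention. For `J = 2` this reduces exactly to
#' Lin's pairwise CCC. When the denominator vanishes (all columns constant
#' and equal) the coefficient is defined as 1 with attribute
#' `degenerate = TRUE`.
#'
#' @param table numeric n x J matrix, `n >= 2`, `J >= 2`, no missing cells.
#' @return Scalar in `[-1, 1]`.
#' @export
#' @examples
#' occc(cbind(1:5, 1:5))              # identical columns: 1
#' occc(cbind(c(1, 2), c(2, 1)))      # perfectly discordant: -1
occc <- function(table) {
  table <- as.matrix(table)
  n <- nrow(table)
  J <- ncol(table)
  if (n < 2L || J < 2L) stop("`table` must be at least 2 x 2")
  if (anyNA(table)) stop("`table` must have no missing cells")
  mu <- colMeans(table)
  S <- stats::cov(table) * (n - 1) / n
  num <- 2 * sum(S[upper.tri(S)])
  den <- (J - 1) * sum(diag(S)) +
    sum(outer(mu, mu, "-")[upper.tri(S)]^2)
  if (den == 0) return(structure(1, degenerate = TRUE))
  num / den
}

#' Classify OCCC stability
#'
#' A feature is called stable across conditions when its OCCC reaches the
#' excellent-agreement cutoff (boundary inclusive).
#'
#' @param occc_value OCCC value(s) in `[-1, 1]`.
#' @param cutoff stability threshold, default 0.85.
#' @return Logical of the same length.
#' @export
classify_stability <- function(occc_value, cutoff = 0.85) {
  if (any(occc_value < -1 - 1e-12 | occc_value > 1 + 1e-12, na.rm = TRUE))
    stop("OCCC values must lie in [-1, 1]")
  occc_value >= cutoff
}
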