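#' Dice similarity coefficient
#'
#' Spatial overlap between two binary masks: `2|A n B| / (|A| + |B|)`,
#' ranging from 0 (no overlap) to 1 (perfect overlap). When both masks
#' are empty the coefficient is undefined and NA is returned (flagged,
#' not zero); when exactly one is empty it is 0.
#'
#' @param a,b logical/binary arrays of identical shape.
#' @return Numeric in [0, 1], or NA when both masks are empty.
#' @examples
#' a <- array(c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE), c(6, 1, 1))
#' b <- array(c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE), c(6, 1, 1))
#' computeDice(a, b) # 2*3 / (4+6) = 0.6
#' @export
computeDice <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("mask shapes differ")
  a <- a > 0; b <- b > 0
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0L) return(NA_real_)
  2 * sum(a & b) / (na + nb)
}

#' Bland-Altman agreement of paired volume measurements
#'
#' Mean difference (bias), 95% limits of agreement (bias +/- 1.96 sample
#' SD of the differences), and the bias as a percentage of the mean of
#' the pairwise means ("percent over/underestimation relative to the
#' mean of both methods").
#'
#' @param vTest,vRef equal-length numeric vectors (mL), n >= 2.
#' @return List with `bias`, `loaLow`, `loaHigh`, `percentBias`,
#'   `sdDiff`, `n`.
#' @examples
#' blandAltman(c(10, 20, 30), c(8, 22, 31))
#' @export
blandAltman <- function(vTest, vRef) {
  if (length(vTest) != length(vRef)) stop("paired vectors must have equal length")
  n <- length(vTest)
  if (n < 2L) stop("need at least 2 pairs (SD undefined otherwise)")
  d <- vTest - vRef
  bias <- mean(d)
  s <- stats::sd(d)
  m <- mean((vTest + vRef) / 2)
  list(bias = bias, loaLow = bias - 1.96 * s, loaHigh = bias + 1.96 * s,
       percentBias = if (abs(m) > 0) 100 * bias / m else NA_real_,
       sdDiff = s, n = n)
}

#' Cohen's kappa (unweighted or quadratic-weighted)
#'
#' Chance-corrected agreement for a k x k cross-rater contingency table:
#' `kappa = 1 - sum(w * observed) / sum(w * expected)` with disagreement
#' weights `w[i,j] = (i != j)` (unweighted) or `((i-j)/(k-1))^2`
#' (quadratic), and expected proportions from the marginal products. For
#' k = 2 the two weightings coincide. Degenerate marginals (zero
#' expected disagreement) yield NA.
#'
#' @param table k x k numeric matrix of counts, rater 1 in rows.
#' @param weighting "none" or "quadratic".
#' @return Numeric kappa, or NA when undefined.
#' @examples
#' cohenKappa(matrix(c(20, 10, 5, 15), 2), "none") # 0.4
#' @export
cohenKappa <- function(table, weighting = c("none", "quadratic")) {
  weighting <- match.arg(weighting)
  table <- as.matrix(table)
  k <- nrow(table)
  if (k < 2L || ncol(table) != k) stop("need a square table with k >= 2 categories")
  n <- sum(table)
  if (n <= 0) stop("table total must be positive")
  p <- table / n
  pe <- outer(rowSums(p), colSums(p))
  idx <- outer(seq_len(k), seq_len(k), "-")
  w <- if (weighting == "none") (idx != 0) * 1 else (idx / (k - 1))^2
  eDis <- sum(w * pe)
  if (eDis <= 0) return(NA_real_)
  1 - sum(w * p) / eDis
}
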