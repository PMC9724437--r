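# Shared statistical kernels. These small functions are the contract the
# rest of the pipeline builds on, so each has a brute-force oracle in the
# test suite.

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up adjustment; monotone in p. Thin wrapper over
#' [stats::p.adjust()] so that every stage corrects multiplicity the same
#' way. `NA` p-values stay `NA` and do not count toward `m`.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return numeric vector of q-values.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("p-values outside [0, 1]")
  p.adjust(p, method = "BH")
}

#' Spearman rank correlation
#'
#' Average ranks for ties (the convention used throughout the pipeline).
#' Pairs with NA in either vector are dropped. Returns NA when either
#' vector is constant after NA removal (undefined rank correlation).
#'
#' @param x,y numeric vectors of equal length.
#' @return Spearman's rho, or NA if undefined.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L || sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y, method = "spearman")
}

#' First-order partial Spearman correlation
#'
#' Rank-transforms all three vectors (average ranks for ties), then applies
#' the first-order partial correlation formula
#' \deqn{\rho_{xy\cdot z} = \frac{\rho_{xy} - \rho_{xz}\rho_{yz}}
#'   {\sqrt{(1 - \rho_{xz}^2)(1 - \rho_{yz}^2)}}}
#' Used to correlate two genes' expression while controlling for tumor
#' purity.
#'
#' @param x,y,z numeric vectors of equal length (>= 10); `z` is the
#'   covariate and must not be constant.
#' @return partial rho, or NA if undefined (e.g. `|rho_xz| = 1`).
#' @export
partial_spearman <- function(x, y, z) {
  n <- length(x)
  if (length(y) != n || length(z) != n) stopf("x, y, z must have equal length")
  if (n < 10L) stopf("need >= 10 observations, got %d", n)
  if (sd(z) == 0) stopf("covariate is constant")
  rxy <- spearman_rho(x, y)
  rxz <- spearman_rho(x, z)
  ryz <- spearman_rho(y, z)
  if (anyNA(c(rxy, rxz, ryz))) return(NA_real_)
  if (abs(rxz) >= 1 - 1e-12 || abs(ryz) >= 1 - 1e-12) return(NA_real_)
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}

#' One-sided exact binomial tail probabilities
#'
#' The enrichment engine behind hallmark assignment, group
#' overrepresentation and developmental-stage tests. `"greater"` returns
#' P(X >= k), `"less"` returns P(X <= k), for X ~ Binomial(n, p0).
#'
#' @param k observed successes.
#' @param n trials.
#' @param p0 null success probability.
#' @param alternative `"greater"` (excess) or `"less"` (depletion).
#' @return tail probability.
#' @export
binom_tail <- function(k, n, p0, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(k >= 0, k <= n, p0 >= 0, p0 <= 1)
  if (alternative == "greater") pbinom(k - 1, n, p0, lower.tail = FALSE)
  else pbinom(k, n, p0)
}

# Odds ratio of the 2x2 table (k in-set partners, n partners, K set size,
# N universe size); +Inf when a denominator cell is empty but k > 0.
odds_ratio_2x2 <- function(k, n, K, N) {
  a <- k; b <- n - k; c <- K - k; d <- N - n - K + k
  if (b == 0 || c == 0) return(if (a > 0) Inf else NaN)
  (a * d) / (b * c)
}
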