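# Independent brute-force oracles. These deliberately use the slowest,
# most literal formulation of each statistic so they share no code path
# with the package implementations they check.

# BH step-up, O(m^2): q_i = min over j with p_j >= p_i of p_j * m / rank_j
oracle_bh <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "min")
  vapply(seq_len(m), function(i) {
    cand <- vapply(seq_len(m), function(j)
      if (p[j] >= p[i]) p[j] * m / rank(p, ties.method = "max")[j] else Inf,
      numeric(1))
    min(1, min(cand))
  }, numeric(1))
}

# Spearman as explicit rank transform + textbook Pearson formula
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# Partial Spearman via residual regression: regress ranks on covariate
# ranks, correlate the residuals
oracle_partial_spearman <- function(x, y, z) {
  rx <- rank(x); ry <- rank(y); rz <- rank(z)
  ex <- residuals(lm(rx ~ rz))
  ey <- residuals(lm(ry ~ rz))
  cor(ex, ey)
}

# One-sided binomial tail as an explicit sum of point masses
oracle_binom_tail <- function(k, n, p0, upper = TRUE) {
  ks <- if (upper) k:n else 0:k
  sum(choose(n, ks) * p0^ks * (1 - p0)^(n - ks))
}

# ssGSEA raw score as an explicit double loop over walk positions
oracle_ssgsea <- function(ranks, gene_set, alpha = 0.25) {
  genes <- names(ranks)
  ord <- order(-ranks, genes)
  in_set <- genes[ord] %in% gene_set
  r <- ranks[ord]
  denom_in <- sum(r[in_set]^alpha)
  n_out <- sum(!in_set)
  es <- 0
  for (i in seq_along(ord)) {
    p_in <- 0; p_out <- 0
    for (j in seq_len(i)) {
      if (in_set[j]) p_in <- p_in + r[j]^alpha / denom_in
      else p_out <- p_out + 1 / n_out
    }
    es <- es + (p_in - p_out)
  }
  unname(es)
}

# Cox partial likelihood for a single predictor with all-distinct event
# times, maximized by Newton iterations on the analytic score/Hessian
oracle_cox_beta <- function(time, event, x, tol = 1e-10) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; x <- x[ord]
  beta <- 0
  for (it in 1:100) {
    U <- 0; I <- 0
    for (i in which(event == 1)) {
      risk <- which(time >= time[i])
      wr <- exp(beta * x[risk])
      xb <- sum(x[risk] * wr) / sum(wr)
      x2b <- sum(x[risk]^2 * wr) / sum(wr)
      U <- U + x[i] - xb
      I <- I + (x2b - xb^2)
    }
    step <- U / I
    beta <- beta + step
    if (abs(step) < tol) break
  }
  beta
}

# Common-dependency flags by explicit per-line sort and quantile
oracle_common_dependency <- function(scores, percentile = 0.9,
                                     top_fraction = 0.062) {
  G <- nrow(scores)
  nr <- matrix(NA_real_, G, ncol(scores), dimnames = dimnames(scores))
  for (j in seq_len(ncol(scores))) {
    ord <- sort(scores[, j], index.return = TRUE)$ix
    rk <- numeric(G); rk[ord] <- seq_len(G)
    # average tied ranks explicitly
    for (v in unique(scores[, j])) {
      idx <- which(scores[, j] == v)
      rk[idx] <- mean(rk[idx])
    }
    nr[, j] <- rk / G
  }
  stat <- apply(nr, 1, function(r) quantile(r, percentile, type = 7, names = FALSE))
  n_top <- ceiling(top_fraction * G)
  flagged <- rownames(scores)[order(stat, rownames(scores))][seq_len(n_top)]
  setNames(rownames(scores) %in% flagged, rownames(scores))
}
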