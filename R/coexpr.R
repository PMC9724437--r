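# Purity-controlled coexpression partner discovery and binomial gene-set
# functional assignment — the annotation route for uncharacterized genes.

# Vectorized partial Spearman of one query against many genes, controlling
# for a covariate: all vectors are rank-transformed once, then the
# first-order partial-correlation formula is applied column-wise.
partial_spearman_vs_matrix <- function(query, mat, covariate) {
  rq <- rank(query); rz <- rank(covariate)
  rm <- apply(mat, 1, rank)                      # samples x genes
  rxy <- suppressWarnings(as.numeric(cor(rq, rm)))
  rxz <- cor(rq, rz)
  ryz <- suppressWarnings(as.numeric(cor(rz, rm)))
  den <- sqrt((1 - rxz^2) * (1 - ryz^2))
  out <- (rxy - rxz * ryz) / den
  out[!is.finite(out)] <- NA_real_
  setNames(out, rownames(mat))
}

#' Coexpression partners of a query gene across cancer types
#'
#' Within each cancer type where the query passes the expression filter,
#' the partial Spearman correlation (controlling for tumor purity) of the
#' query against every other retained gene is computed on tumor samples;
#' the per-gene median across contributing cancers is thresholded at
#' `|rho| >= cutoff`, and partners on the query's own chromosome are
#' removed (chromosomal proximity breeds function-free coexpression).
#' Queries contributing fewer than `min_cancers` cancers get no call.
#'
#' @param query gene id.
#' @param cohorts list of per-cancer bundles with `tpm`, `samples`,
#'   `purity` (as from [generate_cohort()]).
#' @param universe retained gene ids.
#' @param chrom_of named character vector gene -> chromosome.
#' @param cutoff absolute median-correlation cutoff (default 0.4).
#' @param min_cancers minimum contributing cancers (default 3).
#' @param zero_fraction per-cancer expression filter (default 0.2).
#' @param log logbook (optional).
#' @return list with `query`, `partners` (character), `median_rho`
#'   (named over all candidate genes), `n_cancers`.
#' @export
find_partners <- function(query, cohorts, universe, chrom_of, cutoff = 0.4,
                          min_cancers = 3L, zero_fraction = 0.2, log = NULL) {
  if (!query %in% universe) stopf("query %s not in retained universe", query)
  others <- setdiff(universe, query)
  per_cancer <- list()
  for (ct in names(cohorts)) {
    cc <- cohorts[[ct]]
    tum <- cc$samples$sample_id[cc$samples$group == "tumor"]
    tpm <- cc$tpm[, tum, drop = FALSE]
    keep <- expressed_in_cancer(tpm, zero_fraction)
    if (!isTRUE(keep[query])) {
      log_entry(log, "find_partners: %s fails expression filter in %s, cancer skipped",
                query, ct)
      next
    }
    cand <- intersect(others, rownames(tpm)[keep])
    purity <- cc$purity[tum]
    rho <- partial_spearman_vs_matrix(log2(tpm[query, ] + 1),
                                      log2(tpm[cand, , drop = FALSE] + 1),
                                      purity)
    per_cancer[[ct]] <- rho
  }
  if (length(per_cancer) < min_cancers) {
    log_entry(log, "find_partners: %s contributes only %d cancers (< %d), no call",
              query, length(per_cancer), min_cancers)
    return(list(query = query, partners = character(0),
                median_rho = setNames(numeric(0), character(0)),
                n_cancers = length(per_cancer)))
  }
  all_genes <- Reduce(union, lapply(per_cancer, names))
  med <- vapply(all_genes, function(g)
    median(unlist(lapply(per_cancer, function(r) r[g])), na.rm = TRUE),
    numeric(1))
  partners <- names(med)[!is.na(med) & abs(med) >= cutoff]
  partners <- partners[chrom_of[partners] != chrom_of[query]]
  list(query = query, partners = partners, median_rho = med,
       n_cancers = length(per_cancer))
}

#' Assign gene sets to a query from its coexpression partners
#'
#' For each set, a one-sided binomial test of `k` in-set partners among
#' `n` partners with success probability `|set| / |universe|`, plus the
#' odds ratio of the 2x2 table. A set is assigned when the odds ratio
#' exceeds 1 and p < alpha. The query itself is removed from the universe
#' and sets are intersected with it.
#'
#' @param partner_set list from [find_partners()].
#' @param sets named list of gene sets (GMT).
#' @param universe retained gene ids.
#' @param alpha significance cutoff (default 0.05).
#' @param exclude optional gene ids to drop from partners, sets and
#'   universe before testing (e.g. E2F-target-regulated genes for the
#'   robustness rerun).
#' @return data frame: `query`, `set`, `k`, `n`, `set_size`, `p0`,
#'   `odds_ratio`, `p`, `assigned`.
#' @export
assign_sets <- function(partner_set, sets, universe, alpha = 0.05,
                        exclude = NULL) {
  uni <- setdiff(universe, c(partner_set$query, exclude))
  partners <- setdiff(intersect(partner_set$partners, uni), exclude)
  n <- length(partners)
  out <- lapply(names(sets), function(nm) {
    s <- intersect(sets[[nm]], uni)
    K <- length(s)
    k <- length(intersect(partners, s))
    p0 <- K / length(uni)
    p <- if (n == 0L) NA_real_ else binom_tail(k, n, p0, "greater")
    or <- if (n == 0L) NaN else odds_ratio_2x2(k, n, K, length(uni))
    data.frame(query = partner_set$query, set = nm, k = k, n = n,
               set_size = K, p0 = p0, odds_ratio = or, p = p,
               assigned = !is.na(p) && !is.nan(or) && or > 1 && p < alpha,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Overrepresentation of a gene group in membership lists
#'
#' One-sided binomial test of the group's membership fraction against the
#' background universe fraction, per set, with Benjamini-Hochberg FDR
#' across sets. Covers both GMT collections and direct curated-list
#' membership tests (e.g. a curated cell-cycle gene list).
#'
#' @param group gene ids (subset of `universe`).
#' @param sets named list of gene sets, or a single character vector
#'   (treated as one set named `"set"`).
#' @param universe background gene ids.
#' @return data frame: `set`, `k`, `n`, `p0`, `observed_fraction`,
#'   `odds_ratio`, `p`, `fdr`, `enriched`.
#' @export
group_overrepresentation <- function(group, sets, universe) {
  if (!is.list(sets)) sets <- list(set = sets)
  group <- intersect(group, universe)
  n <- length(group)
  if (n == 0L) stopf("empty group after intersecting with universe")
  out <- lapply(names(sets), function(nm) {
    s <- intersect(sets[[nm]], universe)
    p0 <- length(s) / length(universe)
    k <- length(intersect(group, s))
    data.frame(set = nm, k = k, n = n, p0 = p0,
               observed_fraction = k / n,
               odds_ratio = odds_ratio_2x2(k, n, length(s), length(universe)),
               p = binom_tail(k, n, p0, "greater"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$fdr <- bh_fdr(res$p)
  res$enriched <- res$fdr < 0.05 & res$observed_fraction > res$p0
  res
}
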