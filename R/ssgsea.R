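# From-scratch single-sample GSEA: per-sample gene-set scores from the
# difference between the weighted in-set and uniform out-of-set rank
# ECDFs, plus the within-group range rescaling used to compare tumor and
# normal samples.

#' Rank-normalize one sample's expression
#'
#' Ranks 1..G with average ranks for ties; the highest expression gets the
#' highest rank, so the score depends only on within-sample ordering
#' (invariant under any strictly monotone transform).
#'
#' @param x numeric expression vector (>= 2 genes), names kept.
#' @return numeric vector of ranks.
#' @export
rank_normalize <- function(x) {
  if (length(x) < 2L) stopf("need >= 2 genes")
  rank(x, ties.method = "average")
}

#' Raw single-sample enrichment score for one gene set
#'
#' Genes are walked in decreasing rank (ties broken by gene name for
#' determinism). At each position the running in-set ECDF — weighted by
#' rank^alpha — minus the running uniform out-of-set ECDF is accumulated;
#' the score is the *sum* of these differences over all positions (not
#' the maximum deviation). Positive scores mean the set is concentrated
#' among highly expressed genes.
#'
#' @param ranks named numeric vector from [rank_normalize()].
#' @param gene_set character vector; must be a proper nonempty subset of
#'   `names(ranks)`.
#' @param alpha rank-weighting exponent (default 0.25).
#' @return raw enrichment score (numeric scalar).
#' @export
ssgsea_es <- function(ranks, gene_set, alpha = 0.25) {
  genes <- names(ranks)
  if (is.null(genes)) stopf("ranks must be named by gene")
  in_set <- genes %in% gene_set
  k <- sum(in_set)
  if (k == 0L || k == length(genes)) stopf("gene set must be a proper nonempty subset")
  ord <- order(-ranks, genes)
  in_o <- in_set[ord]
  r_o <- ranks[ord]
  w <- ifelse(in_o, r_o^alpha, 0)
  p_in <- cumsum(w) / sum(w)
  p_out <- cumsum(!in_o) / (length(genes) - k)
  sum(p_in - p_out)
}

#' Score a gene-set collection over every sample of a matrix
#'
#' @param expr genes x samples matrix (TPM or any monotone transform).
#' @param sets named list of gene sets.
#' @param alpha rank-weighting exponent.
#' @return data frame: `sample_id`, `set`, `es`.
#' @export
ssgsea_scores <- function(expr, sets, alpha = 0.25) {
  sets <- lapply(sets, intersect, x = rownames(expr))
  out <- lapply(colnames(expr), function(s) {
    r <- rank_normalize(expr[, s])
    names(r) <- rownames(expr)
    data.frame(sample_id = s, set = names(sets),
               es = vapply(sets, function(gs) ssgsea_es(r, gs, alpha), numeric(1)),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Rescale raw enrichment scores within each gene set and cancer type
#'
#' Per set (age group) within each cancer type, raw scores are divided by
#' the range (max - min) across that cancer's samples — making score
#' spreads comparable across sets — and the median of the cancer's
#' *normal* samples is subtracted, anchoring the normal median at 0.
#' Degenerate groups (zero range) are skipped with a logged reason.
#'
#' @param scores data frame from [ssgsea_scores()].
#' @param samples data frame with `sample_id`, `cancer_type`, `group`
#'   (`"tumor"`/`"normal"`).
#' @param log logbook (optional).
#' @return `scores` with `cancer_type`, `group` and `es_rescaled` columns
#'   (degenerate set/cancer combinations dropped).
#' @export
rescale_scores <- function(scores, samples, log = NULL) {
  m <- match(scores$sample_id, samples$sample_id)
  if (anyNA(m)) stopf("samples sheet missing %d score samples", sum(is.na(m)))
  scores$cancer_type <- samples$cancer_type[m]
  scores$group <- samples$group[m]
  parts <- split(scores, list(scores$set, scores$cancer_type), drop = TRUE)
  out <- lapply(parts, function(d) {
    if (!any(d$group == "tumor") || !any(d$group == "normal")) {
      log_entry(log, "rescale_scores: %s/%s lacks tumor or normal samples, skipped",
                d$set[1], d$cancer_type[1])
      return(NULL)
    }
    rng <- max(d$es) - min(d$es)
    if (rng == 0) {
      log_entry(log, "rescale_scores: constant scores for %s/%s, skipped",
                d$set[1], d$cancer_type[1])
      return(NULL)
    }
    e <- d$es / rng
    d$es_rescaled <- e - median(e[d$group == "normal"])
    d
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
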