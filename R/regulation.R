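# Attribution of expression changes to somatic copy number and promoter
# methylation via per-cancer Spearman correlations.

#' Filter methylation probes by missing-data fraction
#'
#' @param beta probes x samples matrix of beta values in `[0,1]` or NA.
#' @param max_na maximum tolerated NA fraction per probe (default 0.05,
#'   strict: a probe with *more* than 5% NA is removed).
#' @return character vector of retained probe ids.
#' @export
filter_probes <- function(beta, max_na = 0.05) {
  vals <- beta[!is.na(beta)]
  if (length(vals) && (min(vals) < 0 || max(vals) > 1))
    stopf("beta values must lie in [0, 1]")
  naf <- rowMeans(is.na(beta))
  rownames(beta)[naf <= max_na]
}

#' Annotate probes with strand-aware signed distance to the TSS
#'
#' Probe coordinates follow BED convention (0-based, half-open); a
#' single-CpG probe at `[start, start+1)` sits at 1-based position
#' `start + 1`. The signed distance is negative upstream of the TSS
#' (5' of the TSS on the coding strand) and positive downstream; the
#' promoter window keeps probes with `-upstream <= d <= downstream`.
#'
#' @param probes data frame with `probe_id`, `gene_id`, `start` (0-based).
#' @param catalog data frame with `gene_id`, `tss` (1-based), `strand`.
#' @param upstream,downstream window half-widths (defaults 1500 / 500 bp).
#' @return `probes` with `signed_dist` and `promoter` columns.
#' @export
annotate_promoter_probes <- function(probes, catalog,
                                     upstream = 1500L, downstream = 500L) {
  m <- match(probes$gene_id, catalog$gene_id)
  if (anyNA(m)) stopf("probes reference %d unknown genes", sum(is.na(m)))
  pos <- probes$start + 1L
  tss <- catalog$tss[m]
  plus <- catalog$strand[m] == "+"
  d <- ifelse(plus, pos - tss, tss - pos)
  probes$signed_dist <- d
  probes$promoter <- d >= -upstream & d <= downstream
  probes
}

#' Select one promoter probe per gene
#'
#' Among a gene's promoter-window probes, keeps the one with the most
#' negative Spearman correlation between beta value and the gene's
#' expression (ties broken by lexicographically smallest probe id).
#' Genes without promoter probes are dropped.
#'
#' @param probes annotated probes ([annotate_promoter_probes()]).
#' @param beta probes x samples beta matrix.
#' @param expr genes x samples expression matrix (same samples).
#' @return data frame `gene_id`, `probe_id`, `rho`.
#' @export
select_promoter_probe <- function(probes, beta, expr) {
  pr <- probes[probes$promoter & probes$probe_id %in% rownames(beta) &
                 probes$gene_id %in% rownames(expr), ]
  if (!nrow(pr)) return(data.frame(gene_id = character(0), probe_id = character(0),
                                   rho = numeric(0)))
  pr <- pr[order(pr$gene_id, pr$probe_id), ]
  pr$rho <- vapply(seq_len(nrow(pr)), function(i)
    spearman_rho(beta[pr$probe_id[i], ], expr[pr$gene_id[i], ]), numeric(1))
  pr <- pr[!is.na(pr$rho), ]
  keep <- !duplicated(pr$gene_id[order(pr$gene_id, pr$rho, pr$probe_id)])
  sel <- pr[order(pr$gene_id, pr$rho, pr$probe_id), ][keep, ]
  sel[c("gene_id", "probe_id", "rho")]
}

#' Correlate expression with a regulatory factor within one cancer type
#'
#' Spearman correlation (average-rank ties, pairwise-complete) of each
#' gene's tumor expression against its copy-number score or selected
#' promoter-probe beta value. Genes whose factor vector is constant are
#' excluded with a logged reason.
#'
#' @param expr genes x tumor-samples expression matrix.
#' @param fac matching factor matrix (same genes and samples).
#' @param factor_name `"SCNA"` or `"methylation"`.
#' @param cancer_type label copied into the result.
#' @param min_n minimum paired samples (default 10).
#' @param log logbook (optional).
#' @return data frame: `gene_id`, `cancer_type`, `factor`, `rho`.
#' @export
expr_factor_correlation <- function(expr, fac, factor_name, cancer_type = NA,
                                    min_n = 10L, log = NULL) {
  common <- intersect(rownames(expr), rownames(fac))
  if (ncol(expr) < min_n) stopf("need >= %d paired samples", min_n)
  rho <- vapply(common, function(g) {
    x <- expr[g, ]; y <- fac[g, ]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < min_n) return(NA_real_)
    if (sd(y[ok]) == 0) {
      log_entry(log, "expr_factor_correlation: %s constant %s vector, excluded",
                g, factor_name)
      return(NA_real_)
    }
    spearman_rho(x, y)
  }, numeric(1))
  out <- data.frame(gene_id = common, cancer_type = cancer_type,
                    factor = factor_name, rho = as.numeric(rho),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[!is.na(out$rho), ]
}

#' Flag strong regulatory correlations
#'
#' SCNA: strong when rho > cutoff; methylation: strong when rho < -cutoff
#' (both strict inequalities; a correlation exactly at the cutoff is not
#' strong).
#'
#' @param correlations data frame from [expr_factor_correlation()].
#' @param cutoff default 0.3 (0.4 is the stringent robustness setting).
#' @return input with a `strong` column.
#' @export
flag_strong <- function(correlations, cutoff = 0.3) {
  correlations$strong <- ifelse(correlations$factor == "SCNA",
                                correlations$rho > cutoff,
                                correlations$rho < -cutoff)
  correlations
}

#' Per-cancer, per-group proportions of strongly correlated genes
#'
#' @param correlations flagged correlations ([flag_strong()]).
#' @param groups named character vector: gene id -> group label (e.g. age
#'   class with the B-PSG/T-PSG split).
#' @return data frame of `cancer_type`, `factor`, `group`, `n`,
#'   `proportion`, plus cross-cancer medians in
#'   `attr(, "cross_cancer_median")`.
#' @export
strong_proportions <- function(correlations, groups) {
  correlations$group <- groups[correlations$gene_id]
  d <- correlations[!is.na(correlations$group), ]
  agg <- aggregate(strong ~ cancer_type + factor + group, data = d,
                   FUN = function(x) c(n = length(x), prop = mean(x)))
  out <- data.frame(agg[c("cancer_type", "factor", "group")],
                    n = agg$strong[, "n"], proportion = agg$strong[, "prop"])
  med <- aggregate(proportion ~ factor + group, data = out, FUN = median)
  attr(out, "cross_cancer_median") <- med
  out
}
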