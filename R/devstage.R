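# Developmental-stage assignment from a 12-stage cerebral time course and
# per-stage binomial enrichment of gene groups.

#' Per-stage median expression
#'
#' @param expr genes x samples matrix.
#' @param stage_map data frame `sample_id`, `stage` (every stage needs
#'   >= 2 samples).
#' @return genes x stages matrix of medians, columns ordered by stage.
#' @export
stage_medians <- function(expr, stage_map) {
  m <- match(colnames(expr), stage_map$sample_id)
  if (anyNA(m)) stopf("stage map missing %d samples", sum(is.na(m)))
  st <- stage_map$stage[m]
  tab <- table(st)
  if (any(tab < 2L)) stopf("every stage needs >= 2 replicates")
  stages <- sort(unique(st))
  out <- sapply(stages, function(s)
    apply(expr[, st == s, drop = FALSE], 1, median))
  colnames(out) <- as.character(stages)
  out
}

#' Remove weakly expressed genes from a developmental series
#'
#' A gene is removed iff *all* stage medians are strictly below the floor
#' (a gene exactly at the floor somewhere is kept).
#'
#' @param medians genes x stages matrix from [stage_medians()].
#' @param floor expression floor (default 0.2).
#' @return the filtered matrix.
#' @export
filter_low <- function(medians, floor = 0.2) {
  medians[apply(medians, 1, max) >= floor, , drop = FALSE]
}

#' Assign each gene to its preferentially upregulated stage
#'
#' Stage medians are transformed (log2(x+1)) and Z-scored per gene
#' (sample SD, n-1 denominator). A gene is assigned to its argmax stage
#' only when the maximal Z exceeds `z_cutoff` (1.2, the 90% quantile of
#' the Z distribution); constant rows (SD 0) and ties for the maximum are
#' unassigned (ties logged).
#'
#' @param medians genes x stages matrix.
#' @param z_cutoff assignment cutoff (default 1.2, strict inequality).
#' @param log_transform apply log2(x+1) before Z-scoring (default TRUE).
#' @param log logbook (optional).
#' @return data frame: `gene_id`, `stage` (NA when unassigned), `z_max`,
#'   plus the Z matrix in `attr(, "z")`.
#' @export
assign_stage <- function(medians, z_cutoff = 1.2, log_transform = TRUE,
                         log = NULL) {
  x <- if (log_transform) log2(medians + 1) else medians
  mu <- rowMeans(x)
  sdv <- apply(x, 1, sd)
  z <- (x - mu) / sdv
  z[sdv == 0, ] <- NA_real_
  zmax <- apply(z, 1, max)
  arg <- apply(z, 1, function(r) if (anyNA(r)) 1L else which.max(r))
  ties <- apply(z, 1, function(r) !anyNA(r) && sum(r == max(r)) > 1L)
  for (g in rownames(medians)[ties])
    log_entry(log, "assign_stage: %s tied maxima, unassigned", g)
  stage <- ifelse(is.na(zmax) | zmax <= z_cutoff | ties, NA_integer_,
                  as.integer(colnames(medians))[arg])
  out <- data.frame(gene_id = rownames(medians), stage = stage, z_max = zmax,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "z") <- z
  out
}

#' Per-stage binomial excess/depletion of a gene group
#'
#' For each stage, one-sided binomial tests in both directions of the
#' group's assigned-stage proportion against a background proportion
#' (by default the universe's own per-stage proportion; a fixed
#' background can be supplied for within-class tests). Trials are the
#' group's assigned genes; Benjamini-Hochberg FDR is applied across the
#' 12 stages x 2 directions.
#'
#' @param group gene ids.
#' @param assignments data frame from [assign_stage()] over the universe.
#' @param background optional named numeric of per-stage background
#'   proportions (names = stage); default computed from `assignments`.
#' @param alpha_fdr significance cutoff (default 0.1).
#' @return data frame: `stage`, `k`, `n`, `p0`, `excess_p`, `depletion_p`,
#'   `excess_fdr`, `depletion_fdr`, `significant`.
#' @export
stage_enrichment <- function(group, assignments, background = NULL,
                             alpha_fdr = 0.1) {
  assigned <- assignments[!is.na(assignments$stage), ]
  stages <- sort(unique(assignments$stage[!is.na(assignments$stage)]))
  if (is.null(background)) {
    background <- table(factor(assigned$stage, levels = stages)) / nrow(assigned)
    background <- setNames(as.numeric(background), as.character(stages))
  }
  grp <- assigned[assigned$gene_id %in% group, ]
  n <- nrow(grp)
  if (n == 0L) stopf("no group gene carries a stage assignment")
  out <- lapply(stages, function(s) {
    k <- sum(grp$stage == s)
    p0 <- background[[as.character(s)]]
    data.frame(stage = s, k = k, n = n, p0 = p0,
               excess_p = binom_tail(k, n, p0, "greater"),
               depletion_p = binom_tail(k, n, p0, "less"))
  })
  res <- do.call(rbind, out)
  q <- bh_fdr(c(res$excess_p, res$depletion_p))
  res$excess_fdr <- q[seq_len(nrow(res))]
  res$depletion_fdr <- q[nrow(res) + seq_len(nrow(res))]
  res$significant <- pmin(res$excess_fdr, res$depletion_fdr) < alpha_fdr
  res
}

#' Overlap of stage-assigned genes with positive-selection gene lists
#'
#' Runs the same binomial engine per supplied list (e.g. genes under
#' positive selection in coding or promoter regions).
#'
#' @param assignments data frame from [assign_stage()].
#' @param selection_lists named list of gene-id character vectors.
#' @param alpha_fdr significance cutoff (default 0.1).
#' @return named list of [stage_enrichment()] tables.
#' @export
selection_overlap <- function(assignments, selection_lists, alpha_fdr = 0.1) {
  if (!length(selection_lists)) stopf("no selection lists supplied")
  lapply(selection_lists, function(lst) {
    if (!length(lst)) stopf("empty selection list")
    stage_enrichment(lst, assignments, alpha_fdr = alpha_fdr)
  })
}
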