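# CRISPR knockout screen reprocessing: sgRNA uniqueness filtering,
# anchored normalization to reference essential/nonessential medians,
# gene-level dependency scores, per-cancer dependency calls and
# common-dependency ranking.

#' Drop non-unique sgRNAs from a screen
#'
#' Uniqueness flags are supplied with the screen (in real data from a
#' precomputed genome-mapping table; sequence alignment is out of scope
#' here). Genes left without any sgRNA disappear from the screen universe.
#'
#' @param screen screen list (`guides`, `lfc`, ...) as from
#'   [generate_screen()].
#' @return the screen with non-unique guides removed.
#' @export
filter_unique_sgrnas <- function(screen) {
  keep <- screen$guides$unique
  screen$guides <- screen$guides[keep, , drop = FALSE]
  screen$lfc <- screen$lfc[keep, , drop = FALSE]
  screen
}

#' Anchored normalization of sgRNA fold changes per cell line
#'
#' Within each cell line (pooling its replicate columns), the medians of
#' all sgRNA fold changes belonging to reference essential and
#' nonessential genes are computed, and the affine map sending the
#' nonessential median to 0 and the essential median to -1 is applied to
#' the line's columns:
#' \deqn{g(x) = (x - m_{non}) / (m_{non} - m_{ess})}
#'
#' @param screen screen list (after [filter_unique_sgrnas()]).
#' @return the screen with `lfc` replaced by scaled values.
#' @export
normalize_screen <- function(screen) {
  line_of <- sub("\\.r[0-9]+$", "", colnames(screen$lfc))
  ess_rows <- screen$guides$gene_id %in% screen$essential_ref
  non_rows <- screen$guides$gene_id %in% screen$nonessential_ref
  if (!any(ess_rows) || !any(non_rows))
    stopf("reference essential/nonessential guides missing from screen")
  for (ln in unique(line_of)) {
    cols <- which(line_of == ln)
    m_ess <- median(screen$lfc[ess_rows, cols])
    m_non <- median(screen$lfc[non_rows, cols])
    if (m_ess == m_non) stopf("degenerate screen in line %s (reference medians equal)", ln)
    screen$lfc[, cols] <- (screen$lfc[, cols] - m_non) / (m_non - m_ess)
  }
  screen
}

#' Gene-level dependency scores per cell line
#'
#' One flat median per gene and cell line over all of the gene's retained
#' sgRNAs and replicate columns (a single median, not a
#' median-of-medians).
#'
#' @param screen normalized screen.
#' @return genes x lines matrix of scores.
#' @export
gene_scores <- function(screen) {
  line_of <- sub("\\.r[0-9]+$", "", colnames(screen$lfc))
  lines <- unique(line_of)
  genes <- unique(screen$guides$gene_id)
  gidx <- split(seq_len(nrow(screen$lfc)), screen$guides$gene_id)[genes]
  out <- sapply(lines, function(ln) {
    cols <- which(line_of == ln)
    vapply(gidx, function(ix) median(screen$lfc[ix, cols]), numeric(1))
  })
  rownames(out) <- genes
  out
}

#' Per-cell-line essentiality and per-cancer dependency calls
#'
#' In each cell line the lowest-scoring `ceiling(fraction x n_genes)`
#' genes are flagged essential (ties at the boundary broken by gene id).
#' Cancer types represented by fewer than `min_lines_per_cancer` cell
#' lines are excluded; a gene is a dependency of a cancer type when it is
#' essential in at least `min_lines` of that cancer's lines.
#'
#' @param scores genes x lines matrix from [gene_scores()].
#' @param line_info data frame `line`, `cancer_type`.
#' @param fraction per-line essential fraction (default 0.117).
#' @param min_lines essential-line floor per cancer (default 3).
#' @param min_lines_per_cancer representation floor (default 5).
#' @return list: `essential` (genes x lines logical), `dependency`
#'   (genes x retained-cancers logical), `retained_cancers`.
#' @export
call_dependencies <- function(scores, line_info, fraction = 0.117,
                              min_lines = 3L, min_lines_per_cancer = 5L) {
  n_ess <- ceiling(fraction * nrow(scores))
  ess <- apply(scores, 2, function(s) {
    ord <- order(s, rownames(scores))
    flag <- rep(FALSE, length(s))
    flag[ord[seq_len(n_ess)]] <- TRUE
    flag
  })
  rownames(ess) <- rownames(scores)
  tab <- table(line_info$cancer_type)
  retained <- names(tab)[tab >= min_lines_per_cancer]
  dep <- sapply(retained, function(ct) {
    lns <- intersect(line_info$line[line_info$cancer_type == ct], colnames(ess))
    rowSums(ess[, lns, drop = FALSE]) >= min_lines
  })
  list(essential = ess, dependency = dep, retained_cancers = retained)
}

#' Common-dependency ranking across all cell lines
#'
#' Within each line, genes are ranked ascending by score (most depleted =
#' rank 1) and the rank is normalized by the gene count. For each gene
#' the 90th percentile of its normalized ranks across lines — its
#' "relative lowest rank" — is recorded; the genes with the smallest such
#' statistic, up to `ceiling(top_fraction x n_genes)`, are flagged as
#' common dependencies.
#'
#' @param scores genes x lines matrix.
#' @param percentile rank summary quantile (default 0.90, type-7).
#' @param top_fraction flagged fraction (default 0.062).
#' @return data frame: `gene_id`, `rank90`, `common`.
#' @export
common_dependency <- function(scores, percentile = 0.90, top_fraction = 0.062) {
  if (ncol(scores) < 1L) stopf("need >= 1 cell line")
  nr <- apply(scores, 2, function(s) rank(s, ties.method = "average")) / nrow(scores)
  r90 <- apply(nr, 1, quantile, probs = percentile, names = FALSE, type = 7)
  n_top <- ceiling(top_fraction * nrow(scores))
  ord <- order(r90, rownames(scores))
  common <- rep(FALSE, nrow(scores))
  common[ord[seq_len(n_top)]] <- TRUE
  data.frame(gene_id = rownames(scores), rank90 = r90, common = common,
             row.names = NULL, stringsAsFactors = FALSE)
}
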