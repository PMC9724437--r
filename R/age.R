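# Gene-age catalog: merging synteny-based locus ages with family-level
# phylostratigraphy, age-class boundaries, the tau tissue-specificity
# index, and the gene-model filters defining the analysis universe.

#' Merge synteny-based and phylostratigraphy gene ages
#'
#' Synteny dates the locus and is reliable only after the vertebrate
#' split (groups 9-14); protein-family phylostratigraphy reaches much
#' deeper (strata 1-8) but cannot separate duplicates from their parental
#' copy. The merge keeps the synteny group for post-vertebrate loci and
#' adopts the family phylostratum for loci dated to the vertebrate
#' ancestor or older. Genes whose two sources fall on opposite sides of
#' the vertebrate split in an impossible direction (pre-vertebrate locus,
#' post-vertebrate family) are flagged as conflicting and excluded from
#' downstream age classes; an old family age for a young locus is *not* a
#' conflict — it marks a derived duplicate, a signal downstream analyses
#' use.
#'
#' @param synteny data frame with columns `gene_id`, `synteny_group`
#'   (character: `"9"`..`"14"` or the `"vertebrate"` sentinel for
#'   pre-vertebrate loci).
#' @param family data frame with columns `gene_id`, `phylostratum`
#'   (integer 1-14).
#' @param vertebrate_boundary first post-vertebrate group (epoch
#'   comparison config; default 9).
#' @return data frame with one row per gene seen in either source:
#'   `gene_id`, `synteny_group`, `phylostratum`, `merged_group`
#'   (NA when conflicting or undatable), `conflict`.
#' @export
merge_ages <- function(synteny, family, vertebrate_boundary = 9L) {
  for (tb in list(synteny, family)) {
    if (anyDuplicated(tb$gene_id)) stopf("duplicate gene ids in age table")
  }
  genes <- union(synteny$gene_id, family$gene_id)
  syn <- synteny$synteny_group[match(genes, synteny$gene_id)]
  fam <- family$phylostratum[match(genes, family$gene_id)]

  syn_num <- suppressWarnings(as.integer(syn))
  syn_pre <- !is.na(syn) & is.na(syn_num)      # "vertebrate" sentinel
  syn_post <- !is.na(syn_num)
  if (any(syn_post & (syn_num < vertebrate_boundary | syn_num > 14L)))
    stopf("numeric synteny groups must lie in %d..14", vertebrate_boundary)
  fam_post <- !is.na(fam) & fam >= vertebrate_boundary

  conflict <- syn_pre & fam_post
  merged <- rep(NA_integer_, length(genes))
  merged[syn_post] <- syn_num[syn_post]                 # young locus: synteny wins
  merged[syn_pre & !conflict] <- fam[syn_pre & !conflict]  # old locus: family stratum
  only_fam <- is.na(syn) & !is.na(fam)
  merged[only_fam] <- fam[only_fam]
  merged[conflict] <- NA_integer_

  data.frame(gene_id = genes, synteny_group = syn, phylostratum = fam,
             merged_group = merged, conflict = conflict,
             stringsAsFactors = FALSE)
}

#' Classify merged age groups into UC / EM / MM / PSG classes
#'
#' @param assignments data frame from [merge_ages()] (or any frame with
#'   `gene_id`, `merged_group`, `conflict`).
#' @param boundaries named list partitioning 1..14 into four contiguous
#'   blocks; defaults to UC 1-3, EM 4-11, MM 12-13, PSG 14.
#' @return the input with an `age_class` column (NA for conflicting or
#'   undatable genes).
#' @export
classify_age_class <- function(assignments,
                               boundaries = list(UC = 1:3, EM = 4:11,
                                                 MM = 12:13, PSG = 14L)) {
  all_groups <- sort(unlist(boundaries))
  if (!identical(as.integer(all_groups), 1:14))
    stopf("boundaries must partition groups 1..14")
  lookup <- rep(NA_character_, 14L)
  for (cl in names(boundaries)) lookup[boundaries[[cl]]] <- cl
  assignments$age_class <- ifelse(
    assignments$conflict | is.na(assignments$merged_group),
    NA_character_, lookup[assignments$merged_group])
  assignments
}

#' Tissue-specificity index tau
#'
#' \deqn{\tau = \sum_i (1 - x_i / x_{max}) / (N - 1)} for a profile of
#' per-tissue values; 0 for a uniform profile, 1 for single-tissue
#' expression. The caller chooses the scale; [tissue_profiles()] applies
#' it to log2(TPM+1) tissue means.
#'
#' @param x nonnegative per-tissue values, length >= 2, max > 0.
#' @return tau in `[0, 1]`.
#' @export
tau_index <- function(x) {
  if (length(x) < 2L) stopf("tau needs >= 2 tissues")
  if (any(x < 0)) stopf("tau requires nonnegative values")
  m <- max(x)
  if (m == 0) stopf("all-zero profile: tau undefined")
  sum(1 - x / m) / (length(x) - 1L)
}

#' Per-gene tissue profiles and tissue-bias classification
#'
#' Averages >= 3 replicates per tissue, computes tau on log2(TPM+1) means,
#' and classifies genes as tissue-biased when tau exceeds the cutoff
#' (strict inequality). All-zero genes are excluded with a logged reason.
#'
#' @param panel TPM matrix, genes x samples.
#' @param tissue_of character vector mapping each column to its tissue.
#' @param tau_cutoff bias cutoff (default 0.8).
#' @param log logbook (optional).
#' @return data frame: `gene_id`, `tau`, `bias_class`, `top_tissue`.
#' @export
tissue_profiles <- function(panel, tissue_of, tau_cutoff = 0.8, log = NULL) {
  stopifnot(ncol(panel) == length(tissue_of))
  tissues <- unique(tissue_of)
  means <- sapply(tissues, function(t)
    rowMeans(panel[, tissue_of == t, drop = FALSE]))
  lmeans <- log2(means + 1)
  mx <- apply(lmeans, 1, max)
  ok <- mx > 0
  for (g in rownames(panel)[!ok])
    log_entry(log, "tissue_profiles: %s all-zero across tissues, tau undefined", g)
  tau <- rep(NA_real_, nrow(panel))
  tau[ok] <- apply(lmeans[ok, , drop = FALSE], 1, tau_index)
  top <- tissues[apply(lmeans, 1, which.max)]
  data.frame(gene_id = rownames(panel), tau = tau,
             bias_class = ifelse(is.na(tau), NA_character_,
                                 ifelse(tau > tau_cutoff, "tissue-biased", "broad")),
             top_tissue = ifelse(ok, top, NA_character_),
             stringsAsFactors = FALSE)
}

#' Gene-model filters defining the retained analysis universe
#'
#' Four pure predicates applied to the catalog, the normal-tissue panel
#' and the tumor cohorts: (1) protein-coding biotype with transcript
#' length >= 150 bp; (2) paralog identity <= 97.5% (higher identity
#' defeats unique read mapping); (3) expressed somewhere in the tissue
#' panel (TPM >= `panel_floor` in at least one tissue mean); (4) not
#' unexpressed (zero in more than `zero_fraction` of samples) in *every*
#' cancer type. The returned set is the universe used by all downstream
#' stages.
#'
#' @param catalog data frame with `gene_id`, `biotype`, `length`,
#'   `paralog_identity`.
#' @param panel TPM matrix (genes x panel samples) or NULL to skip
#'   filter 3.
#' @param cohorts list of per-cancer bundles with a `tpm` matrix (genes x
#'   samples), or NULL to skip filter 4.
#' @param min_length,max_identity,panel_floor,zero_fraction cutoffs.
#' @param log logbook (optional).
#' @return character vector of retained gene ids.
#' @export
filter_gene_models <- function(catalog, panel = NULL, cohorts = NULL,
                               min_length = 150L, max_identity = 0.975,
                               panel_floor = 0.2, zero_fraction = 0.2,
                               log = NULL) {
  keep1 <- catalog$biotype == "protein_coding" & catalog$length >= min_length
  keep2 <- catalog$paralog_identity <= max_identity
  keep3 <- rep(TRUE, nrow(catalog))
  if (!is.null(panel)) {
    mx <- apply(panel, 1, max)
    keep3 <- mx[match(catalog$gene_id, rownames(panel))] >= panel_floor
    keep3[is.na(keep3)] <- FALSE
  }
  keep4 <- rep(TRUE, nrow(catalog))
  if (!is.null(cohorts)) {
    expressed_any <- rep(FALSE, nrow(catalog))
    for (cc in cohorts) {
      zf <- rowMeans(cc$tpm == 0)
      ok <- zf[match(catalog$gene_id, rownames(cc$tpm))] <= zero_fraction
      ok[is.na(ok)] <- FALSE
      expressed_any <- expressed_any | ok
    }
    keep4 <- expressed_any
  }
  keep <- keep1 & keep2 & keep3 & keep4
  log_entry(log, "filter_gene_models: %d/%d retained (biotype/length %d, identity %d, panel %d, cancer %d removed)",
            sum(keep), nrow(catalog), sum(!keep1), sum(!keep2), sum(!keep3), sum(!keep4))
  catalog$gene_id[keep]
}

#' Per-cancer expression filter for correlation-based stages
#'
#' Survival and coexpression analyses depend on expression variance and
#' skip genes without any reads in more than `zero_fraction` of a cancer
#' type's samples.
#'
#' @param tpm genes x samples matrix for one cancer type.
#' @param zero_fraction maximum tolerated zero fraction (default 0.2).
#' @return logical vector over rows of `tpm`.
#' @export
expressed_in_cancer <- function(tpm, zero_fraction = 0.2) {
  rowMeans(tpm == 0) <= zero_fraction
}
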