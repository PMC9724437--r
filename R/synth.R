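# Synthetic multi-omics generator with planted ground truth.
#
# Every downstream stage (differential expression, ssGSEA, regulation,
# coexpression, survival, screen, developmental staging) consumes the
# logical shapes produced here, so each stage has a recovery test against
# the planted truth. Each output draws from its own RNG stream
# (child_seed(seed, tag)) so toggling one output never perturbs another.

#' Configuration for the synthetic multi-omics generator
#'
#' Defaults define the study conditions used throughout the test suite and
#' the acceptance run: 2000 genes across 13 cancer types with 150 tumor and
#' 16 normal samples each (the cohort-inclusion floor of the emulated
#' pan-cancer corpus), age-class proportions matching a genome-scale
#' catalog (UC 32.5%, EM 48.1%, MM 16.8%, PSG 2.6%), planted pan-cancer
#' effects of |log2FC| = 1 in 6 cancer types, copy-number coupling rho 0.6
#' for broadly transcribed PSGs, promoter-methylation coupling -0.5 for a
#' subset of genes, Cox log-hazard 0.8 on planted prognostic genes, a
#' coexpressed cell-cycle module, screen depletion at the
#' essential-reference level, and 4-fold developmental stage bias.
#'
#' @param n_genes number of genes.
#' @param n_cancer_types number of emulated cancer types.
#' @param n_tumor,n_normal samples per cancer type.
#' @param class_props named simplex over `c("UC","EM","MM","PSG")`.
#' @param conflict_fraction fraction of genes given conflicting dual ages.
#' @param dispersion negative-binomial dispersion (1/size).
#' @param pan_up_lfc,pan_down_lfc planted log2 effects.
#' @param n_affected_cancers cancer types carrying each planted effect.
#' @param n_pan_up_psg,n_pan_up_uc,n_pan_down_em planted pan-regulated
#'   gene counts per class.
#' @param cna_rho_bpsg Spearman coupling between expression and copy
#'   number planted on broadly transcribed PSGs (0 elsewhere).
#' @param meth_rho,meth_coupled_fraction planted (negative) methylation
#'   coupling and the fraction of genes carrying it.
#' @param surv_beta,n_prognostic planted per-SD log-hazard and number of
#'   unfavorable prognostic genes (an equal-sized favorable set gets
#'   `-surv_beta`).
#' @param surv_cancers_per_gene cancer types in which each prognostic
#'   gene's hazard link is active. Keeping this small bounds the total
#'   hazard heterogeneity per cancer; a large omitted-covariate (frailty)
#'   variance would attenuate every marginal per-gene hazard ratio.
#' @param module_size,module_rho planted coexpression ("cell cycle")
#'   module size and target pairwise Spearman correlation.
#' @param sgrnas_per_gene,screen_replicates screen design.
#' @param lines_per_cancer integer vector (recycled) of cell lines per
#'   cancer type; cancers under the 5-line floor are exercised by the
#'   default `c(6,6,6,6,6,6,6,6,6,3,3,3,3)`.
#' @param n_ref_essential,n_ref_nonessential reference gene-list sizes.
#' @param essential_depletion raw log fold-change planted on essential
#'   genes (the nonessential center is 0).
#' @param screen_noise_sd sgRNA-level noise.
#' @param nonunique_fraction fraction of sgRNAs flagged non-unique.
#' @param n_planted_essential planted essential genes (half common across
#'   all lines, half restricted to two cancer types).
#' @param stage_replicates replicates per developmental stage (12 stages,
#'   summing to 52 samples as in the cerebral time course emulated).
#' @param stage_bias_fold planted fold elevation at the biased stage.
#' @param n_stage_biased planted stage-biased genes per stage.
#' @param dev_noise_sd log2-scale noise in the developmental series.
#' @param n_tissues tissue-panel size (normal adult tissues).
#' @param tissue_biased_fraction,psg_tissue_biased_fraction planted
#'   tissue-biased fractions overall and for PSGs.
#' @param na_fraction baseline probe NA rate; `bad_probe_fraction` of
#'   probes get `bad_probe_na` instead (to exercise the probe filter).
#' @param bad_probe_fraction,bad_probe_na see above.
#' @param seed integer seed; fixed seed implies byte-identical outputs.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_genes = 2000L,
                         n_cancer_types = 13L,
                         n_tumor = 150L,
                         n_normal = 16L,
                         class_props = c(UC = 0.325, EM = 0.481, MM = 0.168, PSG = 0.026),
                         conflict_fraction = 0.05,
                         dispersion = 0.2,
                         pan_up_lfc = 1.0,
                         pan_down_lfc = -1.0,
                         n_affected_cancers = 6L,
                         n_pan_up_psg = 20L,
                         n_pan_up_uc = 30L,
                         n_pan_down_em = 30L,
                         cna_rho_bpsg = 0.6,
                         meth_rho = -0.5,
                         meth_coupled_fraction = 0.2,
                         surv_beta = 0.8,
                         n_prognostic = 10L,
                         surv_cancers_per_gene = 2L,
                         module_size = 40L,
                         module_rho = 0.7,
                         sgrnas_per_gene = 4L,
                         screen_replicates = 2L,
                         lines_per_cancer = c(rep(6L, 9), rep(3L, 4)),
                         n_ref_essential = 60L,
                         n_ref_nonessential = 120L,
                         essential_depletion = -2.0,
                         screen_noise_sd = 0.2,
                         nonunique_fraction = 0.05,
                         n_planted_essential = 16L,
                         stage_replicates = c(2L, 3L, 5L, 5L, 6L, 6L, 5L, 4L, 4L, 4L, 4L, 4L),
                         stage_bias_fold = 4,
                         n_stage_biased = 25L,
                         dev_noise_sd = 0.25,
                         n_tissues = 26L,
                         tissue_biased_fraction = 0.25,
                         psg_tissue_biased_fraction = 0.6,
                         na_fraction = 0.005,
                         bad_probe_fraction = 0.05,
                         bad_probe_na = 0.10,
                         seed = 1L) {
  cfg <- as.list(environment())
  counts <- c(cfg$n_genes, cfg$n_cancer_types, cfg$n_tumor, cfg$n_normal)
  if (any(counts < 1)) stopf("all counts must be >= 1")
  if (!setequal(names(class_props), c("UC", "EM", "MM", "PSG")))
    stopf("class_props must be named over UC, EM, MM, PSG")
  if (abs(sum(class_props) - 1) > 1e-8 || any(class_props < 0))
    stopf("class_props must be a simplex (sum to 1, nonnegative)")
  if (cfg$dispersion <= 0) stopf("dispersion must be positive")
  if (length(stage_replicates) != 12L || any(stage_replicates < 2L))
    stopf("need 12 developmental stages with >= 2 replicates each")
  cfg$lines_per_cancer <- rep_len(as.integer(lines_per_cancer), n_cancer_types)
  cfg$cancer_types <- sprintf("C%02d", seq_len(n_cancer_types))
  class(cfg) <- "synth_config"
  cfg
}

# Age groups 1..14 partitioned into classes (shared with classify_age_class
# defaults): UC 1-3, EM 4-11, MM 12-13, PSG 14.
default_class_blocks <- function() {
  list(UC = 1:3, EM = 4:11, MM = 12:13, PSG = 14L)
}

#' Generate the synthetic gene catalog and its two age-source tables
#'
#' Emits per-gene annotation: true age group (1-14) and class, a
#' family-level phylostratum (for PSGs, a fraction descend from unicellular
#' founder families, enabling "UC-derived duplicate" tests), chromosome,
#' strand, TSS, transcript length, biotype, paralog identity, and a
#' planted tissue-bias class. A `conflict_fraction` of genes carries
#' contradictory dual ages to exercise the merge step. The derived
#' `synteny` and `family` tables are what [merge_ages()] consumes.
#'
#' @param config a [synth_config()].
#' @return list with `catalog` (data frame), `synteny`, `family` (age
#'   source tables), and `class_blocks`.
#' @export
generate_catalog <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(child_seed(config$seed, "catalog"))
  G <- config$n_genes
  gene_id <- sprintf("g%04d", seq_len(G))
  blocks <- default_class_blocks()

  # class assignment honoring the proportions to within +-1 by construction
  target <- round(config$class_props * G)
  target[1] <- G - sum(target[-1])
  cls <- sample(rep(names(target), times = target))
  group <- integer(G)
  for (cl in names(blocks)) {
    idx <- which(cls == cl)
    blk <- blocks[[cl]]
    group[idx] <- if (length(blk) == 1L) rep(blk, length(idx))
                  else sample(blk, length(idx), replace = TRUE)
  }

  # family-level (phylostratum) age: old genes keep their group; young
  # genes belong to families whose founder may be far older (duplicates).
  family <- group
  young <- which(group >= 9L)
  uc_derived <- rep(FALSE, G)
  uc_derived[young] <- runif(length(young)) < 0.37
  family[young][uc_derived[young]] <- sample(1:3, sum(uc_derived[young]), replace = TRUE)

  conflict <- rep(FALSE, G)
  n_conf <- round(config$conflict_fraction * G)
  conflict[sample.int(G, n_conf)] <- TRUE

  biased <- rep(FALSE, G)
  is_psg <- cls == "PSG"
  biased[is_psg] <- runif(sum(is_psg)) < config$psg_tissue_biased_fraction
  biased[!is_psg] <- runif(sum(!is_psg)) < config$tissue_biased_fraction
  tissues <- sprintf("T%02d", seq_len(config$n_tissues))

  catalog <- data.frame(
    gene_id = gene_id,
    chrom = sample(paste0("chr", 1:22), G, replace = TRUE),
    strand = sample(c("+", "-"), G, replace = TRUE),
    tss = sample.int(2e8, G),
    length = sample(500:5000, G, replace = TRUE),
    biotype = ifelse(runif(G) < 0.97, "protein_coding",
                     sample(c("lincRNA", "pseudogene"), G, replace = TRUE)),
    paralog_identity = pmin(1, stats::rbeta(G, 1.2, 6) + ifelse(runif(G) < 0.03, 0.95, 0)),
    panel_expressed = runif(G) < 0.97,
    true_group = group,
    true_class = cls,
    family_stratum = family,
    uc_derived = uc_derived,
    conflict = conflict,
    bias_class = ifelse(biased, "tissue-biased", "broad"),
    top_tissue = ifelse(biased, sample(tissues, G, replace = TRUE), NA_character_),
    stringsAsFactors = FALSE
  )

  # Derived age-source tables. Synteny dates loci: post-vertebrate genes
  # carry groups 9-14, older loci collapse to the "vertebrate" sentinel.
  # The family table carries the phylostratum. Conflicting genes are
  # planted as pre-vertebrate synteny calls paired with post-vertebrate
  # phylostrata (the impossible combination merge_ages must flag).
  syn_group <- ifelse(group >= 9L, as.character(group), "vertebrate")
  fam_stratum <- family
  conf_idx <- which(conflict)
  syn_group[conf_idx] <- "vertebrate"
  fam_stratum[conf_idx] <- sample(9:14, length(conf_idx), replace = TRUE)

  # source dropout: family-only dating is emitted only for pre-vertebrate
  # loci (a family age alone cannot date a young locus correctly)
  miss_syn <- runif(G) < 0.04 & !conflict & group <= 8L
  miss_fam <- runif(G) < 0.06 & !conflict & !miss_syn
  synteny <- data.frame(gene_id = gene_id[!miss_syn],
                        synteny_group = syn_group[!miss_syn],
                        stringsAsFactors = FALSE)
  family_tab <- data.frame(gene_id = gene_id[!miss_fam],
                           phylostratum = fam_stratum[!miss_fam],
                           stringsAsFactors = FALSE)

  list(catalog = catalog, synteny = synteny, family = family_tab,
       class_blocks = blocks)
}

#' Generate the 26-tissue normal expression panel
#'
#' TPM-like matrix of per-tissue replicate samples (3 replicates each)
#' consistent with the catalog's planted tissue-bias classes: biased genes
#' are strongly elevated in their top tissue; a small fraction of genes is
#' left unexpressed everywhere to exercise the expression filter.
#'
#' @param catalog data frame from [generate_catalog()].
#' @param config a [synth_config()].
#' @return list with `tpm` (genes x samples), `tissue_of` (sample -> tissue).
#' @export
generate_tissue_panel <- function(catalog, config) {
  set.seed(child_seed(config$seed, "panel"))
  G <- nrow(catalog)
  tissues <- sprintf("T%02d", seq_len(config$n_tissues))
  reps <- 3L
  samples <- paste(rep(tissues, each = reps), seq_len(reps), sep = "_r")
  base <- rlnorm(G, meanlog = 1.5, sdlog = 1)
  unexpressed <- !catalog$panel_expressed
  base[unexpressed] <- 0
  tpm <- matrix(0, G, length(samples), dimnames = list(catalog$gene_id, samples))
  tissue_of <- rep(tissues, each = reps)
  for (j in seq_along(samples)) {
    mu <- base
    bi <- !is.na(catalog$top_tissue) & catalog$top_tissue == tissue_of[j]
    lo <- !is.na(catalog$top_tissue) & catalog$top_tissue != tissue_of[j]
    mu[bi] <- mu[bi] * 20
    mu[lo] <- mu[lo] * 0.05
    tpm[, j] <- mu * rlnorm(G, 0, 0.2)
  }
  tpm[unexpressed, ] <- 0
  list(tpm = tpm, tissue_of = setNames(tissue_of, samples))
}

#' Generate the per-cancer multi-omics cohort with planted ground truth
#'
#' For each cancer type: negative-binomial counts and TPM for tumor and
#' normal samples (gene means log-normal across genes); planted pan-up /
#' pan-down genes shifted by the configured log2 effect in
#' `n_affected_cancers` cancer types; gene-level copy-number scores and
#' promoter beta values rank-coupled to expression via a Gaussian copula at
#' the planted Spearman rho; tumor purity in (0, 1]; progression-free
#' survival with an exponential baseline, uniform censoring and planted
#' per-gene log-hazard links; a coexpressed module with a shared latent
#' factor and a purity confounder (so partial correlation has real work).
#'
#' @param catalog_bundle list from [generate_catalog()].
#' @param config a [synth_config()].
#' @return list with `cancers` (per-cancer bundles: `counts`, `tpm`,
#'   `samples`, `cna`, `meth`, `probes`, `purity`, `survival`),
#'   `gene_lengths`, and `truth` (planted labels).
#' @export
generate_cohort <- function(catalog_bundle, config) {
  stopifnot(inherits(config, "synth_config"))
  catalog <- catalog_bundle$catalog
  G <- nrow(catalog)
  genes <- catalog$gene_id

  set.seed(child_seed(config$seed, "planting"))
  truth <- plant_truth(catalog, config)

  set.seed(child_seed(config$seed, "probes"))
  probes <- make_probe_annotation(catalog)

  cancers <- setNames(vector("list", config$n_cancer_types), config$cancer_types)
  base_mu <- NULL
  for (ci in seq_along(config$cancer_types)) {
    ct <- config$cancer_types[ci]
    set.seed(child_seed(config$seed, paste0("expression-", ct)))
    if (is.null(base_mu)) {
      set.seed(child_seed(config$seed, "gene-means"))
      base_mu <- rnorm(G, mean = 6, sd = 1.5)  # log2 scale
      set.seed(child_seed(config$seed, paste0("expression-", ct)))
    }
    cancers[[ct]] <- generate_one_cancer(catalog, config, truth, ct, base_mu,
                                         probes)
  }
  list(cancers = cancers, gene_lengths = setNames(catalog$length, genes),
       truth = truth)
}

# Decide which genes carry which planted signal. Planted sets are chosen
# from non-conflicting protein-coding genes so every label survives the
# age-merge and model filters.
plant_truth <- function(catalog, config) {
  eligible <- catalog$gene_id[!catalog$conflict &
                              catalog$biotype == "protein_coding" &
                              catalog$paralog_identity <= 0.975 &
                              catalog$panel_expressed]
  by_class <- split(catalog$gene_id, catalog$true_class)
  pick <- function(class, n, exclude = character(0)) {
    pool <- setdiff(intersect(by_class[[class]], eligible), exclude)
    if (length(pool) < n)
      stopf("requested %d planted %s genes but only %d eligible", n, class, length(pool))
    sample(pool, n)
  }
  pan_up_psg <- pick("PSG", config$n_pan_up_psg)
  pan_up_uc <- pick("UC", config$n_pan_up_uc)
  pan_down_em <- pick("EM", config$n_pan_down_em)
  pan_up <- c(pan_up_psg, pan_up_uc)

  # coexpression module: distinct chromosomes are not forced (the
  # same-chromosome exclusion is itself under test). Drawn from UC genes
  # without pan-regulated overlap, so the module factor's extra variance
  # does not interact with tumor/normal effect recovery.
  module <- pick("UC", config$module_size, exclude = c(pan_up, pan_down_em))

  prog_unfav <- sample(setdiff(pan_up, module), config$n_prognostic)
  prog_fav <- pick("EM", config$n_prognostic, exclude = c(pan_down_em, module))
  prog_cancers <- lapply(seq_len(2L * config$n_prognostic), function(i)
    sample(config$cancer_types, min(config$surv_cancers_per_gene,
                                    length(config$cancer_types))))
  names(prog_cancers) <- c(prog_unfav, prog_fav)

  aff <- lapply(seq_len(config$n_pan_up_psg + config$n_pan_up_uc), function(i)
    sample(config$cancer_types, config$n_affected_cancers))
  names(aff) <- pan_up
  aff_down <- lapply(seq_len(config$n_pan_down_em), function(i)
    sample(config$cancer_types, config$n_affected_cancers))
  names(aff_down) <- pan_down_em

  meth_coupled <- sample(eligible, round(config$meth_coupled_fraction * nrow(catalog)))

  list(pan_up = pan_up, pan_down = pan_down_em,
       pan_up_psg = pan_up_psg,
       affected = c(aff, aff_down),
       prognostic = c(setNames(rep(config$surv_beta, length(prog_unfav)), prog_unfav),
                      setNames(rep(-config$surv_beta, length(prog_fav)), prog_fav)),
       prognostic_cancers = prog_cancers,
       module = module,
       meth_coupled = meth_coupled,
       conflicting = catalog$gene_id[catalog$conflict])
}

generate_one_cancer <- function(catalog, config, truth, ct, base_mu, probes) {
  G <- nrow(catalog)
  genes <- catalog$gene_id
  nT <- config$n_tumor; nN <- config$n_normal
  tumor_ids <- sprintf("%s_T%03d", ct, seq_len(nT))
  normal_ids <- sprintf("%s_N%03d", ct, seq_len(nN))
  ids <- c(tumor_ids, normal_ids)
  is_tumor <- c(rep(TRUE, nT), rep(FALSE, nN))
  n <- length(ids)

  purity <- pmin(1, pmax(0.3, stats::rbeta(nT, 8, 3)))
  purity_z <- as.numeric(scale(purity))

  logmu <- matrix(rep(base_mu + rnorm(G, 0, 0.1), n), G, n)
  # planted tumor/normal effect
  for (g in intersect(names(truth$affected), genes)) {
    if (ct %in% truth$affected[[g]]) {
      eff <- if (g %in% truth$pan_up) config$pan_up_lfc else config$pan_down_lfc
      logmu[match(g, genes), is_tumor] <- logmu[match(g, genes), is_tumor] + eff
    }
  }
  # coexpression module: shared latent factor + purity confounding. The
  # loading is sized so the *realized* pairwise correlation (after
  # count-level noise) targets module_rho: w^2 = rho/(1-rho) * v_other,
  # where v_other estimates the non-factor log2-scale variance (residual
  # noise plus negative-binomial sampling at the typical count level).
  fac <- rnorm(n)
  mi <- match(truth$module, genes)
  s_noise <- 0.5
  s_mod <- s_noise * sqrt(0.3)
  v_nb <- (config$dispersion + 2^-6) / log(2)^2
  w <- sqrt(config$module_rho / (1 - config$module_rho) * (s_mod^2 + v_nb))
  logmu[mi, ] <- logmu[mi, ] + rep(w * fac, each = length(mi))
  logmu[mi, is_tumor] <- logmu[mi, is_tumor] + rep(0.4 * purity_z, each = length(mi))
  # an unrelated 20% of genes also track purity (confounder background)
  conf_idx <- which(runif(G) < 0.2)
  logmu[conf_idx, is_tumor] <- logmu[conf_idx, is_tumor] +
    rep(0.4 * purity_z, each = length(conf_idx))

  noise_sd <- rep(s_noise, G)
  noise_sd[mi] <- s_mod
  logmu <- logmu + matrix(rnorm(G * n), G, n) * noise_sd
  libfac <- rlnorm(n, 0, 0.25)
  mu <- t(t(2^logmu) * libfac)
  size <- 1 / config$dispersion
  counts <- matrix(rnbinom(G * n, mu = as.numeric(mu), size = size), G, n,
                   dimnames = list(genes, ids))
  rate <- counts / catalog$length
  tpm <- t(t(rate) / colSums(rate)) * 1e6
  dimnames(tpm) <- dimnames(counts)

  # one sample per patient: tumor and normal samples come from disjoint
  # patient series, so no duplicates are ever emitted
  samples <- data.frame(
    sample_id = ids,
    patient = paste0(ct, "_P", sprintf("%03d", c(seq_len(nT), nT + seq_len(nN)))),
    cancer_type = ct, group = ifelse(is_tumor, "tumor", "normal"),
    stringsAsFactors = FALSE)

  # copy number: Gaussian copula on realized tumor expression ranks
  rho_cna <- ifelse(catalog$true_class == "PSG" & catalog$bias_class == "broad",
                    config$cna_rho_bpsg, 0)
  tt <- tpm[, tumor_ids, drop = FALSE]
  cna <- copula_couple(tt, rho_cna)
  dimnames(cna) <- list(genes, tumor_ids)

  # methylation: per gene a promoter probe (coupled at meth_rho for the
  # planted subset), a second promoter probe left uncoupled, and one
  # distal probe outside the window.
  rho_m <- ifelse(genes %in% truth$meth_coupled, config$meth_rho, 0)
  meth_main <- pnorm(copula_couple(tt, rho_m))
  nP <- nrow(probes)
  meth <- matrix(pnorm(rnorm(nP * nT)), nP, nT,
                 dimnames = list(probes$probe_id, tumor_ids))
  meth[probes$role == "promoter_coupled", ] <- meth_main
  bad <- runif(nP) < config$bad_probe_fraction
  na_rate <- ifelse(bad, config$bad_probe_na, config$na_fraction)
  na_mask <- matrix(runif(nP * nT), nP, nT) < na_rate
  meth[na_mask] <- NA

  # survival: exponential baseline modulated by planted per-gene hazards
  prog <- intersect(names(truth$prognostic), genes)
  prog <- prog[vapply(prog, function(g) ct %in% truth$prognostic_cancers[[g]],
                      logical(1))]
  lp <- rep(0, nT)
  for (g in prog) {
    z <- as.numeric(scale(log2(tt[match(g, genes), ] + 1)))
    lp <- lp + truth$prognostic[[g]] * z
  }
  age <- round(rnorm(nT, 62, 9))
  stage <- sample(1:4, nT, replace = TRUE, prob = c(0.3, 0.35, 0.25, 0.1))
  gender <- sample(c("F", "M"), nT, replace = TRUE)
  lp <- lp + 0.15 * (stage - mean(stage))
  t_event <- rexp(nT, rate = 0.35 * exp(lp))
  t_cens <- runif(nT, 0.5, 8)
  survival <- data.frame(
    patient = samples$patient[is_tumor], cancer_type = ct,
    time = pmin(t_event, t_cens), event = as.integer(t_event <= t_cens),
    age = age, stage = stage, gender = gender, stringsAsFactors = FALSE)

  list(counts = counts, tpm = tpm, samples = samples, cna = cna,
       meth = meth, probes = probes,
       purity = setNames(purity, tumor_ids), survival = survival)
}

# Couple a new Gaussian row to each row of `expr` at (approximately) the
# requested Spearman rho via the normal-scores copula on realized ranks.
copula_couple <- function(expr, rho) {
  G <- nrow(expr); n <- ncol(expr)
  z <- t(apply(expr, 1, function(x) qnorm((rank(x, ties.method = "average") - 0.5) / n)))
  z * rho + matrix(rnorm(G * n), G, n) * sqrt(1 - rho^2)
}

# Three probes per gene in BED convention (0-based, half-open): one coupled
# probe inside the promoter window, one uncoupled inside, one distal.
make_probe_annotation <- function(catalog) {
  G <- nrow(catalog)
  up <- ifelse(catalog$strand == "+", -1L, 1L)  # direction of upstream
  off1 <- sample(-1200:400, G, replace = TRUE)
  off2 <- sample(-1200:400, G, replace = TRUE)
  off3 <- sample(5000:20000, G, replace = TRUE)
  pos <- function(off) ifelse(catalog$strand == "+", catalog$tss + off,
                              catalog$tss - off)
  probes <- rbind(
    data.frame(gene_id = catalog$gene_id, chrom = catalog$chrom,
               pos1 = pos(off1), role = "promoter_coupled"),
    data.frame(gene_id = catalog$gene_id, chrom = catalog$chrom,
               pos1 = pos(off2), role = "promoter_free"),
    data.frame(gene_id = catalog$gene_id, chrom = catalog$chrom,
               pos1 = pos(off3), role = "distal"))
  probes$probe_id <- sprintf("cg%05d", seq_len(nrow(probes)))
  probes$start <- probes$pos1 - 1L  # 0-based
  probes$end <- probes$pos1
  probes[c("probe_id", "gene_id", "chrom", "start", "end", "role")]
}

#' Generate a synthetic CRISPR knockout screen
#'
#' `sgrnas_per_gene` guides per gene, `screen_replicates` replicate columns
#' per cell line. Reference essential genes are centered at the planted
#' depletion and nonessential genes at 0 (raw scale), so the anchored
#' normalization maps their medians to -1 and 0. Planted essential genes
#' carry the depletion in their lines only; a configurable fraction of
#' sgRNAs is flagged non-unique for the uniqueness filter to drop.
#'
#' @param catalog_bundle list from [generate_catalog()].
#' @param config a [synth_config()].
#' @return a `screen` list: `guides` (sgRNA -> gene, uniqueness), `lfc`
#'   (sgRNA x line:replicate matrix), `line_info` (line -> cancer type),
#'   `essential_ref`, `nonessential_ref`, and `truth_essential`
#'   (gene -> character vector of dependent lines).
#' @export
generate_screen <- function(catalog_bundle, config) {
  stopifnot(inherits(config, "synth_config"))
  catalog <- catalog_bundle$catalog
  set.seed(child_seed(config$seed, "screen"))
  genes <- catalog$gene_id
  G <- length(genes)

  lines <- unlist(lapply(seq_along(config$cancer_types), function(i)
    sprintf("L_%s_%d", config$cancer_types[i], seq_len(config$lines_per_cancer[i]))))
  line_ct <- rep(config$cancer_types, times = config$lines_per_cancer)
  line_info <- data.frame(line = lines, cancer_type = line_ct,
                          stringsAsFactors = FALSE)

  pool <- genes
  ess_ref <- sample(pool, config$n_ref_essential)
  pool <- setdiff(pool, ess_ref)
  noness_ref <- sample(pool, config$n_ref_nonessential)
  pool <- setdiff(pool, noness_ref)
  planted <- sample(pool, config$n_planted_essential)
  n_common <- config$n_planted_essential %/% 2L
  big_ct <- config$cancer_types[config$lines_per_cancer >= 5L]
  truth_essential <- c(
    setNames(lapply(seq_len(n_common), function(i) lines), planted[seq_len(n_common)]),
    setNames(lapply((n_common + 1):config$n_planted_essential, function(i) {
      cts <- sample(big_ct, 2)
      lines[line_ct %in% cts]
    }), planted[(n_common + 1):config$n_planted_essential]))

  k <- config$sgrnas_per_gene
  guides <- data.frame(
    sgrna_id = sprintf("sg_%s_%d", rep(genes, each = k), rep(seq_len(k), G)),
    gene_id = rep(genes, each = k), stringsAsFactors = FALSE)
  nonuniq <- rep(FALSE, nrow(guides))
  n_nu <- round(config$nonunique_fraction * nrow(guides))
  if (n_nu > 0) nonuniq[sample.int(nrow(guides), n_nu)] <- TRUE
  guides$unique <- !nonuniq

  cols <- paste(rep(lines, each = config$screen_replicates),
                paste0("r", seq_len(config$screen_replicates)), sep = ".")
  col_line <- rep(lines, each = config$screen_replicates)

  # gene x line planted effect
  eff <- matrix(0, G, length(lines), dimnames = list(genes, lines))
  eff[ess_ref, ] <- config$essential_depletion
  for (g in names(truth_essential)) eff[g, truth_essential[[g]]] <- config$essential_depletion
  guide_off <- rnorm(nrow(guides), 0, 0.1)
  lfc <- eff[guides$gene_id, col_line, drop = FALSE] + guide_off +
    matrix(rnorm(nrow(guides) * length(cols), 0, config$screen_noise_sd),
           nrow(guides), length(cols))
  dimnames(lfc) <- list(guides$sgrna_id, cols)

  structure(list(guides = guides, lfc = lfc, line_info = line_info,
                 essential_ref = ess_ref, nonessential_ref = noness_ref,
                 truth_essential = truth_essential),
            class = "atavipan_screen")
}

#' Generate a synthetic developmental time series (12 stages)
#'
#' Emulates a cerebral development series: per-stage replicate samples with
#' stage-biased genes elevated `stage_bias_fold`-fold at their planted
#' stage and all other genes flat plus log-normal noise. A small fraction
#' of genes is kept below the downstream expression floor.
#'
#' @param catalog_bundle list from [generate_catalog()].
#' @param config a [synth_config()].
#' @return list with `expr` (genes x samples, TPM-like), `stage_map`
#'   (sample -> stage), `stage_labels`, and `truth_stage` (named planted
#'   stages). Stage 1 is the embryonic stage.
#' @export
generate_dev_series <- function(catalog_bundle, config) {
  stopifnot(inherits(config, "synth_config"))
  catalog <- catalog_bundle$catalog
  set.seed(child_seed(config$seed, "devseries"))
  genes <- catalog$gene_id
  G <- length(genes)
  stages <- seq_len(12L)
  stage_labels <- c("4PCW", "5PCW", "7PCW", "9PCW", "12PCW", "16PCW",
                    "19-24PCW", "newborn", "infant", "toddler", "adolescent", "adult")
  reps <- config$stage_replicates
  samp <- unlist(lapply(stages, function(s) sprintf("dev_s%02d_r%d", s, seq_len(reps[s]))))
  samp_stage <- rep(stages, times = reps)

  base <- rnorm(G, 2, 1)  # log2 scale
  low <- runif(G) < 0.05
  base[low] <- log2(0.05)

  # plant stage-biased genes, embryonic (stage 1) drawn partly from PSGs
  truth_stage <- integer(0)
  pool <- setdiff(genes[!low], character(0))
  psg <- intersect(pool, catalog$gene_id[catalog$true_class == "PSG"])
  for (s in stages) {
    n_psg1 <- min(10L, config$n_stage_biased %/% 2L, length(psg))
    take <- if (s == 1L) c(sample(psg, n_psg1),
                           sample(setdiff(pool, psg), config$n_stage_biased - n_psg1))
            else sample(pool, config$n_stage_biased)
    pool <- setdiff(pool, take)
    truth_stage <- c(truth_stage, setNames(rep(s, length(take)), take))
  }

  shift <- matrix(0, G, 12L, dimnames = list(genes, NULL))
  shift[cbind(match(names(truth_stage), genes), truth_stage)] <- log2(config$stage_bias_fold)
  logx <- base + shift[, samp_stage] +
    matrix(rnorm(G * length(samp), 0, config$dev_noise_sd), G, length(samp))
  expr <- 2^logx
  expr[low, ] <- pmin(expr[low, ], 0.15)
  dimnames(expr) <- list(genes, samp)

  list(expr = expr, stage_map = data.frame(sample_id = samp, stage = samp_stage,
                                           stringsAsFactors = FALSE),
       stage_labels = stage_labels, truth_stage = truth_stage)
}
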