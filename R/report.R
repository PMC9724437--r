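# End-to-end orchestration from a YAML manifest, paper-style summary
# tables, and recovery scoring against planted ground truth.

#' Run the full pipeline from a manifest
#'
#' Stages run in dependency order: age (catalog merge, tissue profiles,
#' model filters) always; then differential expression, ssGSEA,
#' regulation, coexpression and survival; then screen and developmental
#' staging. Each stage can be toggled in `manifest$stages`. Every output
#' TSV carries a '#'-prefixed provenance header (package version, seed,
#' thresholds — no timestamps), so reruns with the same manifest are
#' byte-identical; every exclusion is recorded with a reason in
#' `exclusions.log`.
#'
#' @param manifest path to a YAML manifest (see [write_synth_inputs()])
#'   or an already-read manifest list.
#' @return invisibly, a list of in-memory stage results (also written
#'   under `manifest$output_dir`).
#' @export
run_all <- function(manifest) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  validate_manifest(manifest)
  th <- manifest$thresholds %||% list()
  stages <- manifest$stages %||% list()
  on_stage <- function(nm) isTRUE(stages[[nm]] %||% TRUE)
  outdir <- manifest$output_dir
  if (!grepl("^/", outdir) && !is.null(manifest$manifest_dir))
    outdir <- file.path(manifest$manifest_dir, outdir)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log <- new_logbook()
  prov <- c(list(seed = manifest$seed), th)
  emit <- function(x, f) write_tsv_prov(x, file.path(outdir, f), prov)
  results <- list()

  ## ---- age: catalog, ages, tissue profiles, universe ----
  catalog <- read.delim(manifest_path(manifest, "catalog"),
                        stringsAsFactors = FALSE)
  ages <- merge_ages(read.delim(manifest_path(manifest, "synteny"),
                                colClasses = c("character", "character")),
                     read.delim(manifest_path(manifest, "family"),
                                colClasses = c("character", "integer")))
  ages <- classify_age_class(ages)
  panel <- read_matrix_tsv(manifest_path(manifest, "panel"))
  tissue_of <- sub("_r[0-9]+$", "", colnames(panel))
  profiles <- tissue_profiles(panel, tissue_of,
                              tau_cutoff = th$tau_cutoff %||% 0.8, log = log)

  tpm_all <- read_matrix_tsv(manifest_path(manifest, "tpm"))
  samples <- read.delim(manifest_path(manifest, "samples"),
                        stringsAsFactors = FALSE)
  counts_all <- read_matrix_tsv(manifest_path(manifest, "counts"))
  cancer_types <- unique(samples$cancer_type)
  cohorts <- lapply(setNames(cancer_types, cancer_types), function(ct) {
    ids <- samples$sample_id[samples$cancer_type == ct]
    list(tpm = tpm_all[, ids, drop = FALSE],
         counts = counts_all[, ids, drop = FALSE],
         samples = samples[samples$cancer_type == ct, ])
  })
  universe <- filter_gene_models(catalog, panel, cohorts, log = log)
  ages$bias_class <- profiles$bias_class[match(ages$gene_id, profiles$gene_id)]
  results$ages <- ages
  results$universe <- universe
  emit(ages, "age_assignments.tsv")
  emit(profiles, "tissue_profiles.tsv")
  writeLines(universe, file.path(outdir, "universe.txt"))

  class_of <- setNames(ages$age_class, ages$gene_id)
  aged_universe <- intersect(universe, ages$gene_id[!is.na(ages$age_class)])

  ## ---- differential expression + pan-cancer calls ----
  if (on_stage("diffexpr")) {
    de <- do.call(rbind, lapply(cancer_types, function(ct) {
      cc <- cohorts[[ct]]
      le <- normalize_and_transform(cc$counts[universe, , drop = FALSE])
      de_call(moderated_two_group_test(le, cc$samples$group, ct),
              alpha = th$alpha %||% 0.05, lfc = th$lfc %||% 0.4)
    }))
    pan <- classify_pan_cancer(de, min_n = th$pan_min_n %||% 3L,
                               ratio = th$pan_ratio %||% 3)
    results$de <- de
    results$pan <- pan
    emit(de, "de_results.tsv")
    emit(pan, "pan_cancer_calls.tsv")
  }

  ## ---- ssGSEA on age classes ----
  if (on_stage("ssgsea")) {
    sets <- split(aged_universe, class_of[aged_universe])
    bias <- setNames(ages$bias_class, ages$gene_id)
    psg <- sets$PSG
    sets$`B-PSG` <- psg[bias[psg] %in% "broad"]
    sets$`T-PSG` <- psg[bias[psg] %in% "tissue-biased"]
    sets <- Filter(function(s) length(s) >= 2, sets)
    es <- ssgsea_scores(tpm_all[universe, , drop = FALSE], sets,
                        alpha = th$ssgsea_alpha %||% 0.25)
    es <- rescale_scores(es, samples, log = log)
    results$ssgsea <- es
    emit(es, "ssgsea_scores.tsv")
  }

  ## ---- regulation: SCNA + methylation attribution ----
  if (on_stage("regulation")) {
    cna_all <- read_matrix_tsv(manifest_path(manifest, "cna"))
    meth_all <- read_matrix_tsv(manifest_path(manifest, "meth"))
    probes <- read_probe_bed(manifest_path(manifest, "probes"))
    probes <- annotate_promoter_probes(probes, catalog)
    reg <- do.call(rbind, lapply(cancer_types, function(ct) {
      cc <- cohorts[[ct]]
      tum <- cc$samples$sample_id[cc$samples$group == "tumor"]
      expr <- cc$tpm[universe, tum, drop = FALSE]
      cna <- cna_all[universe, tum, drop = FALSE]
      beta <- meth_all[, tum, drop = FALSE]
      kept <- filter_probes(beta, max_na = th$max_na %||% 0.05)
      sel <- select_promoter_probe(probes[probes$probe_id %in% kept, ],
                                   beta, expr)
      meth_gene <- beta[sel$probe_id, , drop = FALSE]
      rownames(meth_gene) <- sel$gene_id
      rbind(expr_factor_correlation(expr, cna, "SCNA", ct, log = log),
            expr_factor_correlation(expr, meth_gene, "methylation", ct,
                                    log = log))
    }))
    reg <- flag_strong(reg, cutoff = th$reg_cutoff %||% 0.3)
    grp <- class_of
    bias <- setNames(ages$bias_class, ages$gene_id)
    psg_idx <- which(!is.na(grp) & grp == "PSG")
    grp[psg_idx] <- ifelse(bias[names(grp)[psg_idx]] %in% "tissue-biased",
                           "T-PSG", "B-PSG")
    props <- strong_proportions(reg, grp)
    results$regulation <- reg
    results$reg_proportions <- props
    emit(reg, "regulation_correlations.tsv")
    emit(props, "regulation_proportions.tsv")
    emit(attr(props, "cross_cancer_median"), "regulation_medians.tsv")
  }

  ## ---- coexpression annotation of pan-up PSGs ----
  if (on_stage("coexpr") && !is.null(results$pan)) {
    purity <- read.delim(manifest_path(manifest, "purity"),
                         stringsAsFactors = FALSE)
    for (ct in cancer_types)
      cohorts[[ct]]$purity <- setNames(purity$purity, purity$sample_id)[
        cohorts[[ct]]$samples$sample_id[cohorts[[ct]]$samples$group == "tumor"]]
    hallmarks <- read_gmt(manifest_path(manifest, "hallmarks"))
    chrom_of <- setNames(catalog$chrom, catalog$gene_id)
    up_psg <- intersect(results$pan$gene_id[results$pan$label == "pan-up"],
                        aged_universe[class_of[aged_universe] == "PSG"])
    if (!length(up_psg))
      log_entry(log, "coexpr: no pan-up PSG in the aged universe, stage skipped")
    # queries: an explicit query list when supplied (the usual mode:
    # genes whose function is to be inferred), else the detected pan-up
    # PSGs
    ql_path <- manifest_path(manifest, "query_list")
    queries <- if (!is.null(ql_path)) intersect(readLines(ql_path), universe)
               else sort(up_psg)
    queries <- head(queries, th$n_coexpr_queries %||% 12L)
    partner_sets <- lapply(queries, find_partners, cohorts = cohorts,
                           universe = universe, chrom_of = chrom_of,
                           cutoff = th$partner_cutoff %||% 0.4, log = log)
    assignments <- do.call(rbind, lapply(partner_sets, assign_sets,
                                         sets = hallmarks, universe = universe))
    curated <- readLines(manifest_path(manifest, "curated_list"))
    overrep <- if (length(intersect(up_psg, universe)))
      group_overrepresentation(up_psg, list(curated = curated), universe)
    else NULL
    results$partner_sets <- partner_sets
    results$hallmark_assignments <- assignments
    results$curated_overrep <- overrep
    partners_df <- do.call(rbind, lapply(partner_sets, function(ps)
      if (length(ps$partners))
        data.frame(query = ps$query, partner = ps$partners,
                   median_rho = as.numeric(ps$median_rho[ps$partners]))
      else NULL))
    emit(partners_df %||% data.frame(query = character(0)), "coexpr_partners.tsv")
    emit(assignments %||% data.frame(query = character(0)), "hallmark_assignments.tsv")
    if (!is.null(overrep)) emit(overrep, "curated_overrepresentation.tsv")
  }

  ## ---- survival ----
  if (on_stage("survival")) {
    surv <- read.delim(manifest_path(manifest, "survival"),
                       stringsAsFactors = FALSE)
    cox <- do.call(rbind, lapply(cancer_types, function(ct) {
      cc <- cohorts[[ct]]
      fit_cox(cc$tpm[universe, , drop = FALSE],
              surv[surv$cancer_type == ct, ], cc$samples, ct,
              min_patients = th$min_patients %||% 30L,
              min_events = th$min_events %||% 10L, log = log)
    }))
    prog <- classify_prognostic(cox, alpha_fdr = th$alpha_fdr %||% 0.05)
    topk <- top_k_prognostic(cox, k = min(1500L, length(universe)))
    results$cox <- cox
    results$prognostic <- prog
    results$prognostic_topk <- topk$classes
    emit(cox, "cox_results.tsv")
    emit(prog, "prognostic_classes.tsv")
    emit(topk$classes, "prognostic_classes_topk.tsv")
  }

  ## ---- CRISPR screen ----
  if (on_stage("screen")) {
    sg <- read.delim(manifest_path(manifest, "screen_lfc"),
                     check.names = FALSE, stringsAsFactors = FALSE)
    lfc <- as.matrix(sg[-(1:3)])
    rownames(lfc) <- sg$sgrna_id
    screen <- structure(list(
      guides = sg[1:3], lfc = lfc,
      line_info = read.delim(manifest_path(manifest, "screen_lines"),
                             stringsAsFactors = FALSE),
      essential_ref = readLines(manifest_path(manifest, "essential_ref")),
      nonessential_ref = readLines(manifest_path(manifest, "nonessential_ref"))),
      class = "atavipan_screen")
    screen <- normalize_screen(filter_unique_sgrnas(screen))
    scores <- gene_scores(screen)
    deps <- call_dependencies(scores, screen$line_info,
                              fraction = th$essential_fraction %||% 0.117)
    common <- common_dependency(scores,
                                top_fraction = th$common_top_fraction %||% 0.062)
    results$screen_scores <- scores
    results$dependencies <- deps
    results$common <- common
    emit(data.frame(gene_id = rownames(scores), round(scores, 5),
                    check.names = FALSE), "screen_gene_scores.tsv")
    dep_df <- data.frame(gene_id = rownames(deps$dependency),
                         deps$dependency, check.names = FALSE)
    emit(dep_df, "screen_dependencies.tsv")
    emit(common, "screen_common_dependency.tsv")
  }

  ## ---- developmental staging ----
  if (on_stage("devstage")) {
    dev <- read_matrix_tsv(manifest_path(manifest, "dev_expr"))
    smap <- read.delim(manifest_path(manifest, "dev_stage_map"),
                       stringsAsFactors = FALSE)
    med <- filter_low(stage_medians(dev, smap), floor = th$dev_floor %||% 0.2)
    assign <- assign_stage(med, z_cutoff = th$z_cutoff %||% 1.2, log = log)
    psg_genes <- ages$gene_id[!is.na(ages$age_class) & ages$age_class == "PSG"]
    enr_psg <- stage_enrichment(psg_genes, assign)
    curated <- readLines(manifest_path(manifest, "curated_list"))
    enr_cur <- stage_enrichment(curated, assign)
    sel <- selection_overlap(assign, list(
      coding = readLines(manifest_path(manifest, "selection_coding")),
      promoter = readLines(manifest_path(manifest, "selection_promoter"))))
    results$dev_assignments <- assign
    results$dev_enrichment <- list(psg = enr_psg, curated = enr_cur,
                                   selection = sel)
    emit(assign, "dev_stage_assignments.tsv")
    emit(cbind(group = "PSG", enr_psg), "dev_enrichment_psg.tsv")
    emit(cbind(group = "curated", enr_cur), "dev_enrichment_curated.tsv")
    emit(do.call(rbind, lapply(names(sel), function(nm)
      cbind(list_name = nm, sel[[nm]]))), "dev_enrichment_selection.tsv")
  }

  ## ---- recovery report against planted truth, if available ----
  truth_path <- manifest_path(manifest, "truth")
  if (!is.null(truth_path) && file.exists(truth_path)) {
    truth <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
    recovery <- evaluate_against_truth(results, truth)
    results$recovery <- recovery
    emit(recovery, "recovery_report.tsv")
  }

  writeLines(log$entries, file.path(outdir, "exclusions.log"))
  invisible(results)
}

precision_recall <- function(called, planted, eligible) {
  planted <- intersect(planted, eligible)
  called <- intersect(called, eligible)
  tp <- length(intersect(called, planted))
  data.frame(n_planted = length(planted), n_called = length(called),
             precision = if (length(called)) tp / length(called) else NA_real_,
             recall = if (length(planted)) tp / length(planted) else NA_real_)
}

#' Score pipeline results against planted ground truth
#'
#' Precision and recall for pan-cancer up/down calls, prognostic signs,
#' screen dependency calls, developmental-stage assignments and
#' coexpression-module partner recovery. When nothing was planted for a
#' task, precision is reported as NA (undefined).
#'
#' @param results list from [run_all()].
#' @param truth ground-truth list (from `truth.json`).
#' @return data frame with one row per task.
#' @export
evaluate_against_truth <- function(results, truth) {
  rows <- list()
  if (!is.null(results$pan)) {
    uni <- results$pan$gene_id
    rows$pan_up <- precision_recall(
      results$pan$gene_id[results$pan$label == "pan-up"],
      unlist(truth$pan_up), uni)
    rows$pan_down <- precision_recall(
      results$pan$gene_id[results$pan$label == "pan-down"],
      unlist(truth$pan_down), uni)
  }
  if (!is.null(results$prognostic)) {
    pr <- results$prognostic
    beta <- unlist(truth$prognostic)
    rows$prognostic_unfavorable <- precision_recall(
      pr$gene_id[pr$label == "unfavorable"],
      names(beta)[beta > 0], pr$gene_id)
    rows$prognostic_favorable <- precision_recall(
      pr$gene_id[pr$label == "favorable"],
      names(beta)[beta < 0], pr$gene_id)
  }
  if (!is.null(results$dependencies)) {
    dep <- results$dependencies$dependency
    # reference essential genes are true dependencies by design; score
    # precision/recall over the non-reference genes only
    eligible <- setdiff(rownames(dep),
                        c(unlist(truth$essential_ref),
                          unlist(truth$nonessential_ref)))
    called <- rownames(dep)[rowSums(dep) > 0]
    planted <- names(truth$essential)
    rows$dependency <- precision_recall(called, planted, eligible)
  }
  if (!is.null(results$dev_assignments)) {
    a <- results$dev_assignments
    st <- unlist(truth$stage)
    planted <- intersect(names(st), a$gene_id)
    ass <- a[match(planted, a$gene_id), ]
    correct <- !is.na(ass$stage) & ass$stage == st[planted]
    rows$dev_stage <- data.frame(n_planted = length(planted),
                                 n_called = sum(!is.na(a$stage)),
                                 precision = NA_real_,
                                 recall = mean(correct))
  }
  if (!is.null(results$partner_sets)) {
    module <- unlist(truth$module)
    mod_queries <- Filter(function(ps) ps$query %in% module, results$partner_sets)
    if (length(mod_queries)) {
      rec <- vapply(mod_queries, function(ps)
        length(intersect(ps$partners, module)) /
          max(1L, length(setdiff(module, ps$query))), numeric(1))
      rows$module_partners <- data.frame(n_planted = length(module),
                                         n_called = NA_integer_,
                                         precision = NA_real_,
                                         recall = mean(rec))
    }
  }
  out <- do.call(rbind, rows)
  data.frame(task = rownames(out), out, row.names = NULL)
}
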