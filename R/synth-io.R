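# Emit the synthetic inputs as the plain-text files the pipeline consumes,
# plus a ground-truth JSON and a YAML manifest tying them together.

matrix_tsv <- function(mat, path, id_col = "gene_id") {
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[-1])
  rownames(m) <- df[[1]]
  m
}

#' Write a complete synthetic input bundle and its manifest
#'
#' Generates catalog, age tables, tissue panel, per-cancer expression /
#' copy-number / methylation / purity / survival, screen, gene sets,
#' curated and selection lists and the developmental series under `dir`,
#' plus `truth.json` (planted labels) and `manifest.yaml` (all paths and
#' the default thresholds). Running twice with the same config is
#' byte-identical.
#'
#' @param config a [synth_config()].
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_synth_inputs <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)

  cat_bundle <- generate_catalog(config)
  catalog <- cat_bundle$catalog
  write.table(catalog[c("gene_id", "chrom", "strand", "tss", "length",
                        "biotype", "paralog_identity")],
              p("catalog.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cat_bundle$synteny, p("synteny.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(cat_bundle$family, p("family.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  panel <- generate_tissue_panel(catalog, config)
  matrix_tsv(round(panel$tpm, 4), p("panel.tsv"))

  cohort <- generate_cohort(cat_bundle, config)
  counts <- do.call(cbind, lapply(cohort$cancers, `[[`, "counts"))
  tpm <- do.call(cbind, lapply(cohort$cancers, `[[`, "tpm"))
  samples <- do.call(rbind, lapply(cohort$cancers, `[[`, "samples"))
  matrix_tsv(counts, p("counts.tsv"))
  matrix_tsv(round(tpm, 4), p("tpm.tsv"))
  write.table(samples, p("samples.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  matrix_tsv(round(do.call(cbind, lapply(cohort$cancers, `[[`, "cna")), 5),
             p("cna.tsv"))
  matrix_tsv(round(do.call(cbind, lapply(cohort$cancers, `[[`, "meth")), 5),
             p("meth.tsv"))
  pr <- cohort$cancers[[1]]$probes   # annotation shared across cancers
  bed <- data.frame(pr$chrom, pr$start, pr$end, pr$probe_id, pr$gene_id)
  write.table(bed, p("probes.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  purity <- do.call(rbind, lapply(names(cohort$cancers), function(ct) {
    pu <- cohort$cancers[[ct]]$purity
    data.frame(sample_id = names(pu), purity = round(pu, 4))
  }))
  write.table(purity, p("purity.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  surv <- do.call(rbind, lapply(cohort$cancers, `[[`, "survival"))
  surv$time <- round(surv$time, 5)
  write.table(surv, p("survival.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  screen <- generate_screen(cat_bundle, config)
  sg <- data.frame(screen$guides, round(screen$lfc, 4), check.names = FALSE)
  write.table(sg, p("screen_lfc.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(screen$line_info, p("screen_lines.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(screen$essential_ref, p("essential_ref.txt"))
  writeLines(screen$nonessential_ref, p("nonessential_ref.txt"))

  dev <- generate_dev_series(cat_bundle, config)
  matrix_tsv(round(dev$expr, 4), p("dev_expr.tsv"))
  write.table(dev$stage_map, p("dev_stage_map.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  truth <- cohort$truth
  set.seed(child_seed(config$seed, "genesets"))
  # hallmark-like collection: the planted module as a "cell cycle" set
  # (padded with extra members) plus random sets
  genes <- catalog$gene_id
  sets <- c(list(HM_CELL_CYCLE = unique(c(truth$module,
                                          sample(genes, 80)))),
            setNames(lapply(1:9, function(i) sample(genes, 100)),
                     sprintf("HM_RANDOM_%02d", 1:9)))
  write_gmt(sets, p("hallmarks.gmt"))
  # curated cell-cycle list (a 666-style literature list): the planted
  # module, a slice of the planted cell-cycle pan-up PSGs, embryonic
  # stage-biased genes, and background
  stage1 <- names(dev$truth_stage)[dev$truth_stage == 1L]
  curated <- unique(c(truth$module,
                      utils::head(truth$pan_up_psg, 8L),
                      sample(stage1, min(15L, length(stage1))),
                      sample(genes, 120)))
  writeLines(curated, p("curated_cell_cycle.txt"))
  # coexpression query list: uncharacterized genes of interest — the
  # planted pan-up PSGs plus a few module members
  writeLines(c(utils::head(sort(truth$pan_up_psg), 8L),
               utils::head(sort(truth$module), 4L)), p("queries.txt"))
  # positive-selection lists: one planted inside embryonic-stage genes
  writeLines(unique(c(sample(stage1, min(20L, length(stage1))),
                      sample(genes, 40))), p("selection_coding.txt"))
  writeLines(sample(genes, 60), p("selection_promoter.txt"))

  truth_out <- truth
  truth_out$prognostic <- as.list(truth$prognostic)  # keep names in JSON
  truth_out$affected <- truth$affected
  truth_out$stage <- as.list(dev$truth_stage)
  truth_out$essential <- screen$truth_essential
  truth_out$essential_ref <- screen$essential_ref
  truth_out$nonessential_ref <- screen$nonessential_ref
  jsonlite::write_json(truth_out, p("truth.json"), auto_unbox = FALSE,
                       pretty = TRUE)

  manifest <- list(
    seed = config$seed,
    output_dir = "results",
    inputs = list(
      catalog = "catalog.tsv", synteny = "synteny.tsv", family = "family.tsv",
      panel = "panel.tsv", counts = "counts.tsv", tpm = "tpm.tsv",
      samples = "samples.tsv", cna = "cna.tsv", meth = "meth.tsv",
      probes = "probes.bed", purity = "purity.tsv", survival = "survival.tsv",
      screen_lfc = "screen_lfc.tsv", screen_lines = "screen_lines.tsv",
      essential_ref = "essential_ref.txt",
      nonessential_ref = "nonessential_ref.txt",
      hallmarks = "hallmarks.gmt",
      curated_list = "curated_cell_cycle.txt",
      query_list = "queries.txt",
      selection_coding = "selection_coding.txt",
      selection_promoter = "selection_promoter.txt",
      dev_expr = "dev_expr.tsv", dev_stage_map = "dev_stage_map.tsv",
      truth = "truth.json"),
    stages = list(diffexpr = TRUE, ssgsea = TRUE, regulation = TRUE,
                  coexpr = TRUE, survival = TRUE, screen = TRUE,
                  devstage = TRUE),
    thresholds = list(alpha = 0.05, lfc = 0.4, pan_min_n = 3, pan_ratio = 3,
                      tau_cutoff = 0.8, reg_cutoff = 0.3, max_na = 0.05,
                      partner_cutoff = 0.4, alpha_fdr = 0.05,
                      essential_fraction = 0.117, common_top_fraction = 0.062,
                      dev_floor = 0.2, z_cutoff = 1.2, ssgsea_alpha = 0.25,
                      n_coexpr_queries = 12))
  yaml::write_yaml(manifest, p("manifest.yaml"))
  invisible(p("manifest.yaml"))
}
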