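# The synthetic generator: validation, determinism, planted structure.

test_that("config validation rejects malformed inputs", {
  expect_error(synth_config(n_genes = 0), ">= 1")
  expect_error(synth_config(class_props = c(UC = 0.5, EM = 0.5, MM = 0.2,
                                            PSG = -0.2)), "simplex")
  expect_error(synth_config(class_props = c(UC = 1, EM = 0, XX = 0, PSG = 0)),
               "named")
  expect_error(synth_config(dispersion = 0), "positive")
  expect_error(synth_config(stage_replicates = rep(2L, 11)), "12")
  expect_error(synth_config(stage_replicates = c(1L, rep(4L, 11))),
               ">= 2 replicates")
})

test_that("catalog honors proportions, conflicts, and determinism", {
  cfg <- small_config(seed = 1)
  cb <- generate_catalog(cfg)
  tab <- table(cb$catalog$true_class)
  target <- round(cfg$class_props * cfg$n_genes)
  for (cl in names(target))
    expect_lte(abs(tab[[cl]] - target[[cl]]), 1)
  expect_equal(sum(cb$catalog$conflict),
               round(cfg$conflict_fraction * cfg$n_genes))
  # same config, same seed: identical outputs
  cb2 <- generate_catalog(small_config(seed = 1))
  expect_identical(cb, cb2)
  # a different seed changes the catalog
  expect_false(identical(cb$catalog, generate_catalog(small_config(seed = 2))$catalog))
})

test_that("emitted age tables reproduce the planted groups through the merge", {
  cb <- small_bundle()$cat
  m <- classify_age_class(merge_ages(cb$synteny, cb$family))
  cat <- cb$catalog
  common <- intersect(m$gene_id, cat$gene_id)
  planted_conf <- cat$gene_id[cat$conflict]
  # all planted conflicts that appear in both sources get flagged
  expect_true(all(m$conflict[m$gene_id %in% planted_conf]))
  # non-conflicting merged groups equal the planted truth
  ok <- m$gene_id[!m$conflict & !is.na(m$merged_group)]
  expect_equal(m$merged_group[match(ok, m$gene_id)],
               cat$true_group[match(ok, cat$gene_id)])
})

test_that("cohort couples planted signals and stays reproducible", {
  b <- small_bundle()
  cfg <- b$cfg
  truth <- b$cohort$truth
  # planted rho = 0 gene: realized expression-CNA Spearman near 0
  cat <- b$cat$catalog
  null_gene <- setdiff(cat$gene_id[cat$true_class == "EM"], truth$pan_down)[1]
  cc <- b$cohort$cancers[[1]]
  tum <- cc$samples$sample_id[cc$samples$group == "tumor"]
  expect_lt(abs(spearman_rho(cc$tpm[null_gene, tum], cc$cna[null_gene, tum])),
            0.25)  # n = 60 tumor samples
  # purity in (0, 1]
  expect_true(all(cc$purity > 0 & cc$purity <= 1))
  # every planted label references an emitted gene
  planted_ids <- c(truth$pan_up, truth$pan_down, names(truth$prognostic),
                   truth$module, truth$conflicting)
  expect_true(all(planted_ids %in% cat$gene_id))
  expect_true(all(unlist(truth$affected) %in% cfg$cancer_types))
  # asking for more planted genes than a class holds fails loudly
  expect_error(generate_cohort(b$cat, small_config(n_pan_up_psg = 400L)),
               "eligible")
  # determinism: regenerating is identical
  b2 <- generate_cohort(b$cat, cfg)
  expect_identical(b$cohort$cancers[[2]]$counts, b2$cancers[[2]]$counts)
  expect_identical(b$cohort$truth, b2$truth)
})

test_that("screen generator honors uniqueness config and replicate medians", {
  cfg0 <- small_config(nonunique_fraction = 0)
  sc0 <- generate_screen(generate_catalog(cfg0), cfg0)
  expect_true(all(sc0$guides$unique))
  expect_identical(filter_unique_sgrnas(sc0)$lfc, sc0$lfc)
  b <- small_bundle()
  expect_equal(sum(!b$screen$guides$unique),
               round(b$cfg$nonunique_fraction * nrow(b$screen$guides)))
  # reference lists are disjoint and every sgRNA maps to one gene
  expect_length(intersect(b$screen$essential_ref, b$screen$nonessential_ref), 0)
  expect_equal(nrow(b$screen$lfc), nrow(b$screen$guides))
  # two replicate columns per line: gene score = median over the 8 values
  sc <- filter_unique_sgrnas(b$screen)
  g <- sc$guides$gene_id[1]
  ln <- sc$line_info$line[1]
  idx <- sc$guides$gene_id == g
  cols <- grepl(paste0("^", ln, "\\."), colnames(sc$lfc))
  expect_equal(unname(gene_scores(sc)[g, ln]), median(sc$lfc[idx, cols]))
})

test_that("developmental series plants stage bias and repeats identically", {
  b <- small_bundle()
  dev <- b$dev
  expect_equal(ncol(dev$expr), sum(b$cfg$stage_replicates))
  expect_identical(generate_dev_series(b$cat, b$cfg)$expr, dev$expr)
  # a planted embryonic gene at 4-fold lands in stage 1
  g1 <- names(dev$truth_stage)[dev$truth_stage == 1][1]
  med <- stage_medians(dev$expr, dev$stage_map)
  a <- assign_stage(med[g1, , drop = FALSE])
  expect_equal(a$stage, 1L)
})

test_that("written input bundles are byte-identical under a fixed seed", {
  cfg <- synth_config(n_genes = 120, n_cancer_types = 3, n_tumor = 30,
                      n_normal = 6, n_pan_up_psg = 2, n_pan_up_uc = 3,
                      n_pan_down_em = 3, n_affected_cancers = 3,
                      n_prognostic = 2, module_size = 8,
                      n_planted_essential = 4,
                      n_ref_essential = 10, n_ref_nonessential = 20,
                      lines_per_cancer = c(5, 5, 5), n_stage_biased = 5,
                      seed = 99)
  d1 <- file.path(tempdir(), "synth-det-1")
  d2 <- file.path(tempdir(), "synth-det-2")
  write_synth_inputs(cfg, d1)
  write_synth_inputs(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = sprintf("md5(%s)", f))
  }
})
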