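# Screen filtering, anchored normalization, scores and dependency calls.

toy_screen <- function(lfc_by_gene, lines = c("L1", "L2"), reps = 2,
                       guides_per_gene = 2, ess = "gE", non = "gN") {
  genes <- names(lfc_by_gene)
  guides <- data.frame(
    sgrna_id = sprintf("sg_%s_%d", rep(genes, each = guides_per_gene),
                       seq_len(guides_per_gene)),
    gene_id = rep(genes, each = guides_per_gene),
    unique = TRUE)
  cols <- paste(rep(lines, each = reps), paste0("r", seq_len(reps)), sep = ".")
  lfc <- matrix(rep(unlist(lfc_by_gene)[guides$gene_id], length(cols)),
                nrow(guides), length(cols),
                dimnames = list(guides$sgrna_id, cols))
  structure(list(guides = guides, lfc = lfc,
                 line_info = data.frame(line = lines, cancer_type = "C1"),
                 essential_ref = ess, nonessential_ref = non),
            class = "atavipan_screen")
}

test_that("uniqueness filter drops flagged guides and empty genes", {
  sc <- toy_screen(c(gE = -2, gN = 0, gA = -1, gB = 0.2))
  sc$guides$unique[sc$guides$gene_id == "gB"] <- FALSE     # whole gene
  sc$guides$unique[sc$guides$sgrna_id == "sg_gA_1"] <- FALSE
  f <- filter_unique_sgrnas(sc)
  expect_false("gB" %in% f$guides$gene_id)
  expect_equal(sum(f$guides$gene_id == "gA"), 1L)
  expect_equal(nrow(f$lfc), nrow(f$guides))
  # all unique: identity
  sc2 <- toy_screen(c(gE = -2, gN = 0))
  expect_identical(filter_unique_sgrnas(sc2)$guides, sc2$guides)
})

test_that("normalization anchors reference medians at -1 and 0 exactly", {
  set.seed(71)
  sc <- toy_screen(c(gE = -1.9, gN = 0.1, gA = -0.9, gB = 0.5))
  n <- normalize_screen(sc)
  # affine evaluation: m_non=0.1, m_ess=-1.9, x=-0.9 -> -0.5
  expect_equal(unname(n$lfc["sg_gA_1", 1]), -0.5)
  expect_equal(unname(n$lfc["sg_gE_1", 1]), -1)
  expect_equal(unname(n$lfc["sg_gN_1", 1]), 0)
  # with noise the anchoring identity still holds exactly per line
  sc2 <- toy_screen(setNames(rnorm(30), paste0("g", 1:30)),
                    ess = paste0("g", 1:6), non = paste0("g", 7:14))
  sc2$lfc <- sc2$lfc + matrix(rnorm(length(sc2$lfc), sd = 0.3),
                              nrow(sc2$lfc))
  n2 <- normalize_screen(sc2)
  line_of <- sub("\\.r[0-9]+$", "", colnames(n2$lfc))
  for (ln in unique(line_of)) {
    cols <- line_of == ln
    expect_equal(median(n2$lfc[n2$guides$gene_id %in% sc2$essential_ref, cols]),
                 -1, tolerance = 1e-12)
    expect_equal(median(n2$lfc[n2$guides$gene_id %in% sc2$nonessential_ref, cols]),
                 0, tolerance = 1e-12)
  }
  sc$lfc[] <- 1
  expect_error(normalize_screen(sc), "degenerate")
})

test_that("gene scores are one flat median over guides and replicates", {
  sc <- toy_screen(c(gE = -2, gN = 0, gA = 0))
  # gA: 2 guides x 2 lines x 2 reps; set one line to {-1,-1,0,0} -> median -0.5
  sc$lfc[sc$guides$gene_id == "gA", 1:2] <- matrix(c(-1, -1, 0, 0), 2, 2)
  sc$lfc[sc$guides$gene_id == "gA", 3:4] <- 99   # other line untouched check
  s <- gene_scores(sc)
  expect_equal(unname(s["gA", "L1"]), -0.5)
  expect_equal(unname(s["gA", "L2"]), 99)
  # single guide, single replicate: that value
  sc1 <- toy_screen(c(gE = -2, gN = 0, gZ = 0.7), reps = 1, guides_per_gene = 1)
  expect_equal(unname(gene_scores(sc1)["gZ", "L1"]), 0.7)
  # flat-median oracle on a 4-guide x 2-replicate gene
  set.seed(72)
  sc8 <- toy_screen(c(gE = -2, gN = 0, gM = 0), guides_per_gene = 4)
  vals <- rnorm(8)
  sc8$lfc[sc8$guides$gene_id == "gM", 1:2] <- vals
  expect_equal(unname(gene_scores(sc8)["gM", "L1"]), median(vals))
})

test_that("dependency calling applies the ceiling quota, line floors and cancer floors", {
  set.seed(73)
  G <- 100
  scores <- matrix(rnorm(G * 8, 0, 0.1), G, 8,
                   dimnames = list(sprintf("g%03d", 1:G),
                                   c(paste0("A", 1:6), paste0("B", 1:2))))
  line_info <- data.frame(line = colnames(scores),
                          cancer_type = rep(c("CA", "CB"), c(6, 2)))
  scores["g001", ] <- -5          # essential everywhere
  scores["g002", 1:2] <- -5       # essential in only 2 of 6 lines
  d <- call_dependencies(scores, line_info, fraction = 0.117)
  expect_equal(colSums(d$essential), setNames(rep(12L, 8), colnames(scores)))
  expect_equal(d$retained_cancers, "CA")       # CB has < 5 lines
  expect_true(d$dependency["g001", "CA"])
  expect_false(d$dependency["g002", "CA"])     # 2 < 3 lines
})

test_that("essential calling is invariant to monotone transforms of a line's scores", {
  set.seed(74)
  scores <- matrix(rnorm(50 * 3), 50, 3,
                   dimnames = list(sprintf("g%02d", 1:50), c("L1", "L2", "L3")))
  line_info <- data.frame(line = colnames(scores), cancer_type = "C")
  d1 <- call_dependencies(scores, line_info, min_lines_per_cancer = 3)
  scores2 <- scores
  scores2[, 2] <- exp(scores2[, 2])        # strictly increasing transform
  scores2[, 3] <- scores2[, 3]^3 + 10
  d2 <- call_dependencies(scores2, line_info, min_lines_per_cancer = 3)
  expect_identical(d1$essential, d2$essential)
})

test_that("common dependency matches the brute-force sort/quantile oracle", {
  set.seed(75)
  scores <- matrix(rnorm(100), 20, 5,
                   dimnames = list(sprintf("g%02d", 1:20), paste0("L", 1:5)))
  cd <- common_dependency(scores, top_fraction = 0.2)
  oracle <- oracle_common_dependency(scores, top_fraction = 0.2)
  expect_equal(setNames(cd$common, cd$gene_id), oracle)
  # single line: statistic equals the gene's own normalized rank
  cd1 <- common_dependency(scores[, 1, drop = FALSE])
  expect_equal(cd1$rank90, unname(rank(scores[, 1]) / 20))
  # a gene ranked first everywhere is flagged
  scores["g07", ] <- -99
  cd2 <- common_dependency(scores, top_fraction = 0.05)
  expect_true(cd2$common[cd2$gene_id == "g07"])
  expect_equal(sum(cd2$common), 1L)   # ceiling(0.05 * 20)
})

test_that("common-dependency flags survive adding a strictly worse-ranked gene", {
  set.seed(76)
  scores <- matrix(rnorm(60), 12, 5,
                   dimnames = list(sprintf("g%02d", 1:12), paste0("L", 1:5)))
  cd <- common_dependency(scores, top_fraction = 0.25)
  worse <- matrix(apply(scores, 2, max) + 1, 1, 5,
                  dimnames = list("zzz", colnames(scores)))
  cd2 <- common_dependency(rbind(scores, worse), top_fraction = 0.25)
  flagged_before <- cd$gene_id[cd$common]
  expect_true(all(flagged_before %in% cd2$gene_id[cd2$common]))
})

test_that("planted essentials in the synthetic screen are recovered without reference losses", {
  b <- small_bundle()
  sc <- normalize_screen(filter_unique_sgrnas(b$screen))
  scores <- gene_scores(sc)
  d <- call_dependencies(scores, sc$line_info)
  planted <- names(b$screen$truth_essential)
  for (g in intersect(planted, rownames(scores))) {
    lines <- intersect(b$screen$truth_essential[[g]], colnames(scores))
    # post-normalization gene score below the per-line essential threshold
    expect_true(all(d$essential[g, lines]))
  }
  # planted common essentials (all lines) get dependency calls
  common_planted <- planted[vapply(b$screen$truth_essential, length,
                                   integer(1)) == nrow(sc$line_info)]
  got <- rowSums(d$dependency[intersect(common_planted, rownames(d$dependency)), ,
                              drop = FALSE]) > 0
  expect_true(all(got))
  # nonessential reference genes never earn a dependency call
  non <- intersect(b$screen$nonessential_ref, rownames(d$dependency))
  expect_equal(sum(d$dependency[non, ]), 0L)
})
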