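# Probe filtering, promoter probe selection, and regulatory correlations.

test_that("probe NA filter applies the strict 5% rule", {
  set.seed(41)
  beta <- matrix(runif(10 * 100), 10, 100,
                 dimnames = list(paste0("cg", 1:10), NULL))
  beta[1, 1:6] <- NA    # 6% NA -> removed
  beta[2, 1:5] <- NA    # 5% NA -> kept (strict 'more than')
  beta[3, 1:20] <- NA
  kept <- filter_probes(beta)
  expect_false("cg1" %in% kept)
  expect_true("cg2" %in% kept)
  expect_false("cg3" %in% kept)
  expect_setequal(kept, paste0("cg", c(2, 4:10)))
  expect_error(filter_probes(matrix(2, 1, 4, dimnames = list("x", NULL))),
               "\\[0, 1\\]")
})

test_that("promoter window is strand-aware in BED coordinates", {
  catalog <- data.frame(gene_id = c("gp", "gm"), tss = c(10000L, 10000L),
                        strand = c("+", "-"))
  probes <- data.frame(
    probe_id = paste0("cg", 1:6),
    gene_id = rep(c("gp", "gm"), each = 3),
    # 1-based positions 8499, 10500, 10501 / 11500, 9500, 9499
    start = c(8498L, 10499L, 10500L, 11499L, 9499L, 9498L))
  ann <- annotate_promoter_probes(probes, catalog)
  expect_equal(ann$signed_dist, c(-1501L, 500L, 501L, -1500L, 500L, 501L))
  expect_equal(ann$promoter, c(FALSE, TRUE, FALSE, TRUE, TRUE, FALSE))
})

test_that("promoter probe selection takes the most negative rho with id tie-break", {
  set.seed(42)
  expr <- matrix(rnorm(30), 1, 30, dimnames = list("g1", paste0("s", 1:30)))
  beta <- rbind(cg1 = -0.9 * expr[1, ] + rnorm(30, sd = 0.1),
                cg2 = rnorm(30))
  colnames(beta) <- colnames(expr)
  probes <- data.frame(probe_id = c("cg1", "cg2"), gene_id = "g1",
                       promoter = TRUE)
  sel <- select_promoter_probe(probes, beta, expr)
  expect_equal(sel$probe_id, "cg1")
  expect_lt(sel$rho, -0.5)
  # exact tie on rho: lexicographically smallest probe id wins
  beta2 <- rbind(cgB = beta[1, ], cgA = beta[1, ])
  probes2 <- data.frame(probe_id = c("cgB", "cgA"), gene_id = "g1",
                        promoter = TRUE)
  expect_equal(select_promoter_probe(probes2, beta2, expr)$probe_id, "cgA")
  # single probe: itself
  expect_equal(select_promoter_probe(probes[1, ], beta, expr)$probe_id, "cg1")
})

test_that("expression-factor correlation matches the oracle and handles degeneracy", {
  set.seed(43)
  expr <- matrix(rnorm(3 * 20), 3, 20,
                 dimnames = list(c("g1", "g2", "g3"), paste0("s", 1:20)))
  fac <- expr + matrix(rnorm(60, sd = 0.3), 3, 20)
  fac["g2", ] <- 5   # constant -> excluded
  lg <- atavipan:::new_logbook()
  out <- expr_factor_correlation(expr, fac, "SCNA", "C1", log = lg)
  expect_setequal(out$gene_id, c("g1", "g3"))
  expect_match(lg$entries, "g2", all = FALSE)
  expect_equal(out$rho[out$gene_id == "g1"],
               oracle_spearman(expr["g1", ], fac["g1", ]), tolerance = 1e-10)
  # perfectly monotone pair
  expr2 <- matrix(1:12, 1, 12, dimnames = list("m", NULL))
  expect_equal(expr_factor_correlation(expr2, exp(expr2), "SCNA")$rho, 1)
  # independent pair at n=500 stays near zero
  e3 <- matrix(rnorm(500), 1, 500, dimnames = list("z", NULL))
  f3 <- matrix(rnorm(500), 1, 500, dimnames = list("z", NULL))
  expect_lt(abs(expr_factor_correlation(e3, f3, "SCNA")$rho), 0.1)
})

test_that("strong proportions count hand-tallied toys and shrink with the cutoff", {
  d <- data.frame(
    gene_id = rep(paste0("g", 1:6), 2),
    cancer_type = rep(c("C1", "C2"), each = 6),
    factor = "SCNA",
    rho = c(0.5, 0.2, 0.35, 0, 0.31, 0.9, 0.1, 0.45, 0.29, 0.33, 0.5, 0.01))
  groups <- setNames(rep(c("UC", "PSG"), 3), paste0("g", 1:6))
  p3 <- strong_proportions(flag_strong(d, 0.3), groups)
  # hand count at 0.3: C1 UC {0.5,0.35,0.31} -> 3/3; C1 PSG {0.2,0,0.9} -> 1/3
  expect_equal(p3$proportion[p3$cancer_type == "C1" & p3$group == "UC"], 1)
  expect_equal(p3$proportion[p3$cancer_type == "C1" & p3$group == "PSG"], 1 / 3)
  expect_equal(p3$proportion[p3$cancer_type == "C2" & p3$group == "UC"], 1 / 3)
  expect_equal(p3$proportion[p3$cancer_type == "C2" & p3$group == "PSG"], 2 / 3)
  # rho exactly at the cutoff is NOT strong
  expect_false(flag_strong(data.frame(gene_id = "x", cancer_type = "C",
                                      factor = "SCNA", rho = 0.3))$strong)
  # monotone nonincreasing in the cutoff
  p4 <- strong_proportions(flag_strong(d, 0.4), groups)
  key <- paste(p3$cancer_type, p3$group)
  expect_true(all(p4$proportion[match(key, paste(p4$cancer_type, p4$group))] <=
                    p3$proportion))
  # methylation uses the negative tail
  dm <- data.frame(gene_id = "g", cancer_type = "C", factor = "methylation",
                   rho = c(-0.5))
  expect_true(flag_strong(dm)$strong)
})

test_that("copula coupling converges to the planted Spearman rho", {
  set.seed(44)
  err0 <- err6 <- numeric(20)
  for (s in 1:20) {
    expr <- matrix(rlnorm(500), 1, 500)
    c0 <- atavipan:::copula_couple(expr, 0)
    c6 <- atavipan:::copula_couple(expr, 0.6)
    err0[s] <- spearman_rho(expr[1, ], c0[1, ]) - 0
    err6[s] <- spearman_rho(expr[1, ], c6[1, ]) - 0.6
  }
  # sampling sd of Spearman rho at n=500 is ~0.045, so the max over 20
  # replicates can approach 0.1 under a perfect coupling; bound the mean
  # tightly and the max loosely
  expect_lt(mean(abs(err0)), 0.05)
  expect_lt(mean(abs(err6)), 0.05)
  expect_lt(max(abs(err0)), 0.15)
  expect_lt(max(abs(err6)), 0.15)
})

test_that("B-PSG vs T-PSG copy-number coupling ordering is recovered", {
  b <- small_bundle()
  cat <- b$cat$catalog
  ct <- names(b$cohort$cancers)[1]
  cc <- b$cohort$cancers[[ct]]
  tum <- cc$samples$sample_id[cc$samples$group == "tumor"]
  cors <- flag_strong(expr_factor_correlation(cc$tpm[, tum], cc$cna, "SCNA", ct))
  grp <- setNames(ifelse(cat$true_class == "PSG",
                         ifelse(cat$bias_class == "broad", "B-PSG", "T-PSG"),
                         cat$true_class), cat$gene_id)
  props <- strong_proportions(cors, grp)
  bp <- props$proportion[props$group == "B-PSG"]
  tp <- props$proportion[props$group == "T-PSG"]
  expect_gt(bp, tp)  # planted rho 0.6 vs 0
})
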