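# Age merging, class boundaries, tissue profiles and the model filters.

test_that("merge_ages applies the epoch rules and flags conflicts", {
  syn <- data.frame(gene_id = c("a", "b", "c", "d"),
                    synteny_group = c("12", "vertebrate", "vertebrate", "14"),
                    stringsAsFactors = FALSE)
  fam <- data.frame(gene_id = c("b", "c", "d", "e"),
                    phylostratum = c(2L, 11L, 3L, 6L),
                    stringsAsFactors = FALSE)
  m <- merge_ages(syn, fam)
  get <- function(g, col) m[[col]][m$gene_id == g]
  expect_equal(get("a", "merged_group"), 12L)       # synteny only
  expect_equal(get("b", "merged_group"), 2L)        # old locus takes stratum
  expect_true(get("c", "conflict"))                 # pre-vert locus, post-vert family
  expect_true(is.na(get("c", "merged_group")))
  expect_equal(get("d", "merged_group"), 14L)       # young locus keeps synteny;
  expect_false(get("d", "conflict"))                # old family = derived duplicate
  expect_equal(get("e", "merged_group"), 6L)        # family only
  expect_error(merge_ages(rbind(syn, syn[1, ]), fam), "duplicate")
})

test_that("merge_ages exclusion set matches enumeration of source-pair combinations", {
  # ten genes spanning all combinations of {post-vertebrate synteny,
  # pre-vertebrate synteny, missing} x {old stratum, young stratum, missing}
  syn_vals <- c("9", "9", "9", "vertebrate", "vertebrate", "vertebrate",
                NA, NA, "13", NA)
  fam_vals <- c(2L, 12L, NA, 2L, 12L, NA, 2L, 12L, 9L, NA)
  ids <- sprintf("t%02d", 1:10)
  syn <- data.frame(gene_id = ids[!is.na(syn_vals)],
                    synteny_group = syn_vals[!is.na(syn_vals)])
  fam <- data.frame(gene_id = ids[!is.na(fam_vals)],
                    phylostratum = fam_vals[!is.na(fam_vals)])
  m <- merge_ages(syn, fam)
  m <- m[match(ids[ids %in% m$gene_id], m$gene_id), ]
  # conflicts: exactly the pre-vertebrate synteny + post-vertebrate stratum
  expect_equal(m$gene_id[m$conflict], "t05")
  # merged ages for the rest follow the winner rules
  expect_equal(m$merged_group[m$gene_id %in% c("t01", "t02", "t03")],
               c(9L, 9L, 9L))
  expect_equal(m$merged_group[m$gene_id == "t04"], 2L)
  expect_true(is.na(m$merged_group[m$gene_id == "t06"]))  # undatable
  expect_equal(m$merged_group[m$gene_id %in% c("t07", "t08")], c(2L, 12L))
  expect_equal(m$merged_group[m$gene_id == "t09"], 13L)
  expect_false("t10" %in% m$gene_id)  # absent from both sources
})

test_that("age classes partition groups 1..14 into the configured blocks", {
  toy <- data.frame(gene_id = sprintf("g%02d", 1:14),
                    merged_group = 1:14, conflict = FALSE)
  cl <- classify_age_class(toy)
  expect_equal(as.integer(table(cl$age_class)[c("UC", "EM", "MM", "PSG")]),
               c(3L, 8L, 2L, 1L))
  expect_equal(cl$age_class[cl$merged_group == 1], "UC")
  expect_equal(cl$age_class[cl$merged_group == 14], "PSG")
  # every non-conflicting dated gene gets exactly one class
  expect_false(anyNA(cl$age_class))
  toy$conflict[3] <- TRUE
  expect_true(is.na(classify_age_class(toy)$age_class[3]))
  expect_error(classify_age_class(toy, boundaries = list(UC = 1:3, EM = 4:10,
                                                         MM = 12:13, PSG = 14L)),
               "partition")
})

test_that("tissue profiles classify bias by tau with the strict 0.8 cutoff", {
  panel <- rbind(
    uniform = rep(4, 9),
    onehot = c(1000, rep(0, 8)),
    broadish = c(8, 6, 7, 5, 6, 7, 8, 6, 7))
  colnames(panel) <- paste(rep(c("liver", "brain", "testis"), each = 3),
                           1:3, sep = "_r")
  tissue_of <- rep(c("liver", "brain", "testis"), each = 3)
  prof <- tissue_profiles(panel, tissue_of)
  expect_equal(prof$tau[prof$gene_id == "uniform"], 0)
  expect_equal(prof$tau[prof$gene_id == "onehot"], 1)
  expect_equal(prof$bias_class,
               c("broad", "tissue-biased", "broad"))
  expect_equal(prof$top_tissue[prof$gene_id == "onehot"], "liver")
  # all-zero profile: excluded with a logged reason
  lg <- atavipan:::new_logbook()
  p2 <- rbind(panel, dead = rep(0, 9))
  prof2 <- tissue_profiles(p2, tissue_of, log = lg)
  expect_true(is.na(prof2$tau[prof2$gene_id == "dead"]))
  expect_match(lg$entries, "dead", all = FALSE)
})

test_that("gene-model filters remove one violation each and are order-independent", {
  catalog <- data.frame(
    gene_id = sprintf("g%d", 1:10),
    biotype = c("lincRNA", rep("protein_coding", 9)),
    length = c(2000, 100, rep(2000, 8)),
    paralog_identity = c(0.1, 0.1, 0.98, rep(0.1, 7)),
    stringsAsFactors = FALSE)
  panel <- matrix(5, 10, 4, dimnames = list(catalog$gene_id, paste0("t", 1:4)))
  panel["g4", ] <- 0.1   # under the panel floor everywhere
  tpm <- matrix(10, 10, 20, dimnames = list(catalog$gene_id, paste0("s", 1:20)))
  tpm["g5", 1:6] <- 0    # zero in 30% of samples, in every cancer type
  cohorts <- list(list(tpm = tpm), list(tpm = tpm))
  kept <- filter_gene_models(catalog, panel, cohorts)
  expect_setequal(kept, sprintf("g%d", 6:10))
  # each filter is a pure predicate: relaxing some leaves the others intact
  only34 <- filter_gene_models(catalog, panel, cohorts,
                               min_length = 0, max_identity = 1)
  expect_setequal(setdiff(catalog$gene_id, only34),
                  c("g1", "g4", "g5"))  # biotype filter always applies
  # a gene with identity exactly at 97.5% is kept (<= cutoff)
  catalog$paralog_identity[3] <- 0.975
  expect_true("g3" %in% filter_gene_models(catalog, panel, cohorts))
})
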