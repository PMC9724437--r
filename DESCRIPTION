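Package: atavipan
Title: Pan-Cancer Analysis of Gene-Age Classes Across Tumor Multi-Omics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for studying how genes of different
    evolutionary ages behave in tumors. Merges synteny-based and
    phylostratigraphy gene ages into one catalog, classifies tissue
    specificity (tau index), runs per-cancer tumor-versus-normal
    differential expression with a moderated t-test and a pan-cancer
    up/down classification rule, scores age-class gene sets per sample
    with a from-scratch single-sample GSEA, attributes expression changes
    to copy number and promoter methylation via Spearman correlation,
    annotates uncharacterized genes through purity-controlled partial
    Spearman coexpression and binomial gene-set enrichment, classifies
    prognostic genes from per-cancer Cox models of progression-free
    interval, reprocesses CRISPR knockout screens into dependency and
    common-dependency calls, and assigns genes to developmental stages of
    a 12-stage cerebral time course with per-stage binomial enrichment.
    A synthetic multi-omics generator with planted ground truth makes
    every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    yaml,
    jsonlite
Suggests:
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
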