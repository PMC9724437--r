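# atavipan

Pan-cancer analysis of gene-age classes across tumor multi-omics, as a
tested, reusable R pipeline.

## The problem

Genes can be dated: to unicellular ancestors (UC), early metazoans (EM),
mammals (MM), or primates (PSGs — primate-specific genes). The atavism
hypothesis holds that tumors reactivate unicellular-era programs — UC
genes up, EM genes down. This package provides the machinery to place the
youngest genes on that axis: are PSGs upregulated across cancer types, do
they predict progression, do CRISPR screens show cancer cell lines
depending on them, and do they peak in embryonic cerebral development
where the cell cycle dominates?

It is aimed at computational biologists who want each analysis stage as a
documented, unit-tested function rather than a one-off script, plus a
synthetic multi-omics generator with planted ground truth so the whole
pipeline can be validated end to end without any restricted-access
downloads.

## What's inside

| Stage | Core statistic |
|---|---|
| `merge_ages`, `classify_age_class` | synteny (groups 9–14) + phylostratigraphy (strata 1–8) merge with conflict exclusion |
| `tau_index`, `tissue_profiles` | tissue specificity τ = Σᵢ(1 − xᵢ/x_max)/(N−1), biased if τ > 0.8 |
| `normalize_and_transform`, `moderated_two_group_test` | upper-quartile log2-CPM; moderated t with empirical-Bayes variance shrinkage |
| `classify_pan_cancer` | pan-up ⇔ up in ≥ 3 cancers and n_up ≥ 3·n_down (FDR < 0.05, log2FC ≥ 0.4) |
| `ssgsea_es`, `rescale_scores` | single-sample GSEA: summed difference of weighted in-set vs out-set rank ECDFs (α = 0.25) |
| `expr_factor_correlation`, `strong_proportions` | Spearman ρ of expression vs SCNA (> 0.3) / promoter methylation (< −0.3) |
| `partial_spearman`, `find_partners`, `assign_sets` | purity-controlled partial Spearman ρ_xy·z; median across cancers ≥ 0.4; binomial set assignment (OR > 1, p < 0.05) |
| `fit_cox`, `classify_prognostic`, `top_k_prognostic` | per-gene Cox on progression-free interval; net = unfavorable − favorable cancers |
| `normalize_screen`, `call_dependencies`, `common_dependency` | anchor reference medians at −1/0; per-line top 11.7% essential; 90th-percentile rank, top 6.2% common |
| `stage_medians`, `assign_stage`, `stage_enrichment` | 12-stage Z-scores, assigned if Z_max > 1.2; per-stage binomial excess/depletion |
| `synth_config`, `write_synth_inputs`, `run_all` | planted-truth generator, YAML manifest, end-to-end orchestration |

## Worked example

```r
library(atavipan)

cfg <- synth_config(seed = 42)          # 2000 genes, 13 cancer types,
manifest <- write_synth_inputs(cfg, "synth")  # 150 tumor + 16 normal each
results <- run_all(manifest)
results$recovery
```

```
                    task n_planted n_called precision recall
1                 pan_up        50       50    1.0000  1.000
2               pan_down        30       29    1.0000  0.967
3 prognostic_unfavorable        10       10    0.9000  0.900
4   prognostic_favorable        10       11    0.9091  1.000
5             dependency        16      303    0.0528  1.000
6              dev_stage       300     1782        NA  1.000
7        module_partners        40       NA        NA  0.936
```

Reading this: all 50 planted pan-cancer-upregulated genes (20 PSGs, 30 UC)
are recovered with no false positives; nearly all planted prognostic
hazard links are found (the off-diagonal calls are the false discoveries
a per-cancer FDR of 0.05 licenses); every planted essential gene earns a
dependency call (dependency *precision* is not meaningful under
quota-based essential calling, which flags a fixed 11.7% of genes per
cell line by construction); planted developmental-stage biases and ~94%
of coexpression-module partners are recovered. Individual calls live in
the returned tables, e.g.

```r
head(results$pan[results$pan$label == "pan-up", ], 3)
#     gene_id n_up n_down  label
# 80    g0085    5      0 pan-up
# 130   g0137    5      0 pan-up
# 132   g0139    6      0 pan-up
```

and everything is also written as provenance-headered TSVs under the
manifest's output directory, with every exclusion logged with a reason in
`exclusions.log`.

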