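# Shared synthetic fixtures, built in code and cached for the session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# a small but fully-featured configuration for module-level tests
small_config <- function(seed = 7, ...) {
  defaults <- list(n_genes = 400L, n_cancer_types = 5L, n_tumor = 60L,
                   n_normal = 12L, n_pan_up_psg = 4L, n_pan_up_uc = 8L,
                   n_pan_down_em = 8L, n_affected_cancers = 4L,
                   n_prognostic = 4L, module_size = 15L,
                   n_planted_essential = 6L, n_ref_essential = 20L,
                   n_ref_nonessential = 40L,
                   lines_per_cancer = c(6L, 6L, 6L, 6L, 3L),
                   n_stage_biased = 10L, seed = seed)
  do.call(synth_config, utils::modifyList(defaults, list(...)))
}

small_bundle <- function() cached("small_bundle", {
  cfg <- small_config()
  cb <- generate_catalog(cfg)
  list(cfg = cfg, cat = cb, cohort = generate_cohort(cb, cfg),
       screen = generate_screen(cb, cfg),
       dev = generate_dev_series(cb, cfg))
})

# the default-scale study conditions (13 cancers, 2000 genes, seed 42),
# written to disk and run end to end once; reused by the acceptance suite
default_run <- function() cached("default_run", {
  dir <- file.path(tempdir(), "atavipan-default-synth")
  cfg <- synth_config(seed = 42)
  manifest <- write_synth_inputs(cfg, dir)
  t0 <- Sys.time()
  results <- run_all(manifest)
  list(cfg = cfg, dir = dir, manifest = manifest, results = results,
       elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs")),
       truth = jsonlite::read_json(file.path(dir, "truth.json"),
                                   simplifyVector = TRUE))
})
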