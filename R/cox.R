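# Per-gene, per-cancer Cox proportional-hazards association with the
# progression-free interval, and the net prognostic classification.
#
# Fitting delegates to survival::coxph (partial likelihood, Efron tie
# handling, Wald p for the expression term); the bespoke content is the
# per-SD expression coding, the per-cancer FDR, the net classifier and
# the top-k robustness mode.

#' Per-gene Cox fits against progression-free interval in one cancer type
#'
#' Expression enters as log2(TPM + 1) standardized to unit SD (so hazard
#' ratios are per SD), alongside clinical covariates (age numeric, stage
#' ordinal, gender) when present with at least two observed levels.
#' Genes failing the per-cancer expression filter, degenerate after
#' standardization, or failing convergence are skipped with a logged
#' reason. FDR is Benjamini-Hochberg across the tested genes of the
#' cancer type.
#'
#' @param tpm genes x tumor-samples matrix (columns matched to patients
#'   via `samples`).
#' @param surv data frame: `patient`, `time`, `event` and optional
#'   covariates among `age`, `stage`, `gender`.
#' @param samples data frame mapping `sample_id` to `patient` (tumor rows).
#' @param cancer_type label.
#' @param genes genes to test (default all rows).
#' @param standardize z-score expression (default TRUE; FALSE fits the
#'   raw log2 scale).
#' @param zero_fraction expression-filter cutoff (default 0.2).
#' @param min_patients,min_events design floors (defaults 30 / 10).
#' @param log logbook (optional).
#' @return data frame: `gene_id`, `cancer_type`, `beta`, `hr`, `ci_lo`,
#'   `ci_hi`, `p`, `fdr`, `n`, `n_events`.
#' @export
fit_cox <- function(tpm, surv, samples, cancer_type = NA, genes = rownames(tpm),
                    standardize = TRUE, zero_fraction = 0.2,
                    min_patients = 30L, min_events = 10L, log = NULL) {
  tum <- samples[samples$group == "tumor", c("sample_id", "patient")]
  tum <- tum[tum$patient %in% surv$patient, ]
  sv <- surv[match(tum$patient, surv$patient), ]
  covs <- intersect(c("age", "stage", "gender"), names(sv))
  covs <- covs[vapply(covs, function(cv) length(unique(na.omit(sv[[cv]]))) >= 2L,
                      logical(1))]
  keep <- stats::complete.cases(sv[c("time", "event", covs)])
  tum <- tum[keep, ]; sv <- sv[keep, ]
  if (nrow(sv) < min_patients) stopf("%s: only %d patients (< %d)",
                                     cancer_type, nrow(sv), min_patients)
  if (sum(sv$event) < min_events) stopf("%s: only %d events (< %d)",
                                        cancer_type, sum(sv$event), min_events)
  expr <- tpm[, tum$sample_id, drop = FALSE]
  ok <- expressed_in_cancer(expr, zero_fraction)
  base <- sv[c("time", "event", covs)]
  if ("gender" %in% covs) base$gender <- as.factor(base$gender)
  srv <- survival::Surv(base$time, base$event)
  rhs <- paste(c("x", covs), collapse = " + ")
  fml <- stats::as.formula(paste("srv ~", rhs))

  rows <- lapply(genes, function(g) {
    if (!isTRUE(ok[g])) {
      log_entry(log, "fit_cox: %s fails expression filter in %s", g, cancer_type)
      return(NULL)
    }
    x <- log2(expr[g, ] + 1)
    if (sd(x) == 0) {
      log_entry(log, "fit_cox: %s constant expression in %s", g, cancer_type)
      return(NULL)
    }
    if (standardize) x <- as.numeric(scale(x))
    dat <- cbind(base, x = x)
    fit <- tryCatch(
      survival::coxph(fml, data = dat, ties = "efron",
                      control = survival::coxph.control(eps = 1e-7)),
      error = function(e) NULL, warning = function(w) {
        suppressWarnings(survival::coxph(fml, data = dat, ties = "efron",
                                         control = survival::coxph.control(eps = 1e-7)))
      })
    if (is.null(fit) || is.na(coef(fit)["x"])) {
      log_entry(log, "fit_cox: %s failed to converge in %s", g, cancer_type)
      return(NULL)
    }
    b <- coef(fit)["x"]; se <- sqrt(diag(fit$var))[which(names(coef(fit)) == "x")]
    z <- b / se
    data.frame(gene_id = g, cancer_type = cancer_type, beta = as.numeric(b),
               hr = exp(as.numeric(b)),
               ci_lo = exp(b - 1.959964 * se), ci_hi = exp(b + 1.959964 * se),
               p = 2 * pnorm(abs(z), lower.tail = FALSE),
               n = nrow(dat), n_events = sum(dat$event),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) return(NULL)
  res$fdr <- bh_fdr(res$p)
  rownames(res) <- NULL
  res
}

#' Net prognostic classification across cancer types
#'
#' A cancer counts as unfavorable for a gene when the Cox association is
#' significant (FDR < `alpha_fdr`) with HR > 1 (higher expression, faster
#' progression) and favorable when significant with HR < 1. The net value
#' (unfavorable minus favorable counts) labels the gene `unfavorable`
#' (net > 0), `favorable` (net < 0), `intermediate` (significant
#' somewhere, net 0), or `non-prognostic` (no significant cancer).
#'
#' @param cox_results row-bound [fit_cox()] tables across cancers.
#' @param alpha_fdr per-cancer significance cutoff (default 0.05).
#' @param significant optional logical vector overriding the FDR rule
#'   (used by the top-k mode).
#' @return data frame: `gene_id`, `n_unfavorable`, `n_favorable`, `net`,
#'   `label`.
#' @export
classify_prognostic <- function(cox_results, alpha_fdr = 0.05,
                                significant = NULL) {
  sig <- significant %||% (cox_results$fdr < alpha_fdr)
  unf <- tapply(sig & cox_results$hr > 1, cox_results$gene_id, sum)
  fav <- tapply(sig & cox_results$hr < 1, cox_results$gene_id, sum)
  genes <- names(unf)
  net <- unf - fav
  label <- ifelse(unf + fav == 0, "non-prognostic",
                  ifelse(net > 0, "unfavorable",
                         ifelse(net < 0, "favorable", "intermediate")))
  data.frame(gene_id = genes, n_unfavorable = as.integer(unf),
             n_favorable = as.integer(fav), net = as.integer(net),
             label = as.character(label), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Top-k most PFI-correlated genes per cancer (robustness mode)
#'
#' Selects the `k` smallest Cox p-values within each cancer type (ties at
#' the boundary broken by gene id) and feeds the same net classifier,
#' sidestepping the order-of-magnitude differences in per-cancer
#' significant-gene counts.
#'
#' @param cox_results row-bound [fit_cox()] tables.
#' @param k genes per cancer (default 1500).
#' @return list with `selected` (per-cancer list of gene ids) and
#'   `classes` (net classification treating selection as significance).
#' @export
top_k_prognostic <- function(cox_results, k = 1500L) {
  parts <- split(cox_results, cox_results$cancer_type)
  selected <- lapply(parts, function(d) {
    d <- d[order(d$p, d$gene_id), ]
    head(d$gene_id, k)
  })
  sig <- mapply(function(d, sel) d$gene_id %in% sel,
                parts, selected, SIMPLIFY = FALSE)
  ordered <- do.call(rbind, parts)
  classes <- classify_prognostic(ordered, significant = unlist(sig))
  list(selected = selected, classes = classes)
}
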