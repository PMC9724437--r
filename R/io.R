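# Readers and writers for the plain-text interchange formats the pipeline
# uses: GMT gene sets, BED-like probe annotation, and the YAML run manifest.

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then member gene ids, tab-separated.
#'
#' @param path GMT file path.
#' @return named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stopf("malformed GMT line: %s", substr(l, 1, 50))
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional character vector, recycled to `length(sets)`.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = "na") {
  descriptions <- rep_len(descriptions, length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED-like methylation probe annotation
#'
#' Columns: chrom, start, end, probe_id, gene_id (0-based, half-open
#' coordinates as in BED). A single-CpG probe occupies `[start, start + 1)`.
#'
#' @param path file path (tab separated, no header, `#` comments allowed).
#' @return data frame with columns chrom, start, end, probe_id, gene_id.
#' @export
read_probe_bed <- function(path) {
  x <- read.delim(path, header = FALSE, comment.char = "#",
                  stringsAsFactors = FALSE)
  if (ncol(x) < 5) stopf("probe BED needs >=5 columns, got %d", ncol(x))
  names(x)[1:5] <- c("chrom", "start", "end", "probe_id", "gene_id")
  x[1:5]
}

#' Read a run manifest from YAML
#'
#' @param path YAML file.
#' @return a list with classes validated by [validate_manifest()].
#' @export
read_manifest <- function(path) {
  m <- yaml::read_yaml(path)
  m$manifest_dir <- normalizePath(dirname(path))
  m
}

#' Validate a run manifest
#'
#' Checks that all referenced input files exist and thresholds are within
#' documented ranges.
#'
#' @param manifest list as returned by [read_manifest()].
#' @return the manifest, invisibly; errors otherwise.
#' @export
validate_manifest <- function(manifest) {
  req <- c("inputs", "output_dir", "seed")
  miss <- setdiff(req, names(manifest))
  if (length(miss)) stopf("manifest missing fields: %s", paste(miss, collapse = ", "))
  for (nm in names(manifest$inputs)) {
    p <- manifest_path(manifest, nm)
    if (!file.exists(p)) stopf("manifest input '%s' not found: %s", nm, p)
  }
  th <- manifest$thresholds %||% list()
  chk <- function(name, lo, hi) {
    v <- th[[name]]
    if (!is.null(v) && (v < lo || v > hi))
      stopf("threshold %s = %s outside [%s, %s]", name, v, lo, hi)
  }
  chk("alpha", 0, 1); chk("lfc", 0, 10); chk("reg_cutoff", 0, 1)
  chk("partner_cutoff", 0, 1); chk("essential_fraction", 0, 1)
  chk("common_top_fraction", 0, 1); chk("dev_floor", 0, Inf)
  chk("z_cutoff", 0, Inf); chk("tau_cutoff", 0, 1)
  invisible(manifest)
}

manifest_path <- function(manifest, name) {
  p <- manifest$inputs[[name]]
  if (is.null(p)) return(NULL)
  if (!grepl("^/", p) && !is.null(manifest$manifest_dir))
    p <- file.path(manifest$manifest_dir, p)
  p
}
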