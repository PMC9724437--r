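# Internal helpers shared across stages.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed from a base seed and a file/stage tag
#'
#' Each emitted output draws from its own RNG stream so that toggling one
#' stage never perturbs another. The child seed is a deterministic hash of
#' the base seed and the tag, kept within 32-bit integer range.
#'
#' @param seed integer base seed.
#' @param tag character stage/file tag, e.g. `"expression"`.
#' @return an integer seed.
#' @keywords internal
child_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 2654435.0 + h * 97003.0) %% 2147483647)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Write a TSV with '#'-prefixed provenance header lines
#'
#' @param x data frame.
#' @param path output path.
#' @param provenance named list recorded as `# key: value` lines
#'   (package version is always included; no timestamps, so reruns are
#'   byte-identical).
#' @return `path`, invisibly.
#' @export
write_tsv_prov <- function(x, path, provenance = list()) {
  prov <- c(list(atavipan = as.character(utils::packageVersion("atavipan"))),
            provenance)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(prov)) {
    writeLines(sprintf("# %s: %s", k, paste(format(prov[[k]]), collapse = ",")), con)
  }
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv_prov()], skipping provenance lines
#'
#' @param path file path.
#' @return a data frame.
#' @export
read_tsv_prov <- function(path) {
  read.delim(path, comment.char = "#", sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE)
}

# A minimal exclusion log: stages append reasons; run_all() flushes to file.
new_logbook <- function() {
  env <- new.env(parent = emptyenv())
  env$entries <- character(0)
  env
}

log_entry <- function(log, fmt, ...) {
  if (!is.null(log)) log$entries <- c(log$entries, sprintf(fmt, ...))
  invisible(NULL)
}
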