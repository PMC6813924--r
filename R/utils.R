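# Internal helpers shared across modules.

#' Canonical variant key
#'
#' Builds the `chrom:pos:ref:alt` key used to identify a single alternate
#' allele at a site throughout the package.
#'
#' @param chrom Chromosome label.
#' @param pos 1-based position.
#' @param ref Reference allele string.
#' @param alt Alternate allele string.
#' @return Character vector of keys.
#' @export
variantKey <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

## Classed conditions so callers can distinguish format / configuration /
## ingest / validation failures programmatically.
famrareStop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "famrare_error", "error")))
}

formatError        <- function(msg) famrareStop(msg, "famrare_format_error")
configurationError <- function(msg) famrareStop(msg, "famrare_configuration_error")
ingestError        <- function(msg) famrareStop(msg, "famrare_ingest_error")
validationError    <- function(msg) famrareStop(msg, "famrare_validation_error")

`%||%` <- function(a, b) if (is.null(a)) b else a

## Panel MAF with the absent-treated-as-zero rule. Logs (via message) how many
## panel-absent entries were zero-filled, distinctly from true MAF-0 entries.
effectiveMaf <- function(maf, panel, verbose = TRUE) {
  absent <- is.na(maf)
  if (verbose && any(absent)) {
    message(sum(absent), " variant(s) absent from ", panel,
            " treated as MAF 0 (rare-filter rule)")
  }
  ifelse(absent, 0, maf)
}
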