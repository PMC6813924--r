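# Tab-separated side tables: population frequency panels and cohort
# allele-count tables (alt/total alleles per group, as printed in published
# association tables).

#' Read a population allele-frequency table
#'
#' @param path Tab-separated file with header columns `chrom`, `pos`, `ref`,
#'   `alt`, `maf` (global minor/alternate allele frequency as a fraction).
#' @return data.frame validated so every `maf` lies in \[0, 0.5\].
#' @export
readFrequencyTable <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = c("character", "integer", "character",
                                          "character", "numeric"))
  need <- c("chrom", "pos", "ref", "alt", "maf")
  if (!all(need %in% colnames(tab)))
    formatError(paste("frequency table must have columns:",
                      paste(need, collapse = ", ")))
  if (any(tab$maf < 0 | tab$maf > 0.5))
    validationError("panel MAF values must lie in [0, 0.5]")
  key <- variantKey(tab$chrom, tab$pos, tab$ref, tab$alt)
  if (anyDuplicated(key))
    ingestError(paste("duplicated variant in frequency table:",
                      key[duplicated(key)][1]))
  tab
}

#' Write a population allele-frequency table
#'
#' @param tab data.frame as returned by [readFrequencyTable()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeFrequencyTable <- function(tab, path) {
  utils::write.table(tab[, c("chrom", "pos", "ref", "alt", "maf")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cohort allele-count table
#'
#' One row per (variant, group): `alt` alternate alleles observed out of
#' `total` alleles genotyped in that group, the form in which published
#' case-control allele counts are reported.
#'
#' @param path Tab-separated file with header columns `variant`, `group`,
#'   `alt`, `total`.
#' @return data.frame with validated counts (`0 <= alt <= total`,
#'   `total > 0`).
#' @export
readCountsTable <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = c("character", "character",
                                          "integer", "integer"))
  need <- c("variant", "group", "alt", "total")
  if (!all(need %in% colnames(tab)))
    formatError(paste("counts table must have columns:",
                      paste(need, collapse = ", ")))
  if (any(tab$alt < 0))
    validationError("alt allele counts must be non-negative")
  if (any(tab$total <= 0))
    validationError("total allele counts must be positive")
  bad <- tab$alt > tab$total
  if (any(bad))
    validationError(paste0("alt > total for ", tab$variant[which(bad)[1]],
                           " in group ", tab$group[which(bad)[1]]))
  tab
}

#' Write a candidate report
#'
#' Serializes a candidate table (output of the shortlisting functions) as TSV
#' and/or JSON with a stable column layout.
#'
#' @param candidates A `DataFrame`/data.frame of candidate records.
#' @param path Output path; extension picks the format (`.tsv` or `.json`).
#' @return `path`, invisibly.
#' @export
writeCandidateReport <- function(candidates, path) {
  df <- as.data.frame(candidates)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null", pretty = TRUE)
  } else {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = ".")
  }
  invisible(path)
}
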