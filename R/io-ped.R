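# Extended-PED pedigree I/O.
#
# Dialect: the 6 standard PED columns (family, individual, father, mother,
# sex, phenotype) followed by three extension columns:
#   7  affection category  {unaffected, breast_cancer, ovarian_cancer, other_cancer}
#   8  age at diagnosis    years, "." for unknown
#   9  index flag          0/1 (family ascertained through this patient)
# The standard phenotype column stays 1 (unaffected) / 2 (affected) so the
# file remains readable by conventional PED consumers; the affection category
# column distinguishes breast, ovarian and other cancers. "0" encodes an
# unknown parent. Whether an individual is sequenced is not a pedigree
# property: it is derived from VCF sample membership when a cohort is built.

#' Read an extended PED file
#'
#' @param path Path to a tab-separated, headerless 9-column extended PED file
#'   (see the package vignette for the dialect).
#' @return A [Pedigree-class] with `is_sequenced = NA` (resolved when the
#'   pedigree is attached to a cohort).
#' @export
readPedigree <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "#")
  if (ncol(raw) != 9)
    formatError(paste0("extended PED must have 9 columns, found ", ncol(raw),
                       " in ", path))
  colnames(raw) <- c("family_id", "sample_id", "father_id", "mother_id",
                     "sex", "phenotype", "affection", "age", "index")
  m <- data.frame(
    family_id = raw$family_id,
    sample_id = raw$sample_id,
    father_id = ifelse(raw$father_id == "0", NA_character_, raw$father_id),
    mother_id = ifelse(raw$mother_id == "0", NA_character_, raw$mother_id),
    sex = c("1" = "male", "2" = "female")[raw$sex],
    affection = raw$affection,
    age_at_diagnosis = suppressWarnings(as.numeric(ifelse(raw$age == ".",
                                                          NA, raw$age))),
    is_index = raw$index == "1",
    is_sequenced = NA,
    stringsAsFactors = FALSE)
  if (anyNA(m$sex)) formatError("PED sex column must be 1 (male) or 2 (female)")
  declared_aff <- raw$phenotype == "2"
  actual_aff <- m$affection != "unaffected"
  if (!all(declared_aff == actual_aff))
    formatError(paste("PED phenotype column disagrees with affection category for:",
                      paste(m$sample_id[declared_aff != actual_aff], collapse = ", ")))
  tryCatch(Pedigree(m), error = function(e) {
    msg <- conditionMessage(e)
    if (grepl("cycle", msg)) famrareStop(msg, "famrare_cycle_error")
    if (grepl("unknown parent", msg)) famrareStop(msg, "famrare_reference_error")
    stop(e)
  })
}

#' Write an extended PED file
#'
#' Inverse of [readPedigree()]; the `is_sequenced` column is not serialized.
#'
#' @param ped A [Pedigree-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writePedigree <- function(ped, path) {
  m <- members(ped)
  out <- data.frame(
    m$family_id, m$sample_id,
    ifelse(is.na(m$father_id), "0", m$father_id),
    ifelse(is.na(m$mother_id), "0", m$mother_id),
    ifelse(m$sex == "male", "1", "2"),
    ifelse(m$affection == "unaffected", "1", "2"),
    m$affection,
    ifelse(is.na(m$age_at_diagnosis), ".", as.character(m$age_at_diagnosis)),
    ifelse(m$is_index, "1", "0"))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
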