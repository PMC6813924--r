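#' @import methods
NULL

#' Per-transcript consequence annotations of a cohort
#'
#' @param x A [VariantCohort-class] object.
#' @return A [S4Vectors::DataFrame] with one row per (variant, transcript)
#'   annotation: `key`, `allele`, `gene`, `transcript_id`, `consequence`,
#'   `exon_rank`, `exon_total`, `hgvs_c`, `hgvs_p`.
#' @export
setGeneric("annotations", function(x) standardGeneric("annotations"))

#' Pedigree attached to a cohort
#'
#' @param x A [VariantCohort-class] object.
#' @return A [Pedigree-class] object.
#' @export
setGeneric("pedigree", function(x) standardGeneric("pedigree"))

#' Alternate-allele dosage matrix
#'
#' @param x A [VariantCohort-class] object.
#' @return Integer matrix (variants x samples) of alt-allele counts
#'   (0, 1, 2 or `NA` for missing calls).
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' Pedigree members as a data.frame
#'
#' @param x A [Pedigree-class] object.
#' @return A `data.frame`, one row per individual.
#' @export
setGeneric("members", function(x) standardGeneric("members"))
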