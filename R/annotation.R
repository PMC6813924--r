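# Consequence classification, the last-exon rule and in-silico predictor
# consensus. All rules operate on a single (variant, transcript) annotation;
# a variant is loss-of-function if it is loss-of-function on at least one of
# its transcripts.

LOF_TERMS <- c("stop_gained", "frameshift_variant",
               "splice_acceptor_variant", "splice_donor_variant")

VARIANT_BASED_EXTRA_TERMS <- c("inframe_insertion", "inframe_deletion",
                               "missense_variant", "stop_lost")

KNOWN_TERMS <- c(LOF_TERMS, VARIANT_BASED_EXTRA_TERMS,
                 "synonymous_variant", "intron_variant",
                 "splice_region_variant", "start_lost",
                 "5_prime_UTR_variant", "3_prime_UTR_variant",
                 "upstream_gene_variant", "downstream_gene_variant")

#' Classify a consequence term as loss-of-function
#'
#' Loss-of-function covers stop-gain, frameshift and essential (+/- 2 bp)
#' splice-site variants, i.e. the Sequence Ontology terms `stop_gained`,
#' `frameshift_variant`, `splice_acceptor_variant`, `splice_donor_variant`.
#' Unrecognized terms trigger a warning and are classified non-LoF.
#'
#' @param consequence Character vector of Sequence Ontology consequence terms.
#' @return Logical vector.
#' @examples
#' classifyLof(c("stop_gained", "missense_variant", "splice_donor_variant"))
#' @export
classifyLof <- function(consequence) {
  unknown <- !(consequence %in% KNOWN_TERMS)
  if (any(unknown))
    warning("unrecognized consequence term(s) classified non-LoF: ",
            paste(unique(consequence[unknown]), collapse = ", "))
  consequence %in% LOF_TERMS
}

#' Admission of a consequence into a prioritization variant universe
#'
#' The gene-based workflow admits only loss-of-function variants; the
#' variant-based workflow additionally admits in-frame indels, missense and
#' stop-loss variants.
#'
#' @param consequence Character vector of consequence terms.
#' @param mode `"gene_based"` or `"variant_based"`.
#' @return Logical vector.
#' @export
inVariantUniverse <- function(consequence,
                              mode = c("gene_based", "variant_based")) {
  mode <- match.arg(mode)
  lof <- classifyLof(consequence)
  if (mode == "gene_based") lof
  else lof | consequence %in% VARIANT_BASED_EXTRA_TERMS
}

#' Last-exon membership of an annotation
#'
#' Truncating variants in a transcript's final exon often escape
#' nonsense-mediated decay; cross-cohort replication excludes them. Returns
#' `NA` when the exon rank is unknown — callers treat unknown as excluded
#' from replication (conservative).
#'
#' @param exon_rank,exon_total Integer vectors (`NA` allowed).
#' @return Logical vector (`NA` = unknown).
#' @examples
#' isLastExon(c(3, 11, NA), c(11, 11, 11))
#' @export
isLastExon <- function(exon_rank, exon_total) {
  ifelse(is.na(exon_rank) | is.na(exon_total), NA, exon_rank == exon_total)
}

#' In-silico predictor consensus
#'
#' A variant passes when at least `k` of the (up to seven) prediction tools
#' call it damaging; `unknown` verdicts never count as damaging.
#' Loss-of-function variants bypass the check entirely.
#'
#' @param damaging_count Integer vector: number of damaging verdicts.
#' @param k Minimum damaging verdicts required (default 1: the workflow
#'   retains variants called damaging by a single tool).
#' @param is_lof Logical vector; `TRUE` bypasses the consensus check.
#' @return Logical vector.
#' @export
predictorConsensus <- function(damaging_count, k = 1L, is_lof = FALSE) {
  is_lof | damaging_count >= k
}

#' Count damaging verdicts across a predictor panel
#'
#' @param calls Character matrix or data.frame (variants x tools) of verdicts;
#'   matched case-insensitively against `"damaging"`.
#' @return Integer vector of damaging counts.
#' @export
damagingCount <- function(calls) {
  calls <- as.matrix(calls)
  rowSums(tolower(calls) == "damaging", na.rm = TRUE)
}

## damaging_count per cohort row from the pred_call_* rowData columns
cohortDamagingCount <- function(cohort) {
  rd <- SummarizedExperiment::rowData(cohort)
  cols <- grep("^pred_call_", colnames(rd), value = TRUE)
  if (!length(cols)) return(integer(nrow(cohort)))
  damagingCount(as.data.frame(rd[, cols, drop = FALSE]))
}
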