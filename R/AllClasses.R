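#' @include AllGenerics.R utils.R
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment rowData "rowData<-"
#'   colData "colData<-" assay assays assayNames rowRanges
#' @importFrom S4Vectors "mcols<-"
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
NULL

AFFECTION_LEVELS <- c("unaffected", "breast_cancer", "ovarian_cancer", "other_cancer")

## ---------------------------------------------------------------------------
## Pedigree
## ---------------------------------------------------------------------------

#' Pedigree of one or more families with cancer-affection phenotype
#'
#' Wraps a per-individual table with resolved parent links. `affection` is one
#' of `unaffected`, `breast_cancer`, `ovarian_cancer`, `other_cancer`; any of
#' the three cancer categories counts as "affected". Index patients (the
#' family members through whom a family was ascertained) must be affected.
#'
#' @slot members data.frame with columns `family_id`, `sample_id`,
#'   `father_id`, `mother_id` (`NA` for founders), `sex` ("female"/"male"),
#'   `affection`, `age_at_diagnosis`, `is_index`, `is_sequenced`.
#' @export
setClass("Pedigree", slots = c(members = "data.frame"))

validPedigree <- function(object) {
  m <- object@members
  req <- c("family_id", "sample_id", "father_id", "mother_id", "sex",
           "affection", "age_at_diagnosis", "is_index", "is_sequenced")
  miss <- setdiff(req, colnames(m))
  if (length(miss)) return(paste("missing pedigree columns:", paste(miss, collapse = ", ")))
  if (anyDuplicated(m$sample_id)) return("sample_id values must be unique")
  if (!all(m$affection %in% AFFECTION_LEVELS))
    return(paste("affection must be one of:", paste(AFFECTION_LEVELS, collapse = ", ")))
  if (!all(m$sex %in% c("female", "male"))) return("sex must be 'female' or 'male'")
  bad_idx <- m$is_index & m$affection == "unaffected"
  if (any(bad_idx))
    return(paste("index individuals must be affected:",
                 paste(m$sample_id[bad_idx], collapse = ", ")))
  for (col in c("father_id", "mother_id")) {
    p <- m[[col]]
    known <- is.na(p) | p %in% m$sample_id
    if (!all(known))
      return(paste("unknown parent id(s):", paste(unique(p[!known]), collapse = ", ")))
    same_fam <- is.na(p) | m$family_id[match(p, m$sample_id)] == m$family_id
    if (!all(same_fam, na.rm = TRUE)) return("parents must belong to the same family")
  }
  ## cycle detection: walk ancestry from every individual
  idx <- seq_len(nrow(m))
  names(idx) <- m$sample_id
  for (i in idx) {
    seen <- logical(nrow(m))
    frontier <- i
    while (length(frontier)) {
      if (any(seen[frontier]))
        return(paste("ancestry cycle involving", m$sample_id[i]))
      seen[frontier] <- TRUE
      parents <- c(m$father_id[frontier], m$mother_id[frontier])
      frontier <- idx[parents[!is.na(parents)]]
    }
  }
  TRUE
}
setValidity("Pedigree", validPedigree)

#' Construct a Pedigree
#'
#' @param members data.frame as described in [Pedigree-class]. `father_id` /
#'   `mother_id` use `NA` for unknown (founder) parents.
#' @return A [Pedigree-class] object.
#' @examples
#' ped <- Pedigree(data.frame(
#'   family_id = "F01", sample_id = c("F01S01", "F01S02"),
#'   father_id = NA_character_, mother_id = c(NA, "F01S01"),
#'   sex = "female", affection = "breast_cancer",
#'   age_at_diagnosis = c(46, 44), is_index = c(FALSE, TRUE),
#'   is_sequenced = TRUE))
#' members(ped)
#' @export
Pedigree <- function(members) {
  members$family_id <- as.character(members$family_id)
  members$sample_id <- as.character(members$sample_id)
  members$father_id <- as.character(members$father_id)
  members$mother_id <- as.character(members$mother_id)
  rownames(members) <- NULL
  new("Pedigree", members = members)
}

#' @rdname members
#' @export
setMethod("members", "Pedigree", function(x) x@members)

#' @describeIn Pedigree-class number of individuals
#' @param x A Pedigree.
#' @export
setMethod("length", "Pedigree", function(x) nrow(x@members))

setMethod("show", "Pedigree", function(object) {
  m <- object@members
  aff <- m$affection != "unaffected"
  cat("Pedigree with", nrow(m), "individuals in", length(unique(m$family_id)),
      "families\n  affected:", sum(aff),
      " sequenced:", sum(m$is_sequenced, na.rm = TRUE),
      " index patients:", sum(m$is_index), "\n")
})

## affected = any cancer category (the study counts relatives affected by any
## form of cancer)
isAffected <- function(ped) {
  m <- members(ped)
  stats::setNames(m$affection != "unaffected", m$sample_id)
}

## ---------------------------------------------------------------------------
## VariantCohort
## ---------------------------------------------------------------------------

#' Multi-sample variant cohort with annotations and pedigree
#'
#' A [SummarizedExperiment::RangedSummarizedExperiment] with one row per
#' (site, alt allele) — multi-allelic records are split on ingest — and one
#' column per sequenced sample. Assays:
#' \describe{
#'   \item{AC}{alt-allele dosage 0/1/2, `NA` = missing call}
#'   \item{DP}{total read depth}
#'   \item{AD}{alt-supporting read depth}
#'   \item{GQ}{phred-scaled genotype quality}
#' }
#' `rowData` carries `REF`, `ALT`, `ID`, `QUAL`, panel frequencies
#' `maf_panel_a` / `maf_panel_b` (`NA` = absent from that panel) and the
#' per-tool in-silico predictor verdicts (`pred_call_*`, `pred_score_*`,
#' `damaging_count`). Per-transcript consequence annotations live in the
#' `annotations` slot; the full pedigree (including non-sequenced members) in
#' the `pedigree` slot.
#'
#' @slot annotations [S4Vectors::DataFrame] of per-transcript annotations.
#' @slot pedigree [Pedigree-class].
#' @export
setClass("VariantCohort",
         contains = "RangedSummarizedExperiment",
         slots = c(annotations = "DFrame", pedigree = "Pedigree"))

validVariantCohort <- function(object) {
  an <- assayNames(object)
  need <- c("AC", "DP", "AD", "GQ")
  if (!all(need %in% an))
    return(paste("missing assays:", paste(setdiff(need, an), collapse = ", ")))
  rd <- rowData(object)
  for (col in c("REF", "ALT", "maf_panel_a", "maf_panel_b"))
    if (!col %in% colnames(rd)) return(paste("missing rowData column:", col))
  if (nrow(object)) {
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
      return("row names must be unique variant keys")
    bases_ok <- grepl("^[ACGT]+$", rd$REF) & grepl("^[ACGT]+$", rd$ALT)
    if (!all(bases_ok))
      return("REF/ALT must be non-empty strings over {A,C,G,T}")
    maf_ok <- function(x) all(is.na(x) | (x >= 0 & x <= 0.5))
    if (!maf_ok(rd$maf_panel_a) || !maf_ok(rd$maf_panel_b))
      return("panel MAFs must lie in [0, 0.5] where present")
  }
  ann <- object@annotations
  if (nrow(ann) && !all(ann$key %in% rownames(object)))
    return("annotation keys must match cohort variant keys")
  ped <- object@pedigree
  missing_ped <- setdiff(colnames(object), members(ped)$sample_id)
  if (length(missing_ped))
    return(paste("samples without pedigree entry:",
                 paste(missing_ped, collapse = ", ")))
  TRUE
}
setValidity("VariantCohort", validVariantCohort)

## Internal constructor: `variants` is a data.frame with chrom/pos/ref/alt/
## id/qual (+ optional maf + predictor columns); assays are matrices keyed the
## same way; `ann` the per-transcript annotation table.
newVariantCohort <- function(variants, ac, dp, ad, gq, ann, ped) {
  key <- variantKey(variants$chrom, variants$pos, variants$ref, variants$alt)
  if (anyDuplicated(key))
    ingestError(paste("duplicated (chrom,pos,ref,alt) record(s):",
                      paste(unique(key[duplicated(key)]), collapse = ", ")))
  gr <- GRanges(seqnames = as.character(variants$chrom),
                ranges = IRanges(start = variants$pos,
                                 width = nchar(variants$ref)))
  names(gr) <- key
  rd <- DataFrame(REF = variants$ref, ALT = variants$alt,
                  ID = variants$id %||% NA_character_,
                  QUAL = variants$qual %||% NA_real_,
                  maf_panel_a = variants$maf_panel_a %||% rep(NA_real_, nrow(variants)),
                  maf_panel_b = variants$maf_panel_b %||% rep(NA_real_, nrow(variants)))
  extra <- setdiff(colnames(variants),
                   c("chrom", "pos", "ref", "alt", "id", "qual",
                     "maf_panel_a", "maf_panel_b"))
  for (col in extra) rd[[col]] <- variants[[col]]
  S4Vectors::mcols(gr) <- rd
  dimn <- list(key, colnames(ac))
  dimnames(ac) <- dimnames(dp) <- dimnames(ad) <- dimnames(gq) <- dimn
  se <- SummarizedExperiment(
    assays = list(AC = ac, DP = dp, AD = ad, GQ = gq),
    rowRanges = gr)
  m <- members(ped)
  cd <- m[match(colnames(se), m$sample_id),
          c("family_id", "sex", "affection", "age_at_diagnosis",
            "is_index", "is_sequenced")]
  rownames(cd) <- colnames(se)
  colData(se) <- DataFrame(cd)
  ann <- DataFrame(ann)
  new("VariantCohort", se, annotations = ann, pedigree = ped)
}

#' @rdname annotations
#' @export
setMethod("annotations", "VariantCohort", function(x) x@annotations)

#' @rdname pedigree
#' @export
setMethod("pedigree", "VariantCohort", function(x) x@pedigree)

#' @rdname genotypes
#' @export
setMethod("genotypes", "VariantCohort", function(x) assay(x, "AC"))

setMethod("show", "VariantCohort", function(object) {
  cat("VariantCohort:", nrow(object), "variant records x", ncol(object),
      "samples\n")
  ann <- annotations(object)
  cat("  annotations:", nrow(ann), "(variant, transcript) pairs in",
      length(unique(ann$gene)), "genes\n")
  rd <- rowData(object)
  cat("  panel frequencies: ", sum(!is.na(rd$maf_panel_a)), "/", nrow(object),
      " in panel A, ", sum(!is.na(rd$maf_panel_b)), "/", nrow(object),
      " in panel B\n", sep = "")
  show(pedigree(object))
})

#' Variant keys of a cohort
#'
#' @param x A [VariantCohort-class].
#' @return Character vector `chrom:pos:ref:alt`, one per row.
#' @export
variantKeys <- function(x) rownames(x)
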