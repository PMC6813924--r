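# Gene-based discovery shortlisting and cross-cohort replication.
#
# Discovery keeps loss-of-function variants that are rare in both reference
# panels (MAF <= 0.1%, panel-absent treated as 0 and logged) and segregate in
# affected relatives: carried by >= 2 affected sequenced patients of one
# family, or by the single affected sequenced member in families where
# co-segregation cannot be ascertained. Counted carrier genotypes must pass
# the genotype-QC surrogate (the programmatic stand-in for visual read
# inspection). Replication requires a second rare LoF variant on the same
# transcript in >= 1 unrelated replication patient, with both variants
# outside the transcript's last exon.

#' Genotype-QC surrogate
#'
#' Programmatic stand-in for visual inspection of carrier calls in a genome
#' browser: a heterozygous call passes when depth, genotype quality and
#' allele balance look clean; a homozygous-alt call additionally needs near-
#' complete alt support.
#'
#' @param ac Alt-allele dosage (0/1/2, `NA` missing). Missing calls fail.
#' @param dp,ad,gq Depth, alt-supporting depth, genotype quality (vectors
#'   recycled against `ac`).
#' @param minDepth Minimum depth (default 10).
#' @param minGq Minimum genotype quality (default 20).
#' @param balance Allele-balance band for heterozygous calls (default
#'   `c(0.25, 0.75)`).
#' @param homBalance Minimum alt fraction for homozygous-alt calls
#'   (default 0.9).
#' @return Logical vector.
#' @export
qcSurrogate <- function(ac, dp, ad, gq, minDepth = 10, minGq = 20,
                        balance = c(0.25, 0.75), homBalance = 0.9) {
  bal <- ifelse(dp > 0, ad / dp, NA)
  base <- !is.na(ac) & !is.na(dp) & !is.na(gq) & dp >= minDepth & gq >= minGq
  het_ok <- !is.na(bal) & bal >= balance[1] & bal <= balance[2]
  hom_ok <- !is.na(bal) & bal >= homBalance
  ref_ok <- !is.na(bal) & bal <= 1 - homBalance
  base & ((ac == 1L & het_ok) | (ac == 2L & hom_ok) | (ac == 0L & ref_ok))
}

## per-sample carrier/QC bookkeeping shared by both shortlisting workflows
cohortCarrierInfo <- function(cohort, minDepth, minGq, balance, homBalance) {
  m <- members(pedigree(cohort))
  missing_ped <- setdiff(colnames(cohort), m$sample_id)
  if (length(missing_ped))
    famrareStop(paste("no pedigree for sample(s):",
                      paste(missing_ped, collapse = ", ")),
                "famrare_pedigree_error")
  idx <- match(colnames(cohort), m$sample_id)
  list(
    family = m$family_id[idx],
    affected = m$affection[idx] != "unaffected" & m$is_sequenced[idx],
    unaffected = m$affection[idx] == "unaffected" & m$is_sequenced[idx],
    qc = qcSurrogate(SummarizedExperiment::assay(cohort, "AC"),
                     SummarizedExperiment::assay(cohort, "DP"),
                     SummarizedExperiment::assay(cohort, "AD"),
                     SummarizedExperiment::assay(cohort, "GQ"),
                     minDepth = minDepth, minGq = minGq, balance = balance,
                     homBalance = homBalance))
}

## rare in both panels at threshold (absent-from-panel treated as MAF 0,
## logged separately from true MAF-0 entries); strict = use < instead of <=
rareInBothPanels <- function(cohort, mafMax, strict = FALSE, verbose = TRUE) {
  rd <- SummarizedExperiment::rowData(cohort)
  a <- effectiveMaf(rd$maf_panel_a, "panel A", verbose = verbose)
  b <- effectiveMaf(rd$maf_panel_b, "panel B", verbose = verbose)
  if (strict) a < mafMax & b < mafMax else a <= mafMax & b <= mafMax
}

candidateColumns <- c("key", "chrom", "pos", "ref", "alt", "gene",
                      "transcript_id", "consequence", "exon_rank",
                      "exon_total", "carrier_samples", "carrier_families",
                      "n_carrier_patients", "carriers_in_unaffected",
                      "maf_panel_a", "maf_panel_b", "qc_pass", "stage",
                      "strategies")

emptyCandidates <- function() {
  S4Vectors::DataFrame(
    key = character(), chrom = character(), pos = integer(),
    ref = character(), alt = character(), gene = character(),
    transcript_id = character(), consequence = character(),
    exon_rank = integer(), exon_total = integer(),
    carrier_samples = character(), carrier_families = character(),
    n_carrier_patients = integer(), carriers_in_unaffected = integer(),
    maf_panel_a = numeric(), maf_panel_b = numeric(), qc_pass = logical(),
    stage = character(), strategies = character())
}

buildCandidateRecords <- function(cohort, ann_rows, carrier_list, info,
                                  stage, strategies = "") {
  if (!nrow(ann_rows)) return(emptyCandidates())
  rd <- SummarizedExperiment::rowData(cohort)
  gr <- SummarizedExperiment::rowRanges(cohort)
  i <- match(ann_rows$key, rownames(cohort))
  carriers <- unname(carrier_list[ann_rows$key])
  rec <- S4Vectors::DataFrame(
    key = ann_rows$key,
    chrom = as.character(GenomicRanges::seqnames(gr))[i],
    pos = GenomicRanges::start(gr)[i],
    ref = rd$REF[i], alt = rd$ALT[i],
    gene = ann_rows$gene, transcript_id = ann_rows$transcript_id,
    consequence = ann_rows$consequence,
    exon_rank = ann_rows$exon_rank, exon_total = ann_rows$exon_total,
    carrier_samples = vapply(carriers, function(cs)
      paste(cs$affected, collapse = ","), ""),
    carrier_families = vapply(carriers, function(cs)
      paste(unique(cs$families), collapse = ","), ""),
    n_carrier_patients = vapply(carriers, function(cs)
      length(cs$affected), 0L),
    carriers_in_unaffected = vapply(carriers, function(cs)
      length(cs$unaffected), 0L),
    maf_panel_a = rd$maf_panel_a[i], maf_panel_b = rd$maf_panel_b[i],
    qc_pass = TRUE, stage = stage, strategies = strategies)
  rec <- rec[order(rec$gene, rec$chrom, rec$pos, rec$transcript_id), ]
  rownames(rec) <- NULL
  rec
}

#' Gene-based discovery shortlist
#'
#' Implements the discovery arm of the gene-based prioritization workflow: a
#' variant is shortlisted when (1) it is loss-of-function on at least one
#' transcript, (2) its MAF is at most `mafMax` in both reference panels
#' (panel-absent treated as MAF 0, logged), (3) within at least one family it
#' is carried by `minFamilyCarriers` affected sequenced patients — or by the
#' single affected sequenced member in families where co-segregation cannot
#' be ascertained — and (4) every counted carrier genotype passes the QC
#' surrogate. One record is emitted per qualifying (variant, transcript)
#' pair, sorted by (gene, chrom, pos).
#'
#' @param cohort A [VariantCohort-class] (kinship-excluded samples already
#'   removed).
#' @param mafMax Panel MAF threshold, inclusive (default 0.001, i.e. 0.1%).
#' @param minFamilyCarriers Affected sequenced co-carriers required within a
#'   family (default 2).
#' @param minDepth,minGq,balance,homBalance QC-surrogate thresholds, see
#'   [qcSurrogate()].
#' @param lastExonAtDiscovery Apply the last-exon exclusion already at
#'   discovery (default `FALSE`: it is a replication-stage rule).
#' @param verbose Log filter diagnostics.
#' @return [S4Vectors::DataFrame] of candidate records (stage `"discovery"`).
#' @export
shortlistGenesDiscovery <- function(cohort, mafMax = 0.001,
                                    minFamilyCarriers = 2L,
                                    minDepth = 10, minGq = 20,
                                    balance = c(0.25, 0.75), homBalance = 0.9,
                                    lastExonAtDiscovery = FALSE,
                                    verbose = TRUE) {
  info <- cohortCarrierInfo(cohort, minDepth, minGq, balance, homBalance)
  ann <- as.data.frame(annotations(cohort))
  lof_ann <- ann[classifyLof(ann$consequence), , drop = FALSE]
  if (lastExonAtDiscovery) {
    last <- isLastExon(lof_ann$exon_rank, lof_ann$exon_total)
    lof_ann <- lof_ann[!(last %in% TRUE), , drop = FALSE]
  }
  rare <- rareInBothPanels(cohort, mafMax, verbose = verbose)
  lof_ann <- lof_ann[rare[match(lof_ann$key, rownames(cohort))], , drop = FALSE]

  ac <- genotypes(cohort)
  n_aff_fam <- table(info$family[info$affected])
  carrier_list <- list()
  keep <- logical(nrow(lof_ann))
  for (r in seq_len(nrow(lof_ann))) {
    key <- lof_ann$key[r]
    if (!is.null(carrier_list[[key]])) { keep[r] <- carrier_list[[key]]$ok; next }
    i <- match(key, rownames(cohort))
    carrier <- !is.na(ac[i, ]) & ac[i, ] >= 1L & info$qc[i, ]
    aff_car <- carrier & info$affected
    fams <- unique(info$family[aff_car])
    ok <- FALSE
    for (f in fams) {
      n_car <- sum(aff_car & info$family == f)
      n_aff <- if (f %in% names(n_aff_fam)) n_aff_fam[[f]] else 0L
      if (n_car >= minFamilyCarriers || (n_aff == 1L && n_car >= 1L)) {
        ok <- TRUE; break
      }
    }
    carrier_list[[key]] <- list(
      ok = ok,
      affected = colnames(cohort)[aff_car],
      families = info$family[aff_car],
      unaffected = colnames(cohort)[carrier & info$unaffected])
    keep[r] <- ok
  }
  kept <- lof_ann[keep, , drop = FALSE]
  if (verbose)
    message("gene-based discovery: ", length(unique(kept$key)), "/",
            length(unique(lof_ann$key)), " rare LoF variants segregate in ",
            "affected relatives")
  buildCandidateRecords(cohort, kept, carrier_list, info, stage = "discovery")
}

#' Cross-cohort gene replication
#'
#' A discovery candidate gene replicates when at least one replication
#' patient carries any rare loss-of-function variant (same panel-MAF rule) on
#' the *same transcript* as the discovery variant, with both the discovery
#' and the replication variants outside the transcript's last exon. Unknown
#' exon position is treated as last-exon (conservative: excluded).
#'
#' @param candidates Discovery records from [shortlistGenesDiscovery()].
#' @param repCohort Replication [VariantCohort-class] of unrelated patients.
#' @param mafMax Panel MAF threshold (default 0.001).
#' @param verbose Log diagnostics.
#' @return [S4Vectors::DataFrame] of replicated candidates (stage
#'   `"replicated"`) with the matching replication variant keys and carrier
#'   counts appended.
#' @export
replicateGenes <- function(candidates, repCohort, mafMax = 0.001,
                           verbose = TRUE) {
  rep_ann <- as.data.frame(annotations(repCohort))
  rep_ann <- rep_ann[classifyLof(rep_ann$consequence), , drop = FALSE]
  rep_last <- isLastExon(rep_ann$exon_rank, rep_ann$exon_total)
  rep_ann <- rep_ann[rep_last %in% FALSE, , drop = FALSE]
  rare <- rareInBothPanels(repCohort, mafMax, verbose = verbose)
  rep_ann <- rep_ann[rare[match(rep_ann$key, rownames(repCohort))], , drop = FALSE]
  ac <- genotypes(repCohort)
  n_carriers <- rowSums(!is.na(ac) & ac >= 1L)
  rep_ann <- rep_ann[n_carriers[match(rep_ann$key, rownames(repCohort))] >= 1L,
                     , drop = FALSE]

  out <- candidates[integer(0), ]
  out$replication_keys <- character(0)
  out$n_replication_carriers <- integer(0)
  disc_last <- isLastExon(candidates$exon_rank, candidates$exon_total)
  for (r in seq_len(nrow(candidates))) {
    if (!(disc_last[r] %in% FALSE)) next
    hits <- rep_ann[rep_ann$transcript_id == candidates$transcript_id[r], ,
                    drop = FALSE]
    if (!nrow(hits)) next
    row <- candidates[r, ]
    row$stage <- "replicated"
    row$replication_keys <- paste(unique(hits$key), collapse = ",")
    row$n_replication_carriers <-
      sum(n_carriers[match(unique(hits$key), rownames(repCohort))])
    out <- rbind(out, row)
  }
  if (verbose)
    message("replication: ", length(unique(out$gene)), "/",
            length(unique(candidates$gene)), " genes with same-transcript ",
            "non-last-exon rare LoF support")
  rownames(out) <- NULL
  out
}
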