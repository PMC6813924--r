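# Variant-based prioritization: three shortlisting strategies over the
# extended variant universe (LoF + in-frame indels + missense + stop-loss),
# followed by the shared MAF / predicted-pathogenicity / segregation / QC
# filters and a cross-cohort presence lookup.
#
#   CGV  — variants in a user-supplied cancer-gene list
#   SVGU — identical variants shared across unrelated patients, or distinct
#          variants in the same gene (same transcript) in unrelated patients
#   FSV  — ultra-rare variants (MAF < 0.01%) confined to one patient/family

## affected sequenced carriers per variant (raw dosage, missing excluded)
patientCarrierMatrix <- function(cohort) {
  m <- members(pedigree(cohort))
  idx <- match(colnames(cohort), m$sample_id)
  patient <- m$affection[idx] != "unaffected" & m$is_sequenced[idx]
  ac <- genotypes(cohort)
  carrier <- !is.na(ac) & ac >= 1L
  list(carrier = carrier, patient = patient, family = m$family_id[idx])
}

#' Cancer-gene variant strategy (CGV)
#'
#' Tags variants of the admitted universe whose gene symbol appears in the
#' supplied cancer-gene list (matched after uppercasing both sides).
#'
#' @param cohort A [VariantCohort-class].
#' @param geneList Character vector of gene symbols (e.g. read with
#'   `readLines()` from a one-symbol-per-line file).
#' @return data.frame of tags: `key`, `strategy`, `reason`.
#' @export
cgvSelect <- function(cohort, geneList) {
  geneList <- trimws(geneList)
  geneList <- geneList[nzchar(geneList)]
  if (!length(geneList))
    configurationError("cancer gene list is empty")
  ann <- as.data.frame(annotations(cohort))
  ann <- ann[inVariantUniverse(ann$consequence, "variant_based"), , drop = FALSE]
  hit <- toupper(ann$gene) %in% toupper(geneList)
  keys <- unique(ann$key[hit])
  data.frame(key = keys,
             strategy = rep("CGV", length(keys)),
             reason = rep(NA_character_, length(keys)),
             stringsAsFactors = FALSE)
}

#' Shared variants/genes in unrelated patients (SVGU)
#'
#' Tags (a) identical variants carried by at least two unrelated patients and
#' (b) distinct admitted variants of the same gene (same transcript, unless
#' relaxed) carried by unrelated patients. Two patients are unrelated when
#' they belong to different families *and* their estimated kinship is below
#' `phiMax`.
#'
#' @param cohort A [VariantCohort-class].
#' @param kin Kinship output of [kinshipMatrix()] (or a phi matrix) covering
#'   the cohort samples.
#' @param phiMax Unrelatedness threshold (default 0.0442).
#' @param sameTranscript Require distinct-variant gene sharing to map to the
#'   same transcript (default `TRUE`).
#' @return data.frame of tags: `key`, `strategy`,
#'   `reason` (`identical_variant_shared` / `same_gene_distinct_variants`).
#' @export
svguSelect <- function(cohort, kin, phiMax = 0.0442, sameTranscript = TRUE) {
  phi <- if (is.matrix(kin)) kin else attr(kin, "phi")
  pc <- patientCarrierMatrix(cohort)
  samples <- colnames(cohort)
  unrelatedPair <- function(s1, s2) {
    pc$family[match(s1, samples)] != pc$family[match(s2, samples)] &
      !is.na(phi[cbind(s1, s2)]) & phi[cbind(s1, s2)] < phiMax
  }
  anyUnrelated <- function(set1, set2) {
    grid <- expand.grid(s1 = set1, s2 = set2, stringsAsFactors = FALSE)
    grid <- grid[grid$s1 != grid$s2, , drop = FALSE]
    nrow(grid) > 0 && any(unrelatedPair(grid$s1, grid$s2))
  }
  patients <- samples[pc$patient]
  carriers <- lapply(seq_len(nrow(cohort)), function(i)
    samples[pc$carrier[i, ] & pc$patient])
  names(carriers) <- rownames(cohort)

  ann <- as.data.frame(annotations(cohort))
  ann <- ann[inVariantUniverse(ann$consequence, "variant_based"), , drop = FALSE]
  uni_keys <- unique(ann$key)

  tags <- list()
  ## (a) identical variant shared across unrelated patients
  for (key in uni_keys) {
    cs <- carriers[[key]]
    if (length(cs) >= 2 && anyUnrelated(cs, cs))
      tags[[length(tags) + 1L]] <- data.frame(
        key = key, strategy = "SVGU", reason = "identical_variant_shared",
        stringsAsFactors = FALSE)
  }
  ## (b) distinct variants, same gene (and transcript), unrelated carriers
  group_col <- if (sameTranscript) ann$transcript_id else ann$gene
  for (g in unique(group_col)) {
    g_keys <- unique(ann$key[group_col == g])
    if (length(g_keys) < 2) next
    for (a in seq_along(g_keys)) for (b in seq_along(g_keys)) {
      if (a >= b) next
      if (anyUnrelated(carriers[[g_keys[a]]], carriers[[g_keys[b]]])) {
        tags[[length(tags) + 1L]] <- data.frame(
          key = g_keys[c(a, b)], strategy = "SVGU",
          reason = "same_gene_distinct_variants", stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(tags)) unique(do.call(rbind, tags)) else
    data.frame(key = character(), strategy = character(),
               reason = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Family-specific variant strategy (FSV)
#'
#' Tags ultra-rare variants (MAF strictly below `fsvMafMax` in both panels,
#' panel-absent treated as 0) whose carriers are all confined to a single
#' family or singleton patient.
#'
#' @param cohort A [VariantCohort-class].
#' @param fsvMafMax Strict MAF threshold (default 1e-4, i.e. 0.01%).
#' @param verbose Log the panel-absent count.
#' @return data.frame of tags: `key`, `strategy`, `reason`.
#' @export
fsvSelect <- function(cohort, fsvMafMax = 1e-4, verbose = FALSE) {
  pc <- patientCarrierMatrix(cohort)
  rare <- rareInBothPanels(cohort, fsvMafMax, strict = TRUE, verbose = verbose)
  ann <- as.data.frame(annotations(cohort))
  uni <- unique(ann$key[inVariantUniverse(ann$consequence, "variant_based")])
  keys <- character(0)
  for (key in intersect(uni, rownames(cohort)[rare])) {
    i <- match(key, rownames(cohort))
    fams <- unique(pc$family[pc$carrier[i, ]])
    if (length(fams) == 1L) keys <- c(keys, key)
  }
  data.frame(key = keys, strategy = rep("FSV", length(keys)),
             reason = rep(NA_character_, length(keys)),
             stringsAsFactors = FALSE)
}

#' Variant-based shortlist
#'
#' Combines the strategy tags with the shared filters: a variant is
#' shortlisted when it carries at least one strategy tag, its MAF is at most
#' `mafMax` in both panels, it is loss-of-function or called damaging by at
#' least `consensusK` predictor tools, it is present in *all* affected
#' sequenced members of each carrier family, and every counted carrier call
#' passes the QC surrogate. Tag sets are retained on the output records.
#'
#' @param cohort A [VariantCohort-class].
#' @param tags data.frame of strategy tags (rbind of [cgvSelect()],
#'   [svguSelect()], [fsvSelect()] outputs).
#' @param mafMax Panel MAF threshold (default 0.001).
#' @param consensusK Predictor-consensus threshold (default 1).
#' @param minDepth,minGq,balance,homBalance QC thresholds, see
#'   [qcSurrogate()].
#' @param verbose Log diagnostics.
#' @return [S4Vectors::DataFrame] of candidate records with `strategies`
#'   (comma-joined sorted tag set) and per-strategy reasons.
#' @export
shortlistVariants <- function(cohort, tags, mafMax = 0.001, consensusK = 1L,
                              minDepth = 10, minGq = 20,
                              balance = c(0.25, 0.75), homBalance = 0.9,
                              verbose = TRUE) {
  stopifnot(all(c("key", "strategy") %in% colnames(tags)))
  ## structural invariant: a single-family variant cannot simultaneously be
  ## shared across unrelated patients
  fsv_keys <- tags$key[tags$strategy == "FSV"]
  shared_keys <- tags$key[tags$strategy == "SVGU" &
                            tags$reason %in% "identical_variant_shared"]
  overlap <- intersect(fsv_keys, shared_keys)
  if (length(overlap))
    famrareStop(paste("FSV and SVGU identical-shared tags overlap:",
                      paste(overlap, collapse = ", ")),
                "famrare_invariant_error")

  info <- cohortCarrierInfo(cohort, minDepth, minGq, balance, homBalance)
  ann <- as.data.frame(annotations(cohort))
  uni_ann <- ann[inVariantUniverse(ann$consequence, "variant_based"), ,
                 drop = FALSE]
  tagged <- unique(tags$key)
  rare <- rareInBothPanels(cohort, mafMax, verbose = verbose)
  dmg <- cohortDamagingCount(cohort)
  is_lof_key <- vapply(split(classifyLof(ann$consequence), ann$key), any,
                       logical(1))
  ac <- genotypes(cohort)

  carrier_list <- list()
  ok_keys <- character(0)
  for (key in intersect(tagged, unique(uni_ann$key))) {
    i <- match(key, rownames(cohort))
    if (!rare[i]) next
    lof <- isTRUE(is_lof_key[[key]])
    if (!predictorConsensus(dmg[i], consensusK, lof)) next
    carrier <- !is.na(ac[i, ]) & ac[i, ] >= 1L
    if (!any(carrier)) next
    fams <- unique(info$family[carrier])
    ## every affected sequenced member of each carrier family must carry
    segregates <- all(vapply(fams, function(f) {
      aff_members <- info$affected & info$family == f
      all(carrier[aff_members])
    }, logical(1)))
    if (!segregates) next
    counted <- carrier & info$affected
    if (any(counted & !info$qc[i, ])) next
    carrier_list[[key]] <- list(
      ok = TRUE,
      affected = colnames(cohort)[counted],
      families = info$family[counted],
      unaffected = colnames(cohort)[carrier & info$unaffected])
    ok_keys <- c(ok_keys, key)
  }
  kept_ann <- uni_ann[uni_ann$key %in% ok_keys, , drop = FALSE]
  kept_ann <- kept_ann[!duplicated(kept_ann$key), , drop = FALSE]
  tag_str <- vapply(kept_ann$key, function(k)
    paste(sort(unique(tags$strategy[tags$key == k])), collapse = ","), "")
  reason_str <- vapply(kept_ann$key, function(k) {
    r <- sort(unique(stats::na.omit(tags$reason[tags$key == k])))
    if (length(r)) paste(r, collapse = ",") else NA_character_
  }, "")
  rec <- buildCandidateRecords(cohort, kept_ann, carrier_list, info,
                               stage = "discovery")
  rec$strategies <- unname(tag_str[match(rec$key, kept_ann$key)])
  rec$strategy_reasons <- unname(reason_str[match(rec$key, kept_ann$key)])
  if (verbose)
    message("variant-based shortlist: ", nrow(rec), "/", length(tagged),
            " tagged variants pass MAF/pathogenicity/segregation/QC")
  rec
}

#' Cross-cohort presence of shortlisted variants
#'
#' Flags candidates whose identical (chrom, pos, ref, alt) record is carried
#' by at least one replication patient.
#'
#' @param candidates Records from [shortlistVariants()] (or any candidate
#'   table with a `key` column).
#' @param repCohort Replication [VariantCohort-class].
#' @return `candidates` with `present_in_replication` and
#'   `n_replication_carriers` columns appended.
#' @export
crossCohortPresence <- function(candidates, repCohort) {
  ac <- genotypes(repCohort)
  n_car <- rowSums(!is.na(ac) & ac >= 1L)
  hit <- match(candidates$key, rownames(repCohort))
  n <- ifelse(is.na(hit), 0L, n_car[hit])
  candidates$present_in_replication <- n >= 1L
  candidates$n_replication_carriers <- as.integer(n)
  candidates
}
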