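# Replication cohort: unrelated singleton index patients, sharing the
# discovery cohort's variant universe and frequency panels, with optional
# planted loss-of-function variants in candidate genes (same transcript by
# default, configurable last-exon / other-transcript placements for testing
# the cross-cohort matching rules) and optional identical discovery variants
# (for presence lookups).

#' Simulate a replication cohort of unrelated index patients
#'
#' @param sim Discovery simulation from [simulateCohort()] whose variant
#'   universe, annotations and panels are reused.
#' @param plant Optional data.frame of replication plantings, one row per
#'   planted variant: `gene` (a gene present in the discovery annotations),
#'   `n_carriers` (default 1), `in_last_exon` (default `FALSE`),
#'   `same_transcript` (default `TRUE`). Each planting is a *distinct* new
#'   loss-of-function (frameshift) variant in that gene.
#' @param plant_identical Character vector of discovery variant keys to plant
#'   identically (one carrier each), for presence lookups.
#' @param n_patients Number of unrelated singleton patients (default 51).
#' @param seed Random seed (defaults to the discovery seed + 1).
#' @return list with `cohort` ([VariantCohort-class]) and `truth`
#'   (data.frame of planted replication variants).
#' @export
simulateReplicationCohort <- function(sim, plant = NULL,
                                      plant_identical = character(0),
                                      n_patients = 51L,
                                      seed = sim$config@seed + 1L) {
  cohort <- sim$cohort
  config <- sim$config
  withSeed(seed, {
    rd <- SummarizedExperiment::rowData(cohort)
    variants <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(cohort)),
      pos = GenomicRanges::start(SummarizedExperiment::rowRanges(cohort)),
      ref = rd$REF, alt = rd$ALT, id = rd$ID, qual = rd$QUAL,
      maf_panel_a = rd$maf_panel_a, maf_panel_b = rd$maf_panel_b,
      stringsAsFactors = FALSE)
    pred_cols <- grep("^pred_", colnames(rd), value = TRUE)
    for (col in pred_cols) variants[[col]] <- rd[[col]]
    ann <- as.data.frame(annotations(cohort))
    keys <- rownames(cohort)
    freq <- unname(sim$truth$founder_freq[keys])
    freq[is.na(freq)] <- 0

    ## planted replication LoF variants (new records appended to the table)
    truth <- NULL
    if (!is.null(plant) && nrow(plant)) {
      plant$n_carriers <- plant$n_carriers %||% rep(1L, nrow(plant))
      if (is.null(plant$in_last_exon)) plant$in_last_exon <- FALSE
      if (is.null(plant$same_transcript)) plant$same_transcript <- TRUE
      trows <- list()
      for (i in seq_len(nrow(plant))) {
        g_ann <- ann[ann$gene == plant$gene[i], , drop = FALSE]
        if (!nrow(g_ann))
          configurationError(paste("gene not in discovery annotations:",
                                   plant$gene[i]))
        tx0 <- g_ann$transcript_id[1]
        tot <- g_ann$exon_total[1]
        tx <- if (plant$same_transcript[i]) tx0 else paste0(tx0, "X")
        rank <- if (plant$in_last_exon[i]) tot else max(1L, min(2L, tot - 1L))
        base_key <- g_ann$key[1]
        base_pos <- as.integer(strsplit(base_key, ":")[[1]][2])
        p_pos <- base_pos + 17L + i
        p_chrom <- strsplit(base_key, ":")[[1]][1]
        ra <- refAltFor("frameshift_variant")
        vrow <- data.frame(chrom = p_chrom, pos = p_pos, ref = ra$ref,
                           alt = ra$alt, id = NA_character_, qual = 999,
                           maf_panel_a = NA_real_, maf_panel_b = NA_real_,
                           stringsAsFactors = FALSE)
        for (col in pred_cols) {
          vrow[[col]] <- if (grepl("_call_", col)) "unknown" else
            round(stats::runif(1), 3)
        }
        key_i <- variantKey(p_chrom, p_pos, ra$ref, ra$alt)
        hgp <- hgvsFor("frameshift_variant", p_pos, ra$ref, ra$alt, rank)
        variants <- rbind(variants, vrow)
        ann <- rbind(ann, data.frame(
          key = key_i, allele = ra$alt, gene = plant$gene[i],
          transcript_id = tx, consequence = "frameshift_variant",
          exon_rank = rank, exon_total = tot, hgvs_c = hgp$c,
          hgvs_p = hgp$p, stringsAsFactors = FALSE))
        freq <- c(freq, 0)
        trows[[i]] <- data.frame(
          key = key_i, gene = plant$gene[i], transcript_id = tx,
          n_carriers = plant$n_carriers[i],
          in_last_exon = plant$in_last_exon[i],
          same_transcript = plant$same_transcript[i],
          stringsAsFactors = FALSE)
      }
      truth <- do.call(rbind, trows)
    }
    nv <- nrow(variants)
    new_keys <- variantKey(variants$chrom, variants$pos, variants$ref,
                           variants$alt)

    ids <- sprintf("RF%02dS01", seq_len(n_patients))
    ped <- Pedigree(data.frame(
      family_id = sprintf("RF%02d", seq_len(n_patients)), sample_id = ids,
      father_id = NA_character_, mother_id = NA_character_, sex = "female",
      affection = "breast_cancer",
      age_at_diagnosis = sample(25:60, n_patients, replace = TRUE),
      is_index = TRUE, is_sequenced = TRUE, stringsAsFactors = FALSE))

    AC <- matrix(stats::rbinom(nv * n_patients, 2L, rep(freq, n_patients)),
                 nv, n_patients, dimnames = list(new_keys, ids))
    if (!is.null(truth)) {
      for (i in seq_len(nrow(truth))) {
        carriers <- sample(n_patients, truth$n_carriers[i])
        AC[match(truth$key[i], new_keys), carriers] <- 1L
        truth$carriers[i] <- paste(ids[carriers], collapse = ",")
      }
    }
    for (k in plant_identical) {
      s <- match(k, new_keys)
      if (is.na(s))
        configurationError(paste("identical planting not in cohort:", k))
      AC[s, sample(n_patients, 1)] <- 1L
    }
    qc <- simulateCallMetrics(AC, config)
    rep_cohort <- newVariantCohort(variants, qc$AC, qc$DP, qc$AD, qc$GQ,
                                   ann, ped)
    list(cohort = rep_cohort, truth = truth)
  })
}
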