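# Synthetic cohort generation by Mendelian gene-dropping.
#
# Founder genotypes are drawn from configured minor-allele-frequency strata;
# non-founder alleles are transmitted from parents (one random allele per
# parent per site, independent sites). Risk variants are planted in chosen
# families as a founder-carrier plus a forced transmission to the first
# child, guaranteeing an informative segregating parent-offspring (or sib)
# pair, and affection status is assigned by penetrance for carriers plus a
# background sporadic (phenocopy) rate for everyone else. Families with no
# affected member are ascertained through a forced affected child,
# mirroring the entry criteria of a hereditary-cancer family study.

DEFAULT_PREDICTOR_PANEL <- c("SIFT", "PolyPhen2", "MutationTaster", "CADD",
                             "LRT", "FATHMM", "PROVEAN")

DEFAULT_CONSEQUENCE_WEIGHTS <- c(
  missense_variant = 0.50, synonymous_variant = 0.13, stop_gained = 0.05,
  frameshift_variant = 0.05, splice_donor_variant = 0.025,
  splice_acceptor_variant = 0.025, inframe_deletion = 0.04,
  inframe_insertion = 0.04, stop_lost = 0.02, intron_variant = 0.06,
  splice_region_variant = 0.06)

#' Simulation configuration
#'
#' Defines the study conditions a synthetic cohort emulates. Defaults mirror
#' the scale of a 17-family, 52-individual hereditary breast/ovarian cancer
#' discovery cohort.
#'
#' @slot n_families,n_individuals Cohort scale.
#' @slot n_background_variants Number of background (non-planted) sites.
#' @slot maf_strata,stratum_weights Point masses for founder/panel allele
#'   frequencies; stratum 0 means a private variant (one founder carrier,
#'   absent from both reference panels).
#' @slot planted_risk data.frame of planted risk variants: `gene`,
#'   `consequence`, `n_carrier_families`, `penetrance`.
#' @slot sporadic_rate Background phenocopy affection rate.
#' @slot consequence_weights Sampling weights over consequence terms for
#'   background variants.
#' @slot predictor_panel Names of the in-silico predictor tools (<= 7).
#' @slot mean_depth Mean simulated read depth.
#' @slot genotype_missing_rate Fraction of calls set missing ("./.").
#' @slot qc_noise_rate Fraction of calls given low depth/quality, for
#'   exercising the genotype-QC surrogate.
#' @slot n_sample_swaps Number of samples replaced by unrelated genotypes
#'   (simulated sample mix-ups, for kinship discordance).
#' @slot seed Random seed; identical config + seed gives byte-identical
#'   outputs.
#' @export
setClass("SimulationConfig", slots = c(
  n_families = "integer", n_individuals = "integer",
  n_background_variants = "integer",
  maf_strata = "numeric", stratum_weights = "numeric",
  planted_risk = "data.frame",
  sporadic_rate = "numeric", consequence_weights = "numeric",
  predictor_panel = "character", mean_depth = "numeric",
  genotype_missing_rate = "numeric", qc_noise_rate = "numeric",
  n_sample_swaps = "integer", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  if (object@n_families < 1L) return("need at least one family")
  if (object@n_individuals < 2L * object@n_families)
    return("need at least two individuals per family")
  if (length(object@maf_strata) != length(object@stratum_weights))
    return("maf_strata and stratum_weights must have equal length")
  if (any(object@maf_strata < 0 | object@maf_strata > 0.5))
    return("maf_strata must lie in [0, 0.5]")
  if (nrow(object@planted_risk)) {
    need <- c("gene", "consequence", "n_carrier_families", "penetrance")
    if (!all(need %in% colnames(object@planted_risk)))
      return(paste("planted_risk needs columns:", paste(need, collapse = ", ")))
    if (any(object@planted_risk$penetrance < 0 |
            object@planted_risk$penetrance > 1))
      return("penetrance must lie in [0, 1]")
    if (any(object@planted_risk$n_carrier_families > object@n_families))
      return("more carrier families requested than families simulated")
  }
  if (length(object@predictor_panel) > 7L)
    return("predictor panel holds at most 7 tools")
  if (object@sporadic_rate < 0 || object@sporadic_rate > 1)
    return("sporadic_rate must lie in [0, 1]")
  TRUE
})

#' Build a simulation configuration
#'
#' @param n_families,n_individuals Cohort scale (defaults: 17 families,
#'   52 individuals).
#' @param n_background_variants Number of background sites (default 300).
#' @param maf_strata,stratum_weights Founder/panel MAF point masses and their
#'   sampling weights. Stratum 0 = private variant (one founder carrier,
#'   absent from both panels).
#' @param planted_risk data.frame with columns `gene`, `consequence`,
#'   `n_carrier_families`, `penetrance`; `NULL` for a null simulation.
#' @param sporadic_rate Phenocopy affection rate (default 0.05).
#' @param consequence_weights Named weights over consequence terms for
#'   background variants.
#' @param predictor_panel Predictor tool names (default: 7-tool panel).
#' @param mean_depth Mean read depth (default 80).
#' @param genotype_missing_rate,qc_noise_rate Call-level missingness and
#'   low-quality noise fractions (default 0: post-QC-grade calls).
#' @param n_sample_swaps Simulated sample mix-ups (default 0).
#' @param seed Random seed.
#' @return A [SimulationConfig-class].
#' @export
simulationConfig <- function(n_families = 17L, n_individuals = 52L,
                             n_background_variants = 300L,
                             maf_strata = c(0, 5e-5, 5e-4, 2e-3, 1e-2, 0.25),
                             stratum_weights = c(0.07, 0.14, 0.22, 0.14,
                                                 0.13, 0.30),
                             planted_risk = data.frame(
                               gene = "RISKG1", consequence = "stop_gained",
                               n_carrier_families = 1L, penetrance = 1),
                             sporadic_rate = 0.05,
                             consequence_weights = DEFAULT_CONSEQUENCE_WEIGHTS,
                             predictor_panel = DEFAULT_PREDICTOR_PANEL,
                             mean_depth = 80,
                             genotype_missing_rate = 0, qc_noise_rate = 0,
                             n_sample_swaps = 0L, seed = 1L) {
  if (is.null(planted_risk))
    planted_risk <- data.frame(gene = character(), consequence = character(),
                               n_carrier_families = integer(),
                               penetrance = numeric())
  new("SimulationConfig",
      n_families = as.integer(n_families),
      n_individuals = as.integer(n_individuals),
      n_background_variants = as.integer(n_background_variants),
      maf_strata = maf_strata, stratum_weights = stratum_weights,
      planted_risk = planted_risk, sporadic_rate = sporadic_rate,
      consequence_weights = consequence_weights,
      predictor_panel = predictor_panel, mean_depth = mean_depth,
      genotype_missing_rate = genotype_missing_rate,
      qc_noise_rate = qc_noise_rate,
      n_sample_swaps = as.integer(n_sample_swaps), seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@n_families, "families /",
      object@n_individuals, "individuals,",
      object@n_background_variants, "background variants,",
      nrow(object@planted_risk), "planted risk variant(s), seed",
      object@seed, "\n")
})

## run expr under a fixed RNG state, restoring the caller's state after
withSeed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

## deterministic family sizes (2..5 members) summing to n_individuals
familySizes <- function(n_families, n_individuals) {
  sizes <- rep(2L, n_families)
  extra <- n_individuals - 2L * n_families
  i <- 1L
  while (extra > 0L) {
    if (sizes[i] < 5L) { sizes[i] <- sizes[i] + 1L; extra <- extra - 1L }
    i <- if (i == n_families) 1L else i + 1L
    if (all(sizes == 5L)) break
  }
  if (extra > 0L)
    configurationError("n_individuals too large for family shapes (max 5/family)")
  sizes
}

## family shapes by size; parents always precede children
buildFamilies <- function(n_families, n_individuals) {
  sizes <- familySizes(n_families, n_individuals)
  rows <- list()
  for (f in seq_len(n_families)) {
    fid <- sprintf("F%02d", f)
    id <- function(k) sprintf("%sS%02d", fid, k)
    s <- sizes[f]
    child_sex <- function() if (stats::runif(1) < 0.9) "female" else "male"
    if (s == 2L) {
      fam <- data.frame(
        family_id = fid, sample_id = c(id(1), id(2)),
        father_id = NA_character_, mother_id = c(NA, id(1)),
        sex = c("female", child_sex()))
    } else {
      n_children <- min(s - 2L, 2L)
      kid_ids <- vapply(2L + seq_len(n_children), id, "")
      fam <- data.frame(
        family_id = fid,
        sample_id = c(id(1), id(2), kid_ids),
        father_id = c(NA, NA, rep(id(1), n_children)),
        mother_id = c(NA, NA, rep(id(2), n_children)),
        sex = c("male", "female",
                vapply(kid_ids, function(.) child_sex(), "")))
      if (s == 5L) {   # grandchild of the first child
        fam$sex[3] <- "female"
        fam <- rbind(fam, data.frame(
          family_id = fid, sample_id = id(5), father_id = NA_character_,
          mother_id = id(3), sex = child_sex()))
      }
    }
    rows[[f]] <- fam
  }
  do.call(rbind, rows)
}

BASES <- c("A", "C", "G", "T")

refAltFor <- function(consequence) {
  ref <- sample(BASES, 1)
  if (consequence == "frameshift_variant") {
    list(ref = ref, alt = paste0(ref, sample(BASES, 1)))
  } else if (consequence == "inframe_insertion") {
    list(ref = ref, alt = paste0(ref, paste(sample(BASES, 3, TRUE), collapse = "")))
  } else if (consequence == "inframe_deletion") {
    list(ref = paste0(ref, paste(sample(BASES, 3, TRUE), collapse = "")), alt = ref)
  } else {
    list(ref = ref, alt = sample(setdiff(BASES, ref), 1))
  }
}

hgvsFor <- function(consequence, pos, ref, alt, rank) {
  c_str <- paste0("c.", pos %% 9000L + 1L, ref, ">", alt)
  p_str <- switch(consequence,
                  stop_gained = sprintf("p.Gly%d*", rank * 101L),
                  frameshift_variant = sprintf("p.Arg%dfs", rank * 31L),
                  missense_variant = sprintf("p.Val%dLeu", rank * 53L),
                  stop_lost = sprintf("p.*%dext", rank * 211L),
                  inframe_deletion = sprintf("p.Lys%ddel", rank * 13L),
                  inframe_insertion = sprintf("p.Lys%dins", rank * 13L),
                  NA_character_)
  list(c = c_str, p = p_str)
}

#' Simulate a multi-family discovery cohort
#'
#' Generates pedigrees, gene-dropped genotypes with QC metrics, ANN-style
#' consequence annotations, predictor verdicts, two population frequency
#' panels and a truth manifest, all deterministically from the configuration
#' seed.
#'
#' @param config A [SimulationConfig-class].
#' @return A list of class `famrare_simulation`: `cohort`
#'   ([VariantCohort-class]), `panelA`/`panelB` (frequency tables), `truth`
#'   (planted-variant manifest, swapped samples, founder frequencies) and
#'   `phased` (maternal/paternal allele matrices, for Mendelian-consistency
#'   checks).
#' @export
simulateCohort <- function(config) {
  methods::validObject(config)
  withSeed(config@seed, {
    ped_df <- buildFamilies(config@n_families, config@n_individuals)
    n_ind <- nrow(ped_df)
    ids <- ped_df$sample_id

    ## ---- background variant table ----
    nb <- config@n_background_variants
    chrom <- sample(1:22, nb, replace = TRUE)
    pos <- sample(1000000:50000000, nb)
    ord <- order(chrom, pos)
    chrom <- chrom[ord]; pos <- pos[ord]
    n_genes <- max(1L, as.integer(round(nb / 2)))
    gene_idx <- sample(n_genes, nb, replace = TRUE)
    gene <- sprintf("GENE%04d", gene_idx)
    tx <- sprintf("ENST%06d", gene_idx * 10L + 1L)
    exon_totals_gene <- sample(2:15, n_genes, replace = TRUE)
    exon_total <- exon_totals_gene[gene_idx]
    exon_rank <- vapply(exon_total, function(t) sample.int(t, 1), 1L)
    consequence <- sample(names(config@consequence_weights), nb, replace = TRUE,
                          prob = config@consequence_weights)
    ra <- lapply(consequence, refAltFor)
    refs <- vapply(ra, `[[`, "", "ref")
    alts <- vapply(ra, `[[`, "", "alt")
    stratum <- sample(config@maf_strata, nb, replace = TRUE,
                      prob = config@stratum_weights)
    founder_freq <- stratum
    maf_a <- ifelse(stratum == 0, NA_real_, stratum)
    maf_b <- maf_a
    has_rs <- stats::runif(nb) < 0.3
    rsid <- ifelse(has_rs, sprintf("rs%d", sample(1000000:99999999, nb)),
                   NA_character_)
    qual <- round(stats::runif(nb, 100, 3000), 1)

    variants <- data.frame(chrom = as.character(chrom), pos = pos, ref = refs,
                           alt = alts, id = rsid, qual = qual,
                           maf_panel_a = maf_a, maf_panel_b = maf_b,
                           stringsAsFactors = FALSE)
    ann <- data.frame(key = variantKey(chrom, pos, refs, alts), allele = alts,
                      gene = gene, transcript_id = tx,
                      consequence = consequence, exon_rank = exon_rank,
                      exon_total = exon_total, stringsAsFactors = FALSE)
    hg <- Map(hgvsFor, consequence, pos, refs, alts, exon_rank)
    ann$hgvs_c <- vapply(hg, `[[`, "", "c")
    ann$hgvs_p <- vapply(hg, function(h) h$p %||% NA_character_, "")
    ## a second transcript annotation for ~5% of variants
    sec <- which(stats::runif(nb) < 0.05)
    if (length(sec)) {
      ann2 <- ann[sec, , drop = FALSE]
      ann2$transcript_id <- paste0(ann2$transcript_id, "A")
      ann2$exon_total <- vapply(ann2$exon_total,
                                function(t) sample(2:15, 1), 1L)
      ann2$exon_rank <- vapply(ann2$exon_total,
                               function(t) sample.int(t, 1), 1L)
      ann <- rbind(ann, ann2)
    }

    ## predictor verdicts (variant-level)
    tools <- config@predictor_panel
    for (tool in tools) {
      variants[[paste0("pred_call_", tool)]] <-
        sample(c("damaging", "tolerated", "unknown"), nb, replace = TRUE,
               prob = c(0.2, 0.65, 0.15))
      variants[[paste0("pred_score_", tool)]] <- round(stats::runif(nb), 3)
    }

    ## ---- planted risk variants ----
    pr <- config@planted_risk
    fam_order <- names(sort(table(ped_df$family_id), decreasing = TRUE))
    planted <- NULL
    if (nrow(pr)) {
      fam_cursor <- 0L
      prows <- list()
      for (i in seq_len(nrow(pr))) {
        fams <- fam_order[fam_cursor + seq_len(pr$n_carrier_families[i])]
        fam_cursor <- fam_cursor + pr$n_carrier_families[i]
        cons <- pr$consequence[i]
        ra_i <- refAltFor(cons)
        p_pos <- 90000000L + i * 1000L
        p_chrom <- as.character((i - 1L) %% 22L + 1L)
        hit <- match(pr$gene[i], gene)
        p_tx <- if (!is.na(hit)) tx[hit] else sprintf("ENSTR%04d1", i)
        p_tot <- if (!is.na(hit)) exon_total[hit] else 11L
        p_rank <- max(1L, min(3L, p_tot - 1L))
        vrow <- data.frame(chrom = p_chrom, pos = p_pos, ref = ra_i$ref,
                           alt = ra_i$alt, id = NA_character_, qual = 999,
                           maf_panel_a = NA_real_, maf_panel_b = NA_real_,
                           stringsAsFactors = FALSE)
        lof <- cons %in% LOF_TERMS
        for (tool in tools) {
          vrow[[paste0("pred_call_", tool)]] <-
            if (!lof && match(tool, tools) <= 4) "damaging" else "unknown"
          vrow[[paste0("pred_score_", tool)]] <- round(stats::runif(1), 3)
        }
        key_i <- variantKey(p_chrom, p_pos, ra_i$ref, ra_i$alt)
        hgp <- hgvsFor(cons, p_pos, ra_i$ref, ra_i$alt, p_rank)
        ann_i <- data.frame(key = key_i, allele = ra_i$alt, gene = pr$gene[i],
                            transcript_id = p_tx, consequence = cons,
                            exon_rank = p_rank, exon_total = p_tot,
                            hgvs_c = hgp$c, hgvs_p = hgp$p %||% NA_character_,
                            stringsAsFactors = FALSE)
        variants <- rbind(variants, vrow)
        ann <- rbind(ann, ann_i)
        founder_freq <- c(founder_freq, 0)
        prows[[i]] <- data.frame(key = key_i, gene = pr$gene[i],
                                 transcript_id = p_tx, consequence = cons,
                                 families = paste(fams, collapse = ","),
                                 penetrance = pr$penetrance[i],
                                 stringsAsFactors = FALSE)
      }
      planted <- do.call(rbind, prows)
    }
    nv <- nrow(variants)
    keys <- variantKey(variants$chrom, variants$pos, variants$ref, variants$alt)

    ## ---- gene dropping ----
    Amat <- matrix(0L, nv, n_ind, dimnames = list(keys, ids))  # maternal allele
    Apat <- matrix(0L, nv, n_ind, dimnames = list(keys, ids))
    founder_col <- is.na(ped_df$father_id) & is.na(ped_df$mother_id)
    for (j in which(founder_col)) {
      Amat[, j] <- stats::rbinom(nv, 1L, founder_freq)
      Apat[, j] <- stats::rbinom(nv, 1L, founder_freq)
    }
    ## private background sites: exactly one founder carrier in the cohort
    private <- which(founder_freq == 0 &
                       seq_len(nv) <= config@n_background_variants)
    founders <- which(founder_col)
    for (s in private) {
      Amat[s, ] <- 0L; Apat[s, ] <- 0L
      Amat[s, sample(founders, 1)] <- 1L
    }
    ## planted founder carriers: the founder mother of each carrier family
    forced <- matrix(FALSE, nv, n_ind, dimnames = list(keys, ids))
    if (!is.null(planted)) {
      for (i in seq_len(nrow(planted))) {
        s <- match(planted$key[i], keys)
        for (fid in strsplit(planted$families[i], ",")[[1]]) {
          fam <- ped_df[ped_df$family_id == fid, ]
          mother <- if (nrow(fam) == 2L) fam$sample_id[1] else fam$sample_id[2]
          mcol <- match(mother, ids)
          Amat[s, mcol] <- 1L; Apat[s, mcol] <- 0L
          forced[s, mcol] <- TRUE
        }
      }
    }
    ## drop alleles down the pedigree (parents precede children)
    for (j in seq_len(n_ind)) {
      if (founder_col[j]) next
      mth <- ped_df$mother_id[j]; fth <- ped_df$father_id[j]
      if (!is.na(mth)) {
        mcol <- match(mth, ids)
        pick <- stats::runif(nv) < 0.5
        Amat[, j] <- ifelse(pick, Amat[, mcol], Apat[, mcol])
      } else Amat[, j] <- stats::rbinom(nv, 1L, founder_freq)
      if (!is.na(fth)) {
        fcol <- match(fth, ids)
        pick <- stats::runif(nv) < 0.5
        Apat[, j] <- ifelse(pick, Amat[, fcol], Apat[, fcol])
      } else Apat[, j] <- stats::rbinom(nv, 1L, founder_freq)
    }
    ## forced transmission: first child of the carrier mother inherits the
    ## planted allele (still one of the mother's alleles, hence Mendelian)
    if (!is.null(planted)) {
      for (i in seq_len(nrow(planted))) {
        s <- match(planted$key[i], keys)
        for (fid in strsplit(planted$families[i], ",")[[1]]) {
          fam <- ped_df[ped_df$family_id == fid, ]
          mother <- if (nrow(fam) == 2L) fam$sample_id[1] else fam$sample_id[2]
          kids <- fam$sample_id[!is.na(fam$mother_id) & fam$mother_id == mother]
          if (length(kids)) {
            kcol <- match(kids[1], ids)
            Amat[s, kcol] <- 1L
            forced[s, kcol] <- TRUE
          }
        }
      }
    }
    ## sample swaps: replace a child's genotypes with unrelated draws
    swapped <- character(0)
    if (config@n_sample_swaps > 0L) {
      planted_fams <- if (is.null(planted)) character(0) else
        unlist(strsplit(planted$families, ","))
      cand_fams <- setdiff(fam_order, planted_fams)
      sizes <- table(ped_df$family_id)
      cand_fams <- cand_fams[order(-sizes[cand_fams])]
      for (k in seq_len(min(config@n_sample_swaps, length(cand_fams)))) {
        fam <- ped_df[ped_df$family_id == cand_fams[k], ]
        kids <- fam$sample_id[!is.na(fam$mother_id) | !is.na(fam$father_id)]
        sw <- kids[length(kids)]
        scol <- match(sw, ids)
        Amat[, scol] <- stats::rbinom(nv, 1L, founder_freq)
        Apat[, scol] <- stats::rbinom(nv, 1L, founder_freq)
        swapped <- c(swapped, sw)
      }
    }
    AC <- Amat + Apat

    ## ---- affection ----
    affected <- stats::runif(n_ind) < config@sporadic_rate
    if (!is.null(planted)) {
      for (i in seq_len(nrow(planted))) {
        s <- match(planted$key[i], keys)
        carrier <- AC[s, ] >= 1L
        hit <- carrier & (stats::runif(n_ind) < planted$penetrance[i])
        affected <- affected | hit
      }
    }
    ## ascertainment: every family enters the study through an affected member
    for (fid in unique(ped_df$family_id)) {
      in_fam <- ped_df$family_id == fid
      if (!any(affected[in_fam])) {
        kids <- which(in_fam & (!is.na(ped_df$mother_id) |
                                  !is.na(ped_df$father_id)))
        ## ascertain through the last-listed child, which is independent of
        ## the planted-variant forced transmission (first child)
        affected[kids[length(kids)]] <- TRUE
      }
    }
    affection <- rep("unaffected", n_ind)
    cat_draw <- sample(c("breast_cancer", "ovarian_cancer", "other_cancer"),
                       n_ind, replace = TRUE, prob = c(0.8, 0.1, 0.1))
    cat_draw[cat_draw == "ovarian_cancer" & ped_df$sex == "male"] <- "breast_cancer"
    affection[affected] <- cat_draw[affected]
    age <- rep(NA_real_, n_ind)
    age[affected] <- sample(28:68, sum(affected), replace = TRUE)
    is_index <- logical(n_ind)
    for (fid in unique(ped_df$family_id)) {
      in_fam <- which(ped_df$family_id == fid & affected)
      is_index[in_fam[which.min(age[in_fam])]] <- TRUE
    }
    ped <- Pedigree(data.frame(
      family_id = ped_df$family_id, sample_id = ped_df$sample_id,
      father_id = ped_df$father_id, mother_id = ped_df$mother_id,
      sex = ped_df$sex, affection = affection, age_at_diagnosis = age,
      is_index = is_index, is_sequenced = TRUE, stringsAsFactors = FALSE))

    ## ---- QC metrics ----
    qc <- simulateCallMetrics(AC, config, forced)

    ## carriers listed in the truth manifest
    if (!is.null(planted)) {
      planted$carriers <- vapply(planted$key, function(k) {
        paste(ids[which(qc$AC[match(k, keys), ] >= 1L)], collapse = ",")
      }, "")
    }

    panelA <- data.frame(chrom = variants$chrom, pos = variants$pos,
                         ref = variants$ref, alt = variants$alt,
                         maf = variants$maf_panel_a)[!is.na(variants$maf_panel_a), ]
    panelB <- data.frame(chrom = variants$chrom, pos = variants$pos,
                         ref = variants$ref, alt = variants$alt,
                         maf = variants$maf_panel_b)[!is.na(variants$maf_panel_b), ]
    cohort <- newVariantCohort(variants, qc$AC, qc$DP, qc$AD, qc$GQ, ann, ped)
    structure(list(cohort = cohort, panelA = panelA, panelB = panelB,
                   truth = list(planted = planted, swapped = swapped,
                                founder_freq = stats::setNames(founder_freq, keys)),
                   phased = list(maternal = Amat, paternal = Apat),
                   config = config),
              class = "famrare_simulation")
  })
}

## read depth / allele depth / genotype quality for a dosage matrix;
## forced planted-carrier calls stay clean so the manifest remains the truth
simulateCallMetrics <- function(AC, config, forced = NULL) {
  nv <- nrow(AC); m <- ncol(AC)
  DP <- matrix(pmax(1L, stats::rpois(nv * m, config@mean_depth)), nv, m,
               dimnames = dimnames(AC))
  p_alt <- matrix(0.003, nv, m)
  p_alt[AC == 1L] <- 0.5
  p_alt[AC == 2L] <- 0.98
  AD <- matrix(stats::rbinom(nv * m, as.vector(DP), as.vector(p_alt)), nv, m,
               dimnames = dimnames(AC))
  GQ <- matrix(99L, nv, m, dimnames = dimnames(AC))
  lowgq <- stats::runif(nv * m) < 0.05
  GQ[lowgq] <- sample(30:98, sum(lowgq), replace = TRUE)
  protect <- if (is.null(forced)) matrix(FALSE, nv, m) else forced
  if (config@qc_noise_rate > 0) {
    noisy <- stats::runif(nv * m) < config@qc_noise_rate & !protect
    DP[noisy] <- pmax(1L, stats::rpois(sum(noisy), 5))
    AD[noisy] <- stats::rbinom(sum(noisy), DP[noisy],
                               ifelse(AC[noisy] >= 1L, 0.12, 0.003))
    GQ[noisy] <- sample(2:15, sum(noisy), replace = TRUE)
  }
  ACout <- AC
  if (config@genotype_missing_rate > 0) {
    miss <- stats::runif(nv * m) < config@genotype_missing_rate & !protect
    ACout[miss] <- NA_integer_
  }
  list(AC = ACout, DP = DP, AD = AD, GQ = GQ)
}

#' @export
print.famrare_simulation <- function(x, ...) {
  cat("famrare simulation (seed", x$config@seed, ")\n")
  show(x$cohort)
  pl <- x$truth$planted
  cat("  planted risk variants:", if (is.null(pl)) 0 else nrow(pl),
      " swapped samples:", length(x$truth$swapped), "\n")
  invisible(x)
}

#' Check Mendelian consistency of a simulation
#'
#' Verifies that every non-founder allele equals one of the corresponding
#' parent's two alleles at every site (swapped samples, which model sample
#' mix-ups, are skipped).
#'
#' @param sim Output of [simulateCohort()].
#' @return `TRUE` if consistent, otherwise `FALSE` with attribute
#'   `"failures"` listing offending samples.
#' @export
checkMendelian <- function(sim) {
  Amat <- sim$phased$maternal; Apat <- sim$phased$paternal
  m <- members(pedigree(sim$cohort))
  bad <- character(0)
  for (j in seq_len(nrow(m))) {
    if (m$sample_id[j] %in% sim$truth$swapped) next
    for (side in c("mother", "father")) {
      pid <- if (side == "mother") m$mother_id[j] else m$father_id[j]
      if (is.na(pid)) next
      child_allele <- if (side == "mother") Amat[, m$sample_id[j]] else
        Apat[, m$sample_id[j]]
      ok <- child_allele == Amat[, pid] | child_allele == Apat[, pid]
      if (!all(ok)) bad <- c(bad, m$sample_id[j])
    }
  }
  if (length(bad)) structure(FALSE, failures = unique(bad)) else TRUE
}

#' Write all simulation outputs to a directory
#'
#' Emits the VCF, extended PED, both frequency panels and the truth manifest
#' (JSON), byte-identically for identical config + seed.
#'
#' @param sim Output of [simulateCohort()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "cohort.vcf"),
             ped = file.path(dir, "cohort.ped"),
             panel_a = file.path(dir, "panel_a.tsv"),
             panel_b = file.path(dir, "panel_b.tsv"),
             truth = file.path(dir, "truth.json"))
  writeCohortVcf(sim$cohort, paths["vcf"])
  writePedigree(pedigree(sim$cohort), paths["ped"])
  writeFrequencyTable(sim$panelA, paths["panel_a"])
  writeFrequencyTable(sim$panelB, paths["panel_b"])
  truth <- sim$truth
  truth$founder_freq <- NULL
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(paths)
}
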