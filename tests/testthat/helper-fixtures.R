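# Shared fixtures: compact cohort builder, a hand-written multi-allelic VCF,
# and the brute-force Fisher enumeration oracle.

## minimal pedigree: one row per sample with sensible defaults
testPed <- function(sample_id, family_id = "F01", affection = "breast_cancer",
                    father_id = NA_character_, mother_id = NA_character_,
                    sex = "female", is_index = FALSE, is_sequenced = TRUE,
                    age = 45) {
  n <- length(sample_id)
  Pedigree(data.frame(
    family_id = rep_len(family_id, n), sample_id = sample_id,
    father_id = rep_len(father_id, n), mother_id = rep_len(mother_id, n),
    sex = rep_len(sex, n), affection = rep_len(affection, n),
    age_at_diagnosis = rep_len(age, n), is_index = rep_len(is_index, n),
    is_sequenced = rep_len(is_sequenced, n)))
}

## cohort from a dosage matrix with clean QC metrics unless overridden
testCohort <- function(ac, ped, ann, maf_a = NA_real_, maf_b = NA_real_,
                       dp = NULL, ad = NULL, gq = NULL,
                       damaging = 0L, chrom = NULL, pos = NULL) {
  nv <- nrow(ac)
  chrom <- chrom %||% rep("1", nv)
  pos <- pos %||% (1000L + seq_len(nv))
  variants <- data.frame(chrom = chrom, pos = pos,
                         ref = rep("A", nv), alt = rep("G", nv),
                         id = NA_character_, qual = 100,
                         maf_panel_a = rep_len(maf_a, nv),
                         maf_panel_b = rep_len(maf_b, nv))
  damaging <- rep_len(as.integer(damaging), nv)
  for (t in seq_len(7)) {
    variants[[paste0("pred_call_T", t)]] <-
      ifelse(damaging >= t, "damaging", "tolerated")
    variants[[paste0("pred_score_T", t)]] <- 0.5
  }
  key <- famrare::variantKey(variants$chrom, variants$pos, variants$ref,
                             variants$alt)
  if (!is.null(ann)) {
    ann$key <- key[ann$variant]
    ann$allele <- variants$alt[ann$variant]
    ann$variant <- NULL
    for (col in c("exon_rank", "exon_total"))
      if (is.null(ann[[col]])) ann[[col]] <- NA_integer_
    for (col in c("hgvs_c", "hgvs_p"))
      if (is.null(ann[[col]])) ann[[col]] <- NA_character_
  } else {
    ann <- data.frame(key = character(), allele = character(),
                      gene = character(), transcript_id = character(),
                      consequence = character(), exon_rank = integer(),
                      exon_total = integer(), hgvs_c = character(),
                      hgvs_p = character())
  }
  dims <- dim(ac)
  if (is.null(dp)) dp <- matrix(40L, dims[1], dims[2])
  if (is.null(ad)) {
    frac <- matrix(c(0, 0.5, 1)[ifelse(is.na(ac), 1L, ac) + 1L],
                   dims[1], dims[2])
    ad <- matrix(as.integer(round(dp * frac)), dims[1], dims[2])
  }
  if (is.null(gq)) gq <- matrix(99L, dims[1], dims[2])
  dimnames(dp) <- dimnames(ad) <- dimnames(gq) <- dimnames(ac)
  famrare:::newVariantCohort(variants, ac, dp, ad, gq, ann, ped)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## annotation row shorthand: variant = row index into the cohort
annRow <- function(variant, gene, transcript_id, consequence,
                   exon_rank = NA_integer_, exon_total = NA_integer_) {
  data.frame(variant = variant, gene = gene, transcript_id = transcript_id,
             consequence = consequence, exon_rank = exon_rank,
             exon_total = exon_total)
}

## write a small VCF with the package dialect from raw lines
writeTestVcf <- function(body, path, samples = c("S1", "S2", "S3")) {
  hdr <- c("##fileformat=VCFv4.2",
           "##contig=<ID=1>",
           "##contig=<ID=2>",
           "##INFO=<ID=ANN,Number=.,Type=String,Description=\"ann\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"a\">",
           "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"q\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, body), path)
  path
}

## brute-force two-sided Fisher oracle: enumerate every table with the
## observed margins from first principles (log-binomial coefficients)
fisherOracle <- function(a, b, c, d, relTol = 1e-7) {
  r1 <- a + b; r2 <- c + d; k <- a + c
  if (r1 == 0 || r2 == 0 || k == 0 || (b + d) == 0) return(1)
  xs <- max(0, k - r2):min(k, r1)
  p <- exp(lchoose(r1, xs) + lchoose(r2, k - xs) - lchoose(r1 + r2, k))
  min(1, sum(p[p <= p[match(a, xs)] * (1 + relTol)]))
}

## declared relationship of each kinship pair, from the pedigree table
classifyPairs <- function(kin, m) {
  vapply(seq_len(nrow(kin)), function(r) {
    i <- kin$sample_i[r]; j <- kin$sample_j[r]
    mi <- m[m$sample_id == i, ]; mj <- m[m$sample_id == j, ]
    po <- identical(mj$mother_id, i) || identical(mj$father_id, i) ||
      identical(mi$mother_id, j) || identical(mi$father_id, j)
    if (po) return("parent_offspring")
    if (mi$family_id == mj$family_id &&
        !is.na(mi$mother_id) && !is.na(mj$mother_id) &&
        mi$mother_id == mj$mother_id &&
        identical(mi$father_id, mj$father_id)) return("full_sibs")
    if (mi$family_id != mj$family_id) return("unrelated")
    "other"
  }, "")
}
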