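# VCF ingest and export.
#
# The annotation dialect is a SnpEff-style ANN INFO field with exactly seven
# pipe-separated subfields per transcript annotation:
#
#   allele | consequence | gene | transcript | exon_rank/exon_total | HGVS.c | HGVS.p
#
# plus per-tool in-silico predictor verdicts as paired variant-level INFO keys
# (<TOOL>_call = damaging/tolerated/unknown, <TOOL>_score = numeric). The VEP
# CSQ dialect is not supported.

ANN_FIELDS <- 7L

#' @importFrom VariantAnnotation readVcf ref alt qual geno info header
NULL

## allele-count of alt index k from GT strings; any "." in the call makes the
## whole call missing (excluded from carrier counting and kinship)
gtToAc <- function(gt, k) {
  u <- unique(gt)
  map <- vapply(strsplit(u, "[/|]"), function(al) {
    if (any(al == ".")) NA_integer_ else sum(al == as.character(k))
  }, integer(1))
  unname(map[match(gt, u)])
}

parseAnnStrings <- function(ann_strings, context) {
  if (length(ann_strings) == 0 || all(is.na(ann_strings))) return(NULL)
  parts <- strsplit(ann_strings[!is.na(ann_strings)], "|", fixed = TRUE)
  bad <- lengths(parts) != ANN_FIELDS
  if (any(bad))
    configurationError(paste0(
      "unknown annotation dialect at ", context, ": expected ", ANN_FIELDS,
      " pipe-separated ANN subfields, found ", lengths(parts)[bad][1]))
  m <- do.call(rbind, parts)
  rank_total <- strsplit(m[, 5], "/", fixed = TRUE)
  num_or_na <- function(x) suppressWarnings(as.integer(x))
  data.frame(
    allele = m[, 1],
    consequence = m[, 2],
    gene = m[, 3],
    transcript_id = m[, 4],
    exon_rank = num_or_na(vapply(rank_total, `[`, "", 1L)),
    exon_total = num_or_na(vapply(rank_total, function(x) x[2] %||% NA_character_, "")),
    hgvs_c = ifelse(m[, 6] == ".", NA_character_, m[, 6]),
    hgvs_p = ifelse(m[, 7] == ".", NA_character_, m[, 7]),
    stringsAsFactors = FALSE)
}

#' Read an annotated multi-sample VCF into a VariantCohort
#'
#' Parses a VCF v4.2 file carrying ANN-dialect consequence annotations (see
#' the vignette) and per-tool predictor verdict INFO keys. Multi-allelic
#' records are split into one record per alternate allele; consequence
#' annotations are matched to their allele; population frequencies, if
#' supplied, are left-joined by (chrom, pos, ref, alt) with panel-absent
#' variants kept as `NA` (the rare-variant filters treat absence as MAF 0 and
#' log it).
#'
#' @param path Path to the VCF file.
#' @param pedigree A [Pedigree-class] covering every VCF sample. Sequencing
#'   status is derived from VCF membership.
#' @param panelA,panelB Optional frequency tables from [readFrequencyTable()]
#'   (panel A stands in for a 1000-Genomes-like panel, panel B for a
#'   gnomAD-like panel).
#' @param genome Genome build label attached to the ranges.
#' @param verbose Log join diagnostics.
#' @return A [VariantCohort-class].
#' @export
readCohortVcf <- function(path, pedigree, panelA = NULL, panelB = NULL,
                          genome = "synthetic", verbose = TRUE) {
  vcf <- tryCatch(
    suppressWarnings(VariantAnnotation::readVcf(path, genome = genome)),
    error = function(e) formatError(paste0("malformed VCF '", path, "': ",
                                           conditionMessage(e))))
  hdr_info <- rownames(VariantAnnotation::info(VariantAnnotation::header(vcf)))
  if (!"ANN" %in% hdr_info)
    configurationError("annotation dialect not recognized: no ANN INFO field declared")
  n <- length(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  refs <- as.character(VariantAnnotation::ref(vcf))
  alt_list <- lapply(as.list(VariantAnnotation::alt(vcf)), as.character)
  quals <- VariantAnnotation::qual(vcf)
  ids <- names(rr)
  ids <- ifelse(is.na(ids) | grepl(":", ids), NA_character_, ids)

  gt <- VariantAnnotation::geno(vcf)$GT
  dpm <- VariantAnnotation::geno(vcf)$DP
  gqm <- VariantAnnotation::geno(vcf)$GQ
  adO <- VariantAnnotation::geno(vcf)$AD
  samples <- colnames(gt)
  m <- length(samples)
  adAt <- function(i, k) {           # alt-supporting depth for alt index k
    if (is.null(adO)) return(rep(NA_integer_, m))
    if (is.array(adO) && length(dim(adO)) == 3) return(as.integer(adO[i, , k + 1L]))
    vapply(adO[i, ], function(v) {
      if (length(v) >= k + 1L) as.integer(v[k + 1L]) else NA_integer_
    }, integer(1))
  }
  annL <- VariantAnnotation::info(vcf)$ANN
  call_keys <- grep("_call$", hdr_info, value = TRUE)
  tools <- sub("_call$", "", call_keys)
  getInfo1 <- function(key) {
    v <- VariantAnnotation::info(vcf)[[key]]
    if (is.null(v)) rep(NA, n) else v
  }

  var_rows <- vector("list", n)
  ann_rows <- vector("list", n)
  acL <- list(); dpL <- list(); adL <- list(); gqL <- list()
  r <- 0L
  for (i in seq_len(n)) {
    alts <- alt_list[[i]]
    ann_i <- parseAnnStrings(as.character(annL[[i]]),
                             context = paste0(chrom[i], ":", pos[i]))
    for (k in seq_along(alts)) {
      r <- r + 1L
      vr <- data.frame(chrom = chrom[i], pos = pos[i], ref = refs[i],
                       alt = alts[k], id = ids[i], qual = quals[i],
                       stringsAsFactors = FALSE)
      for (tool in tools) {
        vr[[paste0("pred_call_", tool)]] <- as.character(getInfo1(paste0(tool, "_call"))[i])
        sc <- getInfo1(paste0(tool, "_score"))[i]
        vr[[paste0("pred_score_", tool)]] <- as.numeric(sc)
      }
      var_rows[[r]] <- vr
      acL[[r]] <- gtToAc(gt[i, ], k)
      dpL[[r]] <- as.integer(dpm[i, ])
      adL[[r]] <- adAt(i, k)
      gqL[[r]] <- as.integer(gqm[i, ])
      if (!is.null(ann_i)) {
        sel <- ann_i[ann_i$allele == alts[k], , drop = FALSE]
        if (nrow(sel)) {
          sel$key <- variantKey(chrom[i], pos[i], refs[i], alts[k])
          ann_rows[[r]] <- sel
        }
      }
    }
  }
  variants <- do.call(rbind, var_rows[seq_len(r)])
  toMat <- function(L) matrix(unlist(L), nrow = r, ncol = m, byrow = TRUE,
                              dimnames = list(NULL, samples))
  ann <- do.call(rbind, Filter(Negate(is.null), ann_rows))
  if (is.null(ann))
    ann <- data.frame(key = character(), allele = character(), gene = character(),
                      transcript_id = character(), consequence = character(),
                      exon_rank = integer(), exon_total = integer(),
                      hgvs_c = character(), hgvs_p = character())
  ann <- ann[, c("key", "allele", "gene", "transcript_id", "consequence",
                 "exon_rank", "exon_total", "hgvs_c", "hgvs_p")]
  rownames(ann) <- NULL

  ped <- markSequenced(pedigree, samples)
  cohort <- newVariantCohort(variants, toMat(acL), toMat(dpL), toMat(adL),
                             toMat(gqL), ann, ped)
  attachFrequencies(cohort, panelA, panelB, verbose = verbose)
}

## resolve is_sequenced from VCF sample membership
markSequenced <- function(ped, samples) {
  m <- members(ped)
  m$is_sequenced <- m$sample_id %in% samples
  Pedigree(m)
}

#' Attach population panel frequencies to a cohort
#'
#' Left join by (chrom, pos, ref, alt): every variant record is retained and
#' panel-absent variants are marked `NA` (not silently zero-filled; the
#' zero-as-absent rule is applied, and logged, inside the rare-variant
#' filters).
#'
#' @param cohort A [VariantCohort-class].
#' @param panelA,panelB Frequency tables from [readFrequencyTable()], or
#'   `NULL` to leave a panel unattached.
#' @param verbose Log how many variants were found in each panel.
#' @return The cohort with updated `maf_panel_a` / `maf_panel_b` rowData.
#' @export
attachFrequencies <- function(cohort, panelA = NULL, panelB = NULL,
                              verbose = TRUE) {
  join <- function(panel, label) {
    pk <- variantKey(panel$chrom, panel$pos, panel$ref, panel$alt)
    hit <- match(rownames(cohort), pk)
    if (verbose)
      message("frequency join (", label, "): ", sum(!is.na(hit)), "/",
              nrow(cohort), " variants present in panel")
    panel$maf[hit]
  }
  if (!is.null(panelA))
    SummarizedExperiment::rowData(cohort)$maf_panel_a <- join(panelA, "panel A")
  if (!is.null(panelB))
    SummarizedExperiment::rowData(cohort)$maf_panel_b <- join(panelB, "panel B")
  methods::validObject(cohort)
  cohort
}

fmtNum <- function(x) {
  ifelse(is.na(x), ".",
         vapply(x, function(v) format(v, scientific = FALSE, trim = TRUE,
                                      digits = 15), ""))
}

#' Write a VariantCohort to VCF
#'
#' Emits the package's documented VCF v4.2 dialect (one record per alternate
#' allele, ANN-style annotations, paired predictor INFO keys,
#' `GT:DP:AD:GQ` genotypes). [readCohortVcf()] on the result reconstructs the
#' cohort field for field.
#'
#' @param cohort A [VariantCohort-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeCohortVcf <- function(cohort, path) {
  rd <- SummarizedExperiment::rowData(cohort)
  gr <- SummarizedExperiment::rowRanges(cohort)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  pos <- GenomicRanges::start(gr)
  samples <- colnames(cohort)
  tools <- sub("^pred_call_", "", grep("^pred_call_", colnames(rd), value = TRUE))

  hdr <- c("##fileformat=VCFv4.2",
           "##source=famrare",
           paste0("##contig=<ID=", unique(chrom), ">"),
           paste0("##INFO=<ID=ANN,Number=.,Type=String,Description=\"",
                  "Functional annotations: ",
                  "'Allele|Consequence|Gene|Transcript|Exon_Rank/Exon_Total|",
                  "HGVS.c|HGVS.p'\">"))
  for (tool in tools) {
    hdr <- c(hdr,
             paste0("##INFO=<ID=", tool, "_call,Number=1,Type=String,",
                    "Description=\"", tool, " verdict\">"),
             paste0("##INFO=<ID=", tool, "_score,Number=1,Type=Float,",
                    "Description=\"", tool, " score\">"))
  }
  hdr <- c(hdr,
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
           "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))

  ann <- as.data.frame(annotations(cohort))
  ann_by_key <- split(ann, ann$key)
  ac <- SummarizedExperiment::assay(cohort, "AC")
  dp <- SummarizedExperiment::assay(cohort, "DP")
  ad <- SummarizedExperiment::assay(cohort, "AD")
  gq <- SummarizedExperiment::assay(cohort, "GQ")
  gt_map <- c("0/0", "0/1", "1/1")

  lines <- character(nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    key <- rownames(cohort)[i]
    a <- ann_by_key[[key]]
    info_parts <- character(0)
    if (!is.null(a) && nrow(a)) {
      entries <- vapply(seq_len(nrow(a)), function(ri) {
        rt <- if (is.na(a$exon_rank[ri])) "." else
          paste0(a$exon_rank[ri], "/", a$exon_total[ri])
        paste(a$allele[ri], a$consequence[ri], a$gene[ri], a$transcript_id[ri],
              rt, ifelse(is.na(a$hgvs_c[ri]), ".", a$hgvs_c[ri]),
              ifelse(is.na(a$hgvs_p[ri]), ".", a$hgvs_p[ri]), sep = "|")
      }, "")
      info_parts <- paste0("ANN=", paste(entries, collapse = ","))
    }
    for (tool in tools) {
      cl <- rd[[paste0("pred_call_", tool)]][i]
      sc <- rd[[paste0("pred_score_", tool)]][i]
      if (!is.na(cl))
        info_parts <- c(info_parts, paste0(tool, "_call=", cl))
      if (!is.na(sc))
        info_parts <- c(info_parts, paste0(tool, "_score=", as.character(sc)))
    }
    info <- if (length(info_parts)) paste(info_parts, collapse = ";") else "."
    geno_str <- vapply(seq_along(samples), function(j) {
      acv <- ac[i, j]
      gtv <- if (is.na(acv)) "./." else gt_map[acv + 1L]
      dpv <- dp[i, j]; adv <- ad[i, j]; gqv <- gq[i, j]
      adf <- if (is.na(dpv) || is.na(adv)) "." else paste0(dpv - adv, ",", adv)
      paste(gtv, ifelse(is.na(dpv), ".", dpv), adf,
            ifelse(is.na(gqv), ".", gqv), sep = ":")
    }, "")
    lines[i] <- paste(c(chrom[i], pos[i],
                        ifelse(is.na(rd$ID[i]), ".", rd$ID[i]),
                        rd$REF[i], rd$ALT[i], fmtNum(rd$QUAL[i]), "PASS",
                        info, "GT:DP:AD:GQ", geno_str), collapse = "\t")
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}
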