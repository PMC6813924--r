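# KING-robust pairwise kinship estimation and pedigree-discordance flagging.
#
# The within-pair estimator uses shared-heterozygote and opposite-homozygote
# counts only:
#
#   phi = (N_het,het - 2 * N_AA,aa) / (N_het(i) + N_het(j))
#
# over sites where both samples have non-missing genotypes. It is robust to
# population structure, yields exactly 0.5 for duplicate samples, ~0.25 for
# first-degree relatives and ~0 for unrelated pairs.

## standard KING powers-of-two relationship cutoffs
KINSHIP_CUTOFFS <- c(duplicate = 0.354, first_degree = 0.177,
                     second_degree = 0.0884, third_degree = 0.0442)

#' Estimate kinship for one sample pair
#'
#' @param gi,gj Integer vectors of alt-allele dosages (0/1/2, `NA` missing)
#'   over the same sites. Missing genotypes are dropped pairwise.
#' @return One-row data.frame with `phi`, `n_both_het`, `n_opposite_hom`,
#'   `n_het_i`, `n_het_j`, `n_sites_used`.
#' @examples
#' g <- c(0L, 1L, 1L, 2L, 0L)
#' estimateKinship(g, g)$phi   # duplicate pair: exactly 0.5
#' @export
estimateKinship <- function(gi, gj) {
  if (length(gi) != length(gj))
    validationError("genotype vectors must cover the same sites")
  use <- !is.na(gi) & !is.na(gj)
  gi <- gi[use]; gj <- gj[use]
  n_het_i <- sum(gi == 1L)
  n_het_j <- sum(gj == 1L)
  denom <- n_het_i + n_het_j
  if (denom == 0L)
    famrareStop("kinship undefined: no heterozygous site in either sample",
                "famrare_undefined_kinship")
  n_both_het <- sum(gi == 1L & gj == 1L)
  n_opp <- sum((gi == 0L & gj == 2L) | (gi == 2L & gj == 0L))
  data.frame(phi = (n_both_het - 2 * n_opp) / denom,
             n_both_het = n_both_het, n_opposite_hom = n_opp,
             n_het_i = n_het_i, n_het_j = n_het_j,
             n_sites_used = length(gi))
}

#' Pairwise kinship for all samples of a cohort
#'
#' Sites monomorphic in the cohort (no non-missing alt allele, or no
#' non-missing ref allele) are excluded as uninformative before estimation.
#' Pairs whose estimator denominator is zero get `phi = NA` with a warning.
#'
#' @param x A [VariantCohort-class] or an integer genotype matrix
#'   (sites x samples, dosage coding).
#' @return data.frame of unordered sample pairs with the estimator's
#'   components, plus attribute `"phi"`: the symmetric kinship matrix
#'   (diagonal 0.5).
#' @export
kinshipMatrix <- function(x) {
  G <- if (methods::is(x, "VariantCohort")) genotypes(x) else x
  samples <- colnames(G)
  ## drop cohort-monomorphic sites
  ac_sum <- rowSums(G, na.rm = TRUE)
  an <- 2 * rowSums(!is.na(G))
  poly <- ac_sum > 0 & ac_sum < an
  G <- G[poly, , drop = FALSE]
  M <- !is.na(G)
  H <- (G == 1L) & M
  A0 <- (G == 0L) & M
  A2 <- (G == 2L) & M
  storage.mode(H) <- storage.mode(A0) <- storage.mode(A2) <-
    storage.mode(M) <- "double"
  n_bh <- crossprod(H)
  n_opp <- crossprod(A0, A2) + crossprod(A2, A0)
  n_het_shared <- crossprod(H, M)   # hets of row sample over sites shared w/ col
  n_sites <- crossprod(M)
  m <- length(samples)
  pairs <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
  i <- pairs[, 1]; j <- pairs[, 2]
  denom <- n_het_shared[cbind(i, j)] + n_het_shared[cbind(j, i)]
  phi <- ifelse(denom > 0,
                (n_bh[cbind(i, j)] - 2 * n_opp[cbind(i, j)]) / denom, NA)
  if (anyNA(phi))
    warning(sum(is.na(phi)), " pair(s) with undefined kinship ",
            "(no heterozygous sites); phi set NA")
  out <- data.frame(
    sample_i = samples[i], sample_j = samples[j], phi = phi,
    n_both_het = n_bh[cbind(i, j)], n_opposite_hom = n_opp[cbind(i, j)],
    n_het_i = n_het_shared[cbind(i, j)], n_het_j = n_het_shared[cbind(j, i)],
    n_sites_used = n_sites[cbind(i, j)])
  phi_mat <- matrix(NA_real_, m, m, dimnames = list(samples, samples))
  phi_mat[cbind(i, j)] <- phi
  phi_mat[cbind(j, i)] <- phi
  diag(phi_mat) <- 0.5
  attr(out, "phi") <- phi_mat
  out
}

#' Classify a kinship coefficient into a relationship band
#'
#' Uses the standard KING powers-of-two cutoffs (0.354, 0.177, 0.0884,
#' 0.0442).
#'
#' @param phi Numeric vector of kinship coefficients.
#' @return Character vector: `duplicate`, `first_degree`, `second_degree`,
#'   `third_degree` or `unrelated`.
#' @export
relationshipBand <- function(phi) {
  cut(phi,
      breaks = c(-Inf, KINSHIP_CUTOFFS[c("third_degree", "second_degree",
                                         "first_degree", "duplicate")], Inf),
      labels = c("unrelated", "third_degree", "second_degree",
                 "first_degree", "duplicate"),
      right = FALSE) |> as.character()
}

## declared first-degree sequenced pairs: parent-offspring links and full sibs
declaredFirstDegreePairs <- function(ped, samples) {
  m <- members(ped)
  m <- m[m$sample_id %in% samples, , drop = FALSE]
  po <- rbind(
    data.frame(a = m$sample_id, b = m$father_id, relationship = "parent_offspring"),
    data.frame(a = m$sample_id, b = m$mother_id, relationship = "parent_offspring"))
  po <- po[!is.na(po$b) & po$b %in% samples, , drop = FALSE]
  sib <- NULL
  key <- paste(m$family_id, m$father_id, m$mother_id)
  has_par <- !is.na(m$father_id) | !is.na(m$mother_id)
  for (k in unique(key[has_par])) {
    ids <- m$sample_id[key == k & has_par]
    if (length(ids) >= 2) {
      cmb <- utils::combn(sort(ids), 2)
      sib <- rbind(sib, data.frame(a = cmb[1, ], b = cmb[2, ],
                                   relationship = "full_sibs"))
    }
  }
  out <- rbind(po, sib)
  if (is.null(out) || !nrow(out)) return(out)
  ## canonical order, dedupe
  swap <- out$a > out$b
  tmp <- out$a[swap]; out$a[swap] <- out$b[swap]; out$b[swap] <- tmp
  out[!duplicated(out[, c("a", "b")]), , drop = FALSE]
}

#' Flag pedigree-discordant sample pairs and recommend exclusions
#'
#' A declared first-degree pair (parent-offspring or full sibs, both
#' sequenced) whose estimated kinship falls below the unrelated threshold is
#' flagged as discordant. A sample discordant with *all* of its declared
#' first-degree relatives is recommended for exclusion from downstream
#' analyses — the handling applied in the study to a patient genetically
#' unrelated to her reported mother and sister.
#'
#' @param kin Output of [kinshipMatrix()] (or a symmetric phi matrix).
#' @param ped A [Pedigree-class].
#' @param unrelatedThreshold Kinship below which a declared first-degree pair
#'   is discordant; default 0.0442, the standard KING third-degree cutoff.
#' @return list with `discordant` (data.frame of flagged pairs with declared
#'   relationship, phi and band) and `exclude` (character vector of sample
#'   ids recommended for exclusion).
#' @export
flagPedigreeDiscordance <- function(kin, ped, unrelatedThreshold = 0.0442) {
  phi_mat <- if (is.matrix(kin)) kin else attr(kin, "phi")
  samples <- colnames(phi_mat)
  pairs <- declaredFirstDegreePairs(ped, samples)
  if (is.null(pairs) || !nrow(pairs))
    return(list(discordant = data.frame(sample_i = character(),
                                        sample_j = character(),
                                        relationship = character(),
                                        phi = numeric(), band = character()),
                exclude = character()))
  pairs$phi <- phi_mat[cbind(pairs$a, pairs$b)]
  pairs$band <- relationshipBand(pairs$phi)
  pairs$discordant <- !is.na(pairs$phi) & pairs$phi < unrelatedThreshold
  disc <- pairs[pairs$discordant,
                c("a", "b", "relationship", "phi", "band"), drop = FALSE]
  colnames(disc)[1:2] <- c("sample_i", "sample_j")
  rownames(disc) <- NULL
  ## a sample is excluded when every declared first-degree relationship it
  ## appears in is discordant
  ids <- unique(c(pairs$a, pairs$b))
  exclude <- ids[vapply(ids, function(s) {
    rel <- pairs$a == s | pairs$b == s
    any(rel) && all(pairs$discordant[rel])
  }, logical(1))]
  list(discordant = disc, exclude = sort(exclude))
}
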