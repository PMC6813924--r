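# Case-control allele-count statistics: two-sided Fisher's exact test on
# 2x2 alt/ref allele tables, odds ratios with Woolf or exact-conditional
# confidence intervals, and per-gene cumulative loss-of-function burden
# collapsing. Tables are built from published-style allele counts as
# a = case alt, b = case total - alt, c = control alt, d = control total -
# alt (totals are alt-inclusive: the printed odds ratios reproduce only
# under ref = total - alt).

checkTable <- function(a, b, c, d) {
  v <- c(a, b, c, d)
  if (any(v < 0) || any(v != round(v)))
    validationError("2x2 table cells must be non-negative integers")
}

#' Two-sided Fisher's exact test
#'
#' Conditions on both margins: the two-sided p-value is the sum of
#' hypergeometric probabilities of all tables with the observed margins whose
#' point probability does not exceed that of the observed table (ties
#' compared within relative tolerance `relTol`). Any zero margin yields
#' p = 1 with a warning.
#'
#' @param a,b,c,d Cell counts (vectors are recycled to equal length):
#'   case alt, case ref, control alt, control ref.
#' @param relTol Relative tolerance for the point-probability tie comparison
#'   (default 1e-7).
#' @return Numeric vector of two-sided p-values.
#' @examples
#' fisherTwoSided(169, 12219, 593, 53735)   # ~0.0114
#' @export
fisherTwoSided <- function(a, b, c, d, relTol = 1e-7) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(a, n); b <- rep_len(b, n)
  c <- rep_len(c, n); d <- rep_len(d, n)
  checkTable(a, b, c, d)
  vapply(seq_len(n), function(i) {
    r1 <- a[i] + b[i]; r2 <- c[i] + d[i]
    k <- a[i] + c[i]; k2 <- b[i] + d[i]
    if (r1 == 0 || r2 == 0 || k == 0 || k2 == 0) {
      warning("zero margin: p defined as 1")
      return(1)
    }
    support <- max(0, k - r2):min(k, r1)
    probs <- stats::dhyper(support, r1, r2, k)
    p_obs <- probs[match(a[i], support)]
    min(1, sum(probs[probs <= p_obs * (1 + relTol)]))
  }, numeric(1))
}

#' Odds ratio with confidence interval
#'
#' Point estimate is the sample cross-product ratio `ad/(bc)`. The CI is
#' either the Woolf (log-normal) interval or the exact-conditional interval
#' obtained by inverting the noncentral hypergeometric likelihood. Tables
#' with a zero cell give a degenerate OR (0 or Inf) with the CI omitted and
#' flagged; no continuity correction is applied.
#'
#' @param a,b,c,d Cell counts (recycled).
#' @param method `"exact_conditional"` (default) or `"woolf"`.
#' @param conf Confidence level (default 0.95).
#' @return data.frame with `odds_ratio`, `ci_low`, `ci_high`, `degenerate`,
#'   `method`.
#' @examples
#' oddsRatioCI(169, 12219, 593, 53735)   # OR 1.25 (1.05-1.49)
#' @export
oddsRatioCI <- function(a, b, c, d, method = c("exact_conditional", "woolf"),
                        conf = 0.95) {
  method <- match.arg(method)
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(a, n); b <- rep_len(b, n)
  c <- rep_len(c, n); d <- rep_len(d, n)
  checkTable(a, b, c, d)
  res <- lapply(seq_len(n), function(i) {
    or <- (a[i] * d[i]) / (b[i] * c[i])
    degenerate <- a[i] == 0 || b[i] == 0 || c[i] == 0 || d[i] == 0
    if (degenerate) {
      or <- if (a[i] == 0 || d[i] == 0) {
        if (b[i] == 0 || c[i] == 0) NaN else 0
      } else Inf
      return(data.frame(odds_ratio = or, ci_low = NA_real_,
                        ci_high = NA_real_, degenerate = TRUE,
                        method = method))
    }
    ci <- if (method == "woolf") {
      se <- sqrt(1 / a[i] + 1 / b[i] + 1 / c[i] + 1 / d[i])
      z <- stats::qnorm(1 - (1 - conf) / 2)
      exp(log(or) + c(-1, 1) * z * se)
    } else {
      stats::fisher.test(matrix(c(a[i], b[i], c[i], d[i]), 2, byrow = TRUE),
                         conf.level = conf)$conf.int
    }
    data.frame(odds_ratio = or, ci_low = ci[1], ci_high = ci[2],
               degenerate = FALSE, method = method)
  })
  do.call(rbind, res)
}

#' Full association result for a 2x2 allele table
#'
#' @param a,b,c,d Cell counts (recycled).
#' @param method CI method, see [oddsRatioCI()].
#' @param p_adjust Multiple-testing correction applied across the supplied
#'   tables (`"none"`, default, or any [stats::p.adjust()] method).
#' @return data.frame with cells, `p_two_sided` (adjusted if requested),
#'   `odds_ratio`, `ci_low`, `ci_high`, `degenerate`, `method`.
#' @export
associationTest <- function(a, b, c, d,
                            method = c("exact_conditional", "woolf"),
                            p_adjust = "none") {
  p <- fisherTwoSided(a, b, c, d)
  if (p_adjust != "none") p <- stats::p.adjust(p, method = p_adjust)
  or <- oddsRatioCI(a, b, c, d, method = method)
  n <- nrow(or)
  data.frame(a = rep_len(a, n), b = rep_len(b, n), c = rep_len(c, n),
             d = rep_len(d, n), p_two_sided = p, or)
}

#' Per-gene cumulative LoF burden collapse
#'
#' Aggregates qualifying variants of one gene — loss-of-function, not in the
#' transcript's last exon, MAF at most `mafMax` in both panels — into a
#' single 2x2 cumulative-frequency table: summed alt alleles vs summed
#' remaining alleles in cases and controls, then tests it with
#' [fisherTwoSided()] and [oddsRatioCI()].
#'
#' @param gene Gene symbol (label only).
#' @param variants data.frame with one row per variant: `lof` (logical),
#'   `last_exon` (logical, `NA` = unknown, counted as not-last), `maf_a`,
#'   `maf_b` (`NA` = panel-absent, treated as 0), `case_alt`, `case_total`,
#'   `control_alt`, `control_total`.
#' @param mafMax Qualification MAF threshold (default 0.001).
#' @param method CI method.
#' @return One-row data.frame with `gene`, `n_qualifying`, `empty` and —
#'   when at least one variant qualifies — the collapsed table and test
#'   results. An empty burden is explicit (`empty = TRUE`, p `NA`), never a
#'   silent p = 1.
#' @export
burdenCollapse <- function(gene, variants, mafMax = 0.001,
                           method = c("exact_conditional", "woolf")) {
  method <- match.arg(method)
  maf_a <- ifelse(is.na(variants$maf_a), 0, variants$maf_a)
  maf_b <- ifelse(is.na(variants$maf_b), 0, variants$maf_b)
  qual <- variants$lof & !(variants$last_exon %in% TRUE) &
    maf_a <= mafMax & maf_b <= mafMax
  if (!any(qual)) {
    return(data.frame(gene = gene, n_qualifying = 0L, empty = TRUE,
                      a = NA_integer_, b = NA_integer_, c = NA_integer_,
                      d = NA_integer_, p_two_sided = NA_real_,
                      odds_ratio = NA_real_, ci_low = NA_real_,
                      ci_high = NA_real_, degenerate = NA, method = method))
  }
  q <- variants[qual, , drop = FALSE]
  a <- sum(q$case_alt);    b <- sum(q$case_total - q$case_alt)
  c <- sum(q$control_alt); d <- sum(q$control_total - q$control_alt)
  res <- associationTest(a, b, c, d, method = method)
  data.frame(gene = gene, n_qualifying = sum(qual), empty = FALSE, res)
}
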