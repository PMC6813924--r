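# Fisher exact test, odds ratios, burden collapsing.

test_that("published allele-count tables reproduce printed p-values and odds ratios", {
  ## SETBP1 NFE-TCGA vs NFE-ExAC-nonTCGA
  expect_equal(round(fisherTwoSided(169, 12219, 593, 53735), 4), 0.0114)
  res <- oddsRatioCI(169, 12219, 593, 53735)
  expect_equal(round(res$odds_ratio, 2), 1.25)
  expect_equal(round(c(res$ci_low, res$ci_high), 2), c(1.05, 1.49))
  ## C7orf34 NFE-TCGA vs NFE-ExAC-nonTCGA
  res2 <- oddsRatioCI(44, 12348, 132, 54212)
  expect_equal(round(res2$odds_ratio, 2), 1.46)
  expect_equal(round(c(res2$ci_low, res2$ci_high), 2), c(1.02, 2.07))
  expect_equal(round(fisherTwoSided(44, 12348, 132, 54212), 4), 0.0325)
})

test_that("symmetric tables give p = 1 and zero margins warn with p = 1", {
  expect_equal(fisherTwoSided(5, 95, 5, 95), 1)
  expect_warning(p <- fisherTwoSided(0, 0, 3, 7), "zero margin")
  expect_equal(p, 1)
})

test_that("two-sided p matches the enumeration oracle exactly for all tables N <= 30", {
  A <- B <- C <- D <- integer(0)
  for (n in 1:30) for (a in 0:n) for (b in 0:(n - a)) {
    cc <- 0:(n - a - b)
    A <- c(A, rep(a, length(cc))); B <- c(B, rep(b, length(cc)))
    C <- c(C, cc); D <- c(D, n - a - b - cc)
  }
  p_impl <- suppressWarnings(fisherTwoSided(A, B, C, D))
  p_oracle <- vapply(seq_along(A), function(i)
    fisherOracle(A[i], B[i], C[i], D[i]), numeric(1))
  expect_lt(max(abs(p_impl - p_oracle)), 1e-12)
})

test_that("p agrees with the reference implementation on random tables", {
  set.seed(99)
  for (i in 1:200) {
    t <- rpois(4, sample(c(2, 20, 200), 1)) + c(1, 0, 0, 1)
    p_ref <- stats::fisher.test(matrix(t, 2, byrow = TRUE))$p.value
    expect_equal(fisherTwoSided(t[1], t[2], t[3], t[4]), p_ref,
                 tolerance = 1e-10)
  }
})

test_that("fisher p is invariant under row and column swaps; OR inverts under group swap", {
  set.seed(7)
  for (i in 1:50) {
    t <- rpois(4, 15) + 1
    p <- fisherTwoSided(t[1], t[2], t[3], t[4])
    expect_equal(fisherTwoSided(t[3], t[4], t[1], t[2]), p)  # row swap
    expect_equal(fisherTwoSided(t[2], t[1], t[4], t[3]), p)  # column swap
    or <- oddsRatioCI(t[1], t[2], t[3], t[4])$odds_ratio
    or_swap <- oddsRatioCI(t[3], t[4], t[1], t[2])$odds_ratio
    expect_equal(or_swap, 1 / or)
  }
})

test_that("Woolf CI contains the point OR and narrows with scale", {
  set.seed(3)
  for (i in 1:30) {
    t <- rpois(4, 10) + 1
    res <- oddsRatioCI(t[1], t[2], t[3], t[4], method = "woolf")
    expect_true(res$ci_low <= res$odds_ratio && res$odds_ratio <= res$ci_high)
    res10 <- oddsRatioCI(10 * t[1], 10 * t[2], 10 * t[3], 10 * t[4],
                         method = "woolf")
    expect_lt(res10$ci_high / res10$ci_low, res$ci_high / res$ci_low)
  }
})

test_that("zero cells give degenerate ORs with the CI omitted and flagged", {
  res <- oddsRatioCI(0, 100, 5, 95)
  expect_equal(res$odds_ratio, 0)
  expect_true(res$degenerate)
  expect_true(is.na(res$ci_low) && is.na(res$ci_high))
  expect_equal(oddsRatioCI(5, 0, 5, 95)$odds_ratio, Inf)
})

test_that("burden collapse sums qualifying variants and matches the hand-built table", {
  variants <- data.frame(
    lof = c(TRUE, TRUE, TRUE),
    last_exon = FALSE,
    maf_a = NA_real_, maf_b = NA_real_,
    case_alt = c(1L, 2L, 1L), case_total = 2000L,
    control_alt = c(0L, 1L, 0L), control_total = 20000L)
  res <- burdenCollapse("G", variants)
  expect_equal(res$a, 4); expect_equal(res$c, 1)
  expect_equal(res$b, 5996); expect_equal(res$d, 59999)
  ## frozen from the enumeration oracle on the collapsed table
  expect_equal(res$p_two_sided, 0.0003163971, tolerance = 1e-6)
  expect_equal(res$odds_ratio, 40.02602, tolerance = 1e-6)
  ## a last-exon variant contributes nothing
  variants$last_exon[2] <- TRUE
  res2 <- burdenCollapse("G", variants)
  expect_equal(res2$a, 2)
  expect_equal(res2$n_qualifying, 2L)
  ## a single qualifying variant equals the per-variant result
  v1 <- variants[1, ]
  res3 <- burdenCollapse("G", v1)
  expect_equal(res3$p_two_sided,
               fisherTwoSided(1, 1999, 0, 20000))
  ## nothing qualifying: explicit empty result, not p = 1
  v0 <- variants; v0$lof <- FALSE
  res4 <- burdenCollapse("G", v0)
  expect_true(res4$empty)
  expect_true(is.na(res4$p_two_sided))
})

test_that("association tables built from cohort counts reproduce all printed odds ratios", {
  counts <- readCountsTable(system.file("extdata",
                                        "published_allele_counts.tsv",
                                        package = "famrare"))
  res <- associationFromCounts(counts)
  expect_equal(nrow(res), 6)
  expect_equal(round(res$odds_ratio, 2), c(1.25, 0.99, 1.13, 1.46, 1.14, 1.01))
  ## optional multiple-testing correction is monotone
  p_bh <- associationTest(res$a, res$b, res$c, res$d, p_adjust = "BH")
  expect_true(all(p_bh$p_two_sided >= res$p_two_sided - 1e-12))
})
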