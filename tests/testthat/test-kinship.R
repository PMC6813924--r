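# KING-robust kinship estimation and pedigree-discordance flagging.

test_that("duplicate genotype vectors give phi exactly 0.5 and zero-het pairs error", {
  g <- c(0L, 1L, 1L, 2L, 0L, 1L)
  est <- estimateKinship(g, g)
  expect_identical(est$phi, 0.5)
  expect_equal(est$n_both_het, 3L)
  expect_error(estimateKinship(c(0L, 2L), c(0L, 0L)),
               class = "famrare_undefined_kinship")
})

test_that("kinship is symmetric and unchanged by shared hom-ref sites", {
  set.seed(42)
  gi <- sample(0:2, 500, replace = TRUE)
  gj <- sample(0:2, 500, replace = TRUE)
  e1 <- estimateKinship(gi, gj)
  e2 <- estimateKinship(gj, gi)
  expect_identical(e1$phi, e2$phi)
  ## padding with double-hom-ref sites changes nothing
  e3 <- estimateKinship(c(gi, rep(0L, 200)), c(gj, rep(0L, 200)))
  expect_identical(e1$phi, e3$phi)
})

test_that("gene-dropped pedigrees calibrate phi by relationship class", {
  sim <- simulateCohort(simulationConfig(
    seed = 11, n_families = 12, n_individuals = 48,
    n_background_variants = 10000, maf_strata = 0.3, stratum_weights = 1,
    planted_risk = NULL))
  kin <- kinshipMatrix(sim$cohort)
  m <- members(pedigree(sim$cohort))
  rel <- classifyPairs(kin, m)
  po <- kin$phi[rel == "parent_offspring"]
  sib <- kin$phi[rel == "full_sibs"]
  unrel <- kin$phi[rel == "unrelated"]
  expect_gt(length(po), 10); expect_gt(length(sib), 5)
  expect_lt(abs(mean(po) - 0.25), 0.03)
  expect_lt(abs(mean(sib) - 0.25), 0.03)
  expect_lt(abs(mean(unrel)), 0.03)
  ## one specific unrelated founder pair sits near zero
  founders <- m$sample_id[is.na(m$father_id) & is.na(m$mother_id)]
  pair <- kin[kin$sample_i == founders[1] & kin$sample_j %in% founders &
                m$family_id[match(kin$sample_j, m$sample_id)] !=
                m$family_id[match(founders[1], m$sample_id)], ][1, ]
  expect_lt(abs(pair$phi), 0.02)
  ## duplicate sample (same individual twice)
  g <- genotypes(sim$cohort)[, 1]
  expect_identical(estimateKinship(g, g)$phi, 0.5)
  ## ordering: duplicate > first-degree > unrelated
  expect_true(0.5 > mean(po) && mean(po) > mean(unrel))
})

test_that("declared relatives with unrelated-range phi are flagged; fully discordant samples excluded", {
  m <- members(testPed(c("MOM", "SIS", "ME"),
                       mother_id = c(NA, "MOM", "MOM")))
  samples <- c("MOM", "SIS", "ME")
  phi <- matrix(0.5, 3, 3, dimnames = list(samples, samples))
  phi["MOM", "SIS"] <- phi["SIS", "MOM"] <- 0.24   # concordant sisters-range
  phi["MOM", "ME"] <- phi["ME", "MOM"] <- -0.019   # the reported orphan case
  phi["SIS", "ME"] <- phi["ME", "SIS"] <- -0.015
  res <- flagPedigreeDiscordance(phi, Pedigree(m))
  expect_equal(nrow(res$discordant), 2)
  expect_true(all(res$discordant$band == "unrelated"))
  expect_equal(res$exclude, "ME")   # discordant with all declared relatives
  ## MOM keeps one concordant first-degree link, so she stays
  expect_false("MOM" %in% res$exclude)
})

test_that("a simulated sample swap is discovered and recommended for exclusion", {
  sim <- simulateCohort(simulationConfig(
    seed = 3, n_families = 10, n_individuals = 40,
    n_background_variants = 5000, maf_strata = 0.3, stratum_weights = 1,
    planted_risk = NULL, n_sample_swaps = 1))
  expect_length(sim$truth$swapped, 1)
  kin <- kinshipMatrix(sim$cohort)
  res <- flagPedigreeDiscordance(kin, pedigree(sim$cohort))
  expect_equal(res$exclude, sim$truth$swapped)
})

test_that("relationship bands follow the standard cutoffs", {
  expect_equal(relationshipBand(c(0.49, 0.25, 0.12, 0.06, 0.01, -0.02)),
               c("duplicate", "first_degree", "second_degree", "third_degree",
                 "unrelated", "unrelated"))
})
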