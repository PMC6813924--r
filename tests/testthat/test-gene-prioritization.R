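# Gene-based discovery shortlisting and cross-cohort replication rules.

## two families: F01 mother+daughter (both affected) and F02 trio with one
## affected child; variant 1 segregates in F01, variant 2 is a singleton in
## the multi-affected F01, variant 3 is carried by F02's only affected member
twoFamilyCohort <- function(maf_a = NA_real_, maf_b = NA_real_,
                            consequence = "stop_gained") {
  ped <- Pedigree(data.frame(
    family_id = c("F01", "F01", "F02", "F02", "F02"),
    sample_id = c("MOM", "DGT", "P2", "M2", "KID"),
    father_id = c(NA, NA, NA, NA, "P2"),
    mother_id = c(NA, "MOM", NA, NA, "M2"),
    sex = c("female", "female", "male", "female", "female"),
    affection = c("breast_cancer", "breast_cancer", "unaffected",
                  "unaffected", "breast_cancer"),
    age_at_diagnosis = c(46, 44, NA, NA, 37),
    is_index = c(FALSE, TRUE, FALSE, FALSE, TRUE),
    is_sequenced = TRUE))
  ac <- rbind(c(1L, 1L, 0L, 0L, 0L),
              c(0L, 1L, 0L, 0L, 0L),
              c(0L, 0L, 0L, 0L, 1L))
  colnames(ac) <- c("MOM", "DGT", "P2", "M2", "KID")
  ann <- annRow(1:3, c("G1", "G2", "G3"), c("TX1", "TX2", "TX3"),
                consequence, exon_rank = 3L, exon_total = 11L)
  testCohort(ac, ped, ann, maf_a = maf_a, maf_b = maf_b)
}

test_that("a rare LoF carried by affected mother and daughter is shortlisted", {
  co <- twoFamilyCohort()
  sl <- suppressMessages(shortlistGenesDiscovery(co))
  expect_true("G1" %in% sl$gene)
  rec <- sl[sl$gene == "G1", ]
  expect_equal(rec$n_carrier_patients, 2L)
  expect_equal(rec$carrier_families, "F01")
  ## the singleton LoF in the multi-affected family F01 does not qualify...
  expect_false("G2" %in% sl$gene)
  ## ...but the single-affected-member family F02 qualifies with one carrier
  expect_true("G3" %in% sl$gene)
  ## output is sorted by (gene, chrom, pos)
  expect_equal(sl$gene, sort(sl$gene))
})

test_that("panel MAF above 0.1% in either panel blocks discovery; boundary is inclusive", {
  expect_false("G1" %in%
    suppressMessages(shortlistGenesDiscovery(twoFamilyCohort(maf_b = 0.002)))$gene)
  expect_true("G1" %in%
    suppressMessages(shortlistGenesDiscovery(twoFamilyCohort(maf_a = 0.001,
                                                             maf_b = 0.001)))$gene)
  ## non-LoF consequences are never admitted in gene-based mode
  expect_equal(nrow(suppressMessages(shortlistGenesDiscovery(
    twoFamilyCohort(consequence = "missense_variant")))), 0)
})

test_that("counted carriers must pass the genotype-QC surrogate", {
  co <- twoFamilyCohort()
  ## degrade the daughter's carrier call: skewed allele balance
  ad <- SummarizedExperiment::assay(co, "AD")
  ad["1:1001:A:G", "DGT"] <- 2L
  SummarizedExperiment::assays(co)$AD <- ad
  sl <- suppressMessages(shortlistGenesDiscovery(co))
  expect_false("G1" %in% sl$gene)
})

test_that("qc surrogate thresholds behave on het/hom calls and reject noisy simulated calls", {
  expect_true(qcSurrogate(1L, 60L, 29L, 99L))           # balance 0.48
  expect_false(qcSurrogate(1L, 60L, 5L, 99L))           # balance 0.08
  expect_false(qcSurrogate(1L, 5L, 3L, 99L))            # depth 5
  expect_false(qcSurrogate(1L, 60L, 29L, 10L))          # GQ 10
  expect_true(qcSurrogate(2L, 40L, 39L, 99L))           # hom alt, 0.975
  expect_false(qcSurrogate(2L, 40L, 30L, 99L))          # hom alt, 0.75
  expect_false(qcSurrogate(NA_integer_, 60L, 30L, 99L)) # missing call
  ## rejection rate on simulated noisy carrier calls far exceeds clean calls
  noisy <- simulateCohort(simulationConfig(seed = 8, qc_noise_rate = 0.3,
                                           n_background_variants = 150))
  ac <- genotypes(noisy$cohort)
  qc <- qcSurrogate(ac, SummarizedExperiment::assay(noisy$cohort, "DP"),
                    SummarizedExperiment::assay(noisy$cohort, "AD"),
                    SummarizedExperiment::assay(noisy$cohort, "GQ"))
  het <- !is.na(ac) & ac == 1L
  rej_noisy <- mean(!qc[het])
  clean <- simulateCohort(simulationConfig(seed = 8, qc_noise_rate = 0,
                                           n_background_variants = 150))
  ac2 <- genotypes(clean$cohort)
  qc2 <- qcSurrogate(ac2, SummarizedExperiment::assay(clean$cohort, "DP"),
                     SummarizedExperiment::assay(clean$cohort, "AD"),
                     SummarizedExperiment::assay(clean$cohort, "GQ"))
  rej_clean <- mean(!qc2[!is.na(ac2) & ac2 == 1L])
  expect_gt(rej_noisy, rej_clean + 0.2)
  expect_lt(rej_clean, 0.05)
})

test_that("samples without a pedigree entry are a hard error", {
  co <- twoFamilyCohort()
  expect_error(methods::validObject(famrare:::newVariantCohort(
    data.frame(chrom = "1", pos = 1L, ref = "A", alt = "G",
               id = NA_character_, qual = 1,
               maf_panel_a = NA_real_, maf_panel_b = NA_real_),
    matrix(0L, 1, 1, dimnames = list(NULL, "NOBODY")),
    matrix(10L, 1, 1), matrix(0L, 1, 1), matrix(99L, 1, 1),
    NULL, pedigree(co))))
})

test_that("planted variants are recovered exactly against the truth manifest", {
  sim <- simulateCohort(simulationConfig(
    seed = 13,
    maf_strata = c(2e-3, 1e-2, 0.25), stratum_weights = c(0.3, 0.3, 0.4),
    planted_risk = data.frame(
      gene = c("RISKG1", "RISKG2", "RISKG3"),
      consequence = c("stop_gained", "frameshift_variant",
                      "splice_donor_variant"),
      n_carrier_families = 1L, penetrance = 1)))
  sl <- suppressMessages(shortlistGenesDiscovery(sim$cohort))
  expect_setequal(unique(sl$key), sim$truth$planted$key)
})

test_that("replication needs same transcript, both variants outside the last exon", {
  sim <- simulateCohort(simulationConfig(seed = 6))
  sl <- suppressMessages(shortlistGenesDiscovery(sim$cohort))
  ## same transcript, interior exon: replicates
  rep1 <- simulateReplicationCohort(sim, plant = data.frame(gene = "RISKG1"))
  out1 <- suppressMessages(replicateGenes(sl, rep1$cohort))
  expect_equal(unique(out1$gene), "RISKG1")
  expect_equal(unique(out1$stage), "replicated")
  ## replication genes are a subset of discovery genes
  expect_true(all(out1$gene %in% sl$gene))
  ## last-exon replication variant: empty
  rep2 <- simulateReplicationCohort(sim, plant = data.frame(
    gene = "RISKG1", in_last_exon = TRUE))
  expect_equal(nrow(suppressMessages(replicateGenes(sl, rep2$cohort))), 0)
  ## different transcript: empty
  rep3 <- simulateReplicationCohort(sim, plant = data.frame(
    gene = "RISKG1", same_transcript = FALSE))
  expect_equal(nrow(suppressMessages(replicateGenes(sl, rep3$cohort))), 0)
  ## no planting at all: empty
  rep4 <- simulateReplicationCohort(sim)
  expect_equal(nrow(suppressMessages(replicateGenes(sl, rep4$cohort))), 0)
})

test_that("discovery shortlisting is monotone in its thresholds", {
  sim <- simulateCohort(simulationConfig(seed = 21))
  base <- suppressMessages(shortlistGenesDiscovery(sim$cohort))
  tight_maf <- suppressMessages(shortlistGenesDiscovery(sim$cohort,
                                                        mafMax = 0.0001))
  more_carriers <- suppressMessages(shortlistGenesDiscovery(
    sim$cohort, minFamilyCarriers = 3L))
  expect_true(all(tight_maf$key %in% base$key))
  expect_true(all(more_carriers$key %in% base$key))
})

test_that("null simulations with common-only background produce an empty shortlist", {
  sim <- simulateCohort(simulationConfig(
    seed = 17, planted_risk = NULL,
    maf_strata = c(2e-3, 1e-2, 0.25), stratum_weights = c(0.4, 0.3, 0.3)))
  sl <- suppressMessages(shortlistGenesDiscovery(sim$cohort))
  expect_equal(nrow(sl), 0)
})
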