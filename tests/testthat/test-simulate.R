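# Synthetic-data generator: determinism, Mendelian consistency, founder
# frequency calibration, penetrance behaviour.

test_that("identical config + seed gives byte-identical VCF output", {
  cfg <- simulationConfig(seed = 9, n_families = 5, n_individuals = 16,
                          n_background_variants = 120)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- writeSimulation(simulateCohort(cfg), d1)
  p2 <- writeSimulation(simulateCohort(cfg), d2)
  expect_identical(readLines(p1[["vcf"]]), readLines(p2[["vcf"]]))
  expect_identical(readLines(p1[["ped"]]), readLines(p2[["ped"]]))
  expect_identical(readLines(p1[["truth"]]), readLines(p2[["truth"]]))
  ## and a different seed gives different genotypes
  cfg2 <- simulationConfig(seed = 10, n_families = 5, n_individuals = 16,
                           n_background_variants = 120)
  expect_false(identical(genotypes(simulateCohort(cfg2)$cohort),
                         genotypes(simulateCohort(cfg)$cohort)))
})

test_that("every non-founder allele is traceable to a parent, across seeds", {
  for (seed in c(1, 2, 3)) {
    sim <- simulateCohort(simulationConfig(
      seed = seed, n_families = 6, n_individuals = 22,
      n_background_variants = 150))
    expect_true(isTRUE(checkMendelian(sim)), label = paste("seed", seed))
  }
})

test_that("realized founder allele frequency converges to the configured MAF", {
  sim <- simulateCohort(simulationConfig(
    seed = 5, n_families = 40, n_individuals = 120,
    n_background_variants = 400, maf_strata = c(0.1, 0.3),
    stratum_weights = c(0.5, 0.5), planted_risk = NULL))
  m <- members(pedigree(sim$cohort))
  founders <- m$sample_id[is.na(m$father_id) & is.na(m$mother_id)]
  alle <- sim$phased$maternal[, founders] + sim$phased$paternal[, founders]
  realized <- rowSums(alle) / (2 * length(founders))
  for (f in c(0.1, 0.3)) {
    sites <- sim$truth$founder_freq == f
    ## binomial sampling error of the mean over many sites is tiny
    expect_lt(abs(mean(realized[sites]) - f), 0.02)
  }
})

test_that("penetrance 1.0 makes every planted carrier affected; manifest lists them", {
  sim <- simulateCohort(simulationConfig(
    seed = 4, n_families = 4, n_individuals = 12,
    planted_risk = data.frame(gene = "RISKG1", consequence = "stop_gained",
                              n_carrier_families = 1L, penetrance = 1),
    sporadic_rate = 0))
  pl <- sim$truth$planted
  expect_equal(nrow(pl), 1)
  carriers <- strsplit(pl$carriers, ",")[[1]]
  expect_gte(length(carriers), 2)   # founder + forced child at minimum
  m <- members(pedigree(sim$cohort))
  expect_true(all(m$affection[m$sample_id %in% carriers] != "unaffected"))
})

test_that("planted-gene recovery is perfect at penetrance 1 and degrades as penetrance drops", {
  recovered <- vapply(c(1, 0.5, 0), function(pen) {
    hits <- 0L
    for (seed in 1:8) {
      sim <- simulateCohort(simulationConfig(
        seed = seed, n_families = 8, n_individuals = 26,
        n_background_variants = 80,
        maf_strata = c(2e-3, 1e-2, 0.25), stratum_weights = c(0.3, 0.3, 0.4),
        planted_risk = data.frame(gene = "RISKG1",
                                  consequence = "stop_gained",
                                  n_carrier_families = 1L, penetrance = pen),
        sporadic_rate = 0))
      sl <- suppressMessages(suppressWarnings(
        shortlistGenesDiscovery(sim$cohort)))
      hits <- hits + ("RISKG1" %in% sl$gene)
    }
    hits
  }, integer(1))
  expect_equal(recovered[1], 8L)               # sensitivity 1.0
  expect_true(all(diff(recovered) <= 0))       # monotone degradation
  expect_lt(recovered[3], 8L)
})

test_that("replication plantings obey the transcript and exon placement flags", {
  sim <- simulateCohort(simulationConfig(seed = 6))
  rep1 <- simulateReplicationCohort(sim, plant = data.frame(gene = "RISKG1"))
  tx_disc <- sim$truth$planted$transcript_id
  expect_equal(rep1$truth$transcript_id, tx_disc)
  ann <- as.data.frame(annotations(rep1$cohort))
  a <- ann[ann$key == rep1$truth$key, ]
  expect_lt(a$exon_rank, a$exon_total)
  rep2 <- simulateReplicationCohort(sim, plant = data.frame(
    gene = "RISKG1", in_last_exon = TRUE))
  ann2 <- as.data.frame(annotations(rep2$cohort))
  a2 <- ann2[ann2$key == rep2$truth$key, ]
  expect_equal(a2$exon_rank, a2$exon_total)
  rep3 <- simulateReplicationCohort(sim, plant = data.frame(
    gene = "RISKG1", same_transcript = FALSE))
  expect_false(rep3$truth$transcript_id == tx_disc)
})
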