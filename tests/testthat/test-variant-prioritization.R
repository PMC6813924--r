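# CGV / SVGU / FSV strategy tagging and the combined variant shortlist.

## three families, all members affected+sequenced unless noted:
##   F01: MOM + DGT (mother-daughter), F02: singleton P3, F03: singleton P4
## variants:
##   1  missense, shared by MOM+DGT and the unrelated P3 (SVGU identical)
##   2  missense in gene GC (cancer list), carriers MOM+DGT
##   3  missense, same gene/transcript as 4, carrier P3
##   4  missense, same gene/transcript as 3, carrier P4 (SVGU distinct pair)
##   5  missense, ultra-rare, single family F01 (FSV), carriers MOM+DGT
##   6  synonymous (outside the variant universe), carriers everywhere
strategyCohort <- function(maf_a = NA_real_, damaging = 1L) {
  ped <- Pedigree(data.frame(
    family_id = c("F01", "F01", "F02", "F03"),
    sample_id = c("MOM", "DGT", "P3", "P4"),
    father_id = NA_character_, mother_id = c(NA, "MOM", NA, NA),
    sex = "female", affection = "breast_cancer",
    age_at_diagnosis = c(60, 47, 37, 41),
    is_index = c(FALSE, TRUE, TRUE, TRUE), is_sequenced = TRUE))
  ac <- rbind(c(1L, 1L, 1L, 0L),
              c(1L, 1L, 0L, 0L),
              c(0L, 0L, 1L, 0L),
              c(0L, 0L, 0L, 1L),
              c(1L, 1L, 0L, 0L),
              c(1L, 1L, 1L, 1L))
  colnames(ac) <- c("MOM", "DGT", "P3", "P4")
  ann <- annRow(1:6,
                gene = c("GA", "GC", "GB", "GB", "GD", "GE"),
                transcript_id = c("TXA", "TXC", "TXB", "TXB", "TXD", "TXE"),
                consequence = c(rep("missense_variant", 5),
                                "synonymous_variant"),
                exon_rank = 2L, exon_total = 9L)
  testCohort(ac, ped, ann, maf_a = maf_a, damaging = damaging)
}

## kinship consistent with the declared structure: relatives 0.25, others ~0
strategyPhi <- function() {
  s <- c("MOM", "DGT", "P3", "P4")
  phi <- matrix(0.001, 4, 4, dimnames = list(s, s))
  phi["MOM", "DGT"] <- phi["DGT", "MOM"] <- 0.25
  diag(phi) <- 0.5
  phi
}

test_that("CGV tags exactly the variants in listed genes and rejects empty lists", {
  co <- strategyCohort()
  tags <- cgvSelect(co, c("gc", "GZ"))   # case-insensitive match
  expect_equal(tags$key, "1:1002:A:G")
  expect_equal(tags$strategy, "CGV")
  ## LoF in an unlisted gene stays untagged; synonymous never tagged
  expect_false("1:1006:A:G" %in% cgvSelect(co, "GE")$key)
  expect_error(cgvSelect(co, character(0)),
               class = "famrare_configuration_error")
  ## set-membership oracle on a simulated cohort
  sim <- simulateCohort(simulationConfig(seed = 19, planted_risk = NULL))
  ann <- as.data.frame(annotations(sim$cohort))
  listed <- unique(ann$gene)[1:10]
  tags2 <- cgvSelect(sim$cohort, listed)
  uni <- ann[inVariantUniverse(ann$consequence, "variant_based"), ]
  expect_setequal(tags2$key, unique(uni$key[uni$gene %in% listed]))
})

test_that("SVGU tags identical shared variants and same-gene distinct pairs in unrelated patients", {
  co <- strategyCohort()
  tags <- svguSelect(co, strategyPhi())
  ident <- tags$key[tags$reason == "identical_variant_shared"]
  expect_equal(ident, "1:1001:A:G")
  distinct <- sort(tags$key[tags$reason == "same_gene_distinct_variants"])
  expect_equal(distinct, c("1:1003:A:G", "1:1004:A:G"))
  ## variant 5, confined to one family, is never SVGU
  expect_false("1:1005:A:G" %in% tags$key)
  ## related carriers only (different phi): drop the identical tag
  phi2 <- strategyPhi()
  phi2["MOM", "P3"] <- phi2["P3", "MOM"] <- 0.25
  phi2["DGT", "P3"] <- phi2["P3", "DGT"] <- 0.25
  tags2 <- svguSelect(co, phi2)
  expect_false("1:1001:A:G" %in%
                 tags2$key[tags2$reason == "identical_variant_shared"])
  ## same-transcript requirement can be relaxed but holds by default
  ann <- as.data.frame(annotations(co))
  expect_true(all(ann$transcript_id[ann$key %in% distinct] == "TXB"))
})

test_that("FSV tags ultra-rare single-family variants only", {
  co <- strategyCohort()          # panel-absent => MAF treated as 0
  tags <- fsvSelect(co)
  expect_true("1:1005:A:G" %in% tags$key)   # single-family carriers
  expect_true("1:1002:A:G" %in% tags$key)
  expect_false("1:1001:A:G" %in% tags$key)  # two families
  ## MAF 0.05% in a panel breaks the strict < 0.01% rule
  co2 <- strategyCohort(maf_a = 5e-4)
  expect_equal(nrow(fsvSelect(co2)), 0)
})

test_that("the combined shortlist applies tags, MAF, pathogenicity, segregation and QC", {
  co <- strategyCohort()
  phi <- strategyPhi()
  tags <- rbind(cgvSelect(co, "GC"), svguSelect(co, phi), fsvSelect(co))
  sl <- suppressMessages(shortlistVariants(co, tags))
  ## a missense damaging in 1/7 tools, tagged by two strategies, carried by
  ## both affected relatives of its family, survives
  rec <- sl[sl$key == "1:1002:A:G", ]
  expect_equal(nrow(rec), 1)
  expect_equal(rec$strategies, "CGV,FSV")
  expect_equal(rec$n_carrier_patients, 2L)
  ## output is a subset of the tagged set
  expect_true(all(sl$key %in% tags$key))
  ## raising the consensus requirement above the damaging count empties it
  sl2 <- suppressMessages(shortlistVariants(co, tags, consensusK = 3L))
  expect_equal(nrow(sl2), 0)
  expect_true(all(sl2$key %in% sl$key))
  ## damaging count 0: nothing passes at k = 1 either
  co0 <- strategyCohort(damaging = 0L)
  tags0 <- rbind(cgvSelect(co0, "GC"), svguSelect(co0, phi), fsvSelect(co0))
  expect_equal(nrow(suppressMessages(shortlistVariants(co0, tags0))), 0)
})

test_that("a tagged variant absent from one affected sequenced relative is dropped", {
  co <- strategyCohort()
  ac <- genotypes(co)
  ac["1:1002:A:G", "DGT"] <- 0L   # daughter no longer carries
  SummarizedExperiment::assays(co)$AC <- ac
  tags <- rbind(cgvSelect(co, "GC"), fsvSelect(co))
  sl <- suppressMessages(shortlistVariants(co, tags))
  expect_false("1:1002:A:G" %in% sl$key)
})

test_that("strategy tags are order-independent and FSV/SVGU-identical stay disjoint across runs", {
  for (seed in c(23, 29, 31)) {
    sim <- simulateCohort(simulationConfig(seed = seed))
    kin <- suppressWarnings(kinshipMatrix(sim$cohort))
    svgu <- svguSelect(sim$cohort, kin)
    fsv <- fsvSelect(sim$cohort)
    expect_length(intersect(
      fsv$key, svgu$key[svgu$reason %in% "identical_variant_shared"]), 0)
    tagsA <- rbind(svgu, fsv)
    tagsB <- rbind(fsv, svgu)
    slA <- suppressMessages(shortlistVariants(sim$cohort, tagsA,
                                              verbose = FALSE))
    slB <- suppressMessages(shortlistVariants(sim$cohort, tagsB,
                                              verbose = FALSE))
    expect_identical(as.data.frame(slA), as.data.frame(slB))
  }
})

test_that("cross-cohort presence flags exactly the planted identical overlaps", {
  sim <- simulateCohort(simulationConfig(
    seed = 13,
    maf_strata = c(2e-3, 1e-2, 0.25), stratum_weights = c(0.3, 0.3, 0.4),
    planted_risk = data.frame(
      gene = c("RISKG1", "RISKG2", "RISKG3"),
      consequence = "stop_gained", n_carrier_families = 1L, penetrance = 1)))
  keys <- sim$truth$planted$key
  rep <- simulateReplicationCohort(sim, plant_identical = keys[1:2])
  cand <- S4Vectors::DataFrame(key = keys)
  out <- crossCohortPresence(cand, rep$cohort)
  expect_equal(out$present_in_replication, c(TRUE, TRUE, FALSE))
  expect_equal(sum(out$n_replication_carriers), 2L)
})
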