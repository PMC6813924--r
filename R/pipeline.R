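# End-to-end orchestration: simulate (or load) a discovery cohort, run
# kinship QC with sample exclusion, the gene-based and variant-based
# discovery shortlists, cross-cohort replication, optional allele-count
# association, and write paper-shaped reports plus a filter-funnel log.

#' Pipeline configuration
#'
#' A serializable list of every input path, threshold and mode flag the
#' pipeline uses; the configuration is echoed verbatim (YAML) into the run's
#' output directory.
#'
#' @param simulate Generate inputs with the synthetic-cohort module
#'   (default `TRUE`); otherwise `vcf`, `ped`, `panel_a`, `panel_b` paths
#'   must be given.
#' @param sim Named list of [simulationConfig()] arguments.
#' @param replication_plant data.frame of replication plantings (see
#'   [simulateReplicationCohort()]), or `NULL`.
#' @param vcf,ped,panel_a,panel_b,replication_vcf,replication_ped Input paths
#'   when `simulate = FALSE`.
#' @param gene_list Path to a one-symbol-per-line cancer-gene list, or a
#'   character vector, or `NULL` to skip the CGV strategy.
#' @param counts_table Path to an allele-count table for association, or
#'   `NULL`.
#' @param group_pairs List of `c(case_group, control_group)` label pairs for
#'   association.
#' @param maf_max,fsv_maf_max,min_family_carriers,consensus_k Shortlisting
#'   thresholds.
#' @param qc_depth,qc_gq,qc_balance,qc_hom_balance QC-surrogate thresholds.
#' @param kinship_unrelated Discordance threshold (default 0.0442).
#' @param last_exon_at_discovery Apply the last-exon rule already at
#'   discovery.
#' @param seed Random seed.
#' @param out_dir Output directory for reports (`NULL`: no files written).
#' @return A list of class `famrare_pipeline_config`.
#' @export
pipelineConfig <- function(simulate = TRUE, sim = list(),
                           replication_plant = NULL,
                           vcf = NULL, ped = NULL, panel_a = NULL,
                           panel_b = NULL, replication_vcf = NULL,
                           replication_ped = NULL,
                           gene_list = NULL, counts_table = NULL,
                           group_pairs = NULL,
                           maf_max = 0.001, fsv_maf_max = 1e-4,
                           min_family_carriers = 2L, consensus_k = 1L,
                           qc_depth = 10, qc_gq = 20,
                           qc_balance = c(0.25, 0.75), qc_hom_balance = 0.9,
                           kinship_unrelated = 0.0442,
                           last_exon_at_discovery = FALSE,
                           seed = 1L, out_dir = NULL) {
  cfg <- as.list(environment())
  class(cfg) <- "famrare_pipeline_config"
  cfg
}

stageTry <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    famrareStop(paste0("pipeline stage '", stage, "' failed: ",
                       conditionMessage(e)), "famrare_stage_error")
  })
}

#' Run the full prioritization pipeline
#'
#' Simulate -> kinship QC -> gene-based discovery + replication ->
#' variant-based strategies + shortlist + presence lookup -> association.
#' Every filter stage's input/output counts are recorded in a funnel log
#' (`n_out <= n_in` per stage); reports are written as TSV/JSON when
#' `out_dir` is set, byte-identically for identical config + seed.
#'
#' @param config A [pipelineConfig()] list.
#' @return Invisible list: `cohort`, `kinship`, `discordance`,
#'   `genes_discovery`, `genes_replicated`, `variant_tags`,
#'   `variants_shortlist`, `association`, `funnel`, `truth` (when
#'   simulated).
#' @export
runPipeline <- function(config) {
  funnel <- data.frame(stage = character(), n_in = integer(),
                       n_out = integer())
  logStage <- function(stage, n_in, n_out) {
    message(sprintf("[%s] %d -> %d", stage, n_in, n_out))
    funnel <<- rbind(funnel, data.frame(stage = stage,
                                        n_in = as.integer(n_in),
                                        n_out = as.integer(n_out)))
  }

  ## ---- inputs ----
  sim <- NULL; rep_sim <- NULL
  if (isTRUE(config$simulate)) {
    sim <- stageTry("simulate", {
      sc <- do.call(simulationConfig, c(config$sim, list(seed = config$seed)))
      simulateCohort(sc)
    })
    cohort <- sim$cohort
    rep_sim <- stageTry("simulate_replication",
                        simulateReplicationCohort(sim,
                                                  plant = config$replication_plant))
    rep_cohort <- rep_sim$cohort
  } else {
    cohort <- stageTry("load_inputs", {
      ped <- readPedigree(config$ped)
      pa <- if (!is.null(config$panel_a)) readFrequencyTable(config$panel_a)
      pb <- if (!is.null(config$panel_b)) readFrequencyTable(config$panel_b)
      readCohortVcf(config$vcf, ped, panelA = pa, panelB = pb)
    })
    rep_cohort <- if (!is.null(config$replication_vcf))
      stageTry("load_replication",
               readCohortVcf(config$replication_vcf,
                             readPedigree(config$replication_ped)))
  }

  ## ---- kinship QC ----
  kin <- stageTry("kinship", kinshipMatrix(cohort))
  disc <- stageTry("kinship_discordance",
                   flagPedigreeDiscordance(kin, pedigree(cohort),
                                           config$kinship_unrelated))
  n_samples <- ncol(cohort)
  keep <- setdiff(colnames(cohort), disc$exclude)
  cohort_qc <- cohort[, keep]
  logStage("samples_kinship_qc", n_samples, length(keep))
  kin_qc <- if (length(disc$exclude)) kinshipMatrix(cohort_qc) else kin

  ## ---- gene-based ----
  ann <- as.data.frame(annotations(cohort_qc))
  n_lof <- length(unique(ann$key[classifyLof(ann$consequence)]))
  logStage("gene_discovery_lof", nrow(cohort_qc), n_lof)
  genes_disc <- stageTry("gene_discovery", shortlistGenesDiscovery(
    cohort_qc, mafMax = config$maf_max,
    minFamilyCarriers = config$min_family_carriers,
    minDepth = config$qc_depth, minGq = config$qc_gq,
    balance = config$qc_balance, homBalance = config$qc_hom_balance,
    lastExonAtDiscovery = config$last_exon_at_discovery))
  logStage("gene_discovery_shortlist", n_lof, length(unique(genes_disc$key)))
  genes_rep <- NULL
  if (!is.null(rep_cohort)) {
    genes_rep <- stageTry("gene_replication",
                          replicateGenes(genes_disc, rep_cohort,
                                         mafMax = config$maf_max))
    logStage("gene_replication", length(unique(genes_disc$gene)),
             length(unique(genes_rep$gene)))
  }

  ## ---- variant-based ----
  gene_list <- config$gene_list
  if (!is.null(gene_list) && length(gene_list) == 1 && file.exists(gene_list))
    gene_list <- readLines(gene_list)
  tags <- stageTry("variant_tagging", {
    t <- rbind(
      if (!is.null(gene_list)) cgvSelect(cohort_qc, gene_list),
      svguSelect(cohort_qc, kin_qc),
      fsvSelect(cohort_qc, fsvMafMax = config$fsv_maf_max))
    t
  })
  logStage("variant_tagging", nrow(cohort_qc), length(unique(tags$key)))
  variants_sl <- stageTry("variant_shortlist", shortlistVariants(
    cohort_qc, tags, mafMax = config$maf_max,
    consensusK = config$consensus_k, minDepth = config$qc_depth,
    minGq = config$qc_gq, balance = config$qc_balance,
    homBalance = config$qc_hom_balance))
  logStage("variant_shortlist", length(unique(tags$key)), nrow(variants_sl))
  if (!is.null(rep_cohort)) {
    variants_sl <- stageTry("variant_presence",
                            crossCohortPresence(variants_sl, rep_cohort))
    logStage("variant_presence", nrow(variants_sl),
             sum(variants_sl$present_in_replication))
  }

  ## ---- association ----
  assoc <- NULL
  if (!is.null(config$counts_table)) {
    assoc <- stageTry("association", {
      counts <- if (is.character(config$counts_table))
        readCountsTable(config$counts_table) else config$counts_table
      associationFromCounts(counts, config$group_pairs)
    })
    logStage("association", nrow(assoc), nrow(assoc))
  }

  res <- list(cohort = cohort_qc, kinship = kin_qc, discordance = disc,
              genes_discovery = genes_disc, genes_replicated = genes_rep,
              variant_tags = tags, variants_shortlist = variants_sl,
              association = assoc, funnel = funnel,
              truth = if (!is.null(sim))
                list(discovery = sim$truth, replication = rep_sim$truth))
  if (!is.null(config$out_dir)) writePipelineReports(res, config)
  invisible(res)
}

#' Association results from an allele-count table
#'
#' Builds one 2x2 table per (variant, case-group vs control-group) pair from
#' cohort allele counts (`ref = total - alt`) and tests each with Fisher's
#' exact test and the cross-product odds ratio.
#'
#' @param counts data.frame from [readCountsTable()].
#' @param group_pairs List of `c(case_group, control_group)` label pairs; by
#'   default consecutive group pairs per variant, in table order.
#' @param method CI method, see [oddsRatioCI()].
#' @return data.frame shaped like a published association table: variant,
#'   groups, cells, p, OR, CI, method.
#' @export
associationFromCounts <- function(counts, group_pairs = NULL,
                                  method = c("exact_conditional", "woolf")) {
  method <- match.arg(method)
  rows <- list()
  for (v in unique(counts$variant)) {
    cv <- counts[counts$variant == v, , drop = FALSE]
    pairs <- group_pairs %||%
      lapply(seq_len(nrow(cv) %/% 2), function(i) cv$group[c(2 * i - 1, 2 * i)])
    for (gp in pairs) {
      case <- cv[cv$group == gp[1], , drop = FALSE]
      ctrl <- cv[cv$group == gp[2], , drop = FALSE]
      if (!nrow(case) || !nrow(ctrl)) next
      res <- associationTest(case$alt[1], case$total[1] - case$alt[1],
                             ctrl$alt[1], ctrl$total[1] - ctrl$alt[1],
                             method = method)
      rows[[length(rows) + 1L]] <- data.frame(
        variant = v, case_group = gp[1], control_group = gp[2], res)
    }
  }
  do.call(rbind, rows)
}

writePipelineReports <- function(res, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(name) file.path(config$out_dir, name)
  wt <- function(df, name) {
    utils::write.table(as.data.frame(df), out(name), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = ".")
  }
  wt(res$kinship, "kinship.tsv")
  wt(res$discordance$discordant, "kinship_discordance.tsv")
  writeLines(res$discordance$exclude, out("excluded_samples.txt"))
  wt(res$genes_discovery, "genes_discovery.tsv")
  if (!is.null(res$genes_replicated)) wt(res$genes_replicated, "genes_replicated.tsv")
  writeCandidateReport(res$variants_shortlist, out("variants_shortlist.tsv"))
  writeCandidateReport(res$variants_shortlist, out("variants_shortlist.json"))
  if (!is.null(res$association)) wt(res$association, "association.tsv")
  wt(res$funnel, "funnel_log.tsv")
  cfg <- res_config_serializable(config)
  yaml::write_yaml(cfg, out("config.yaml"))
  if (!is.null(res$truth))
    jsonlite::write_json(res$truth, out("truth.json"), auto_unbox = TRUE,
                         digits = NA, na = "null", pretty = TRUE,
                         force = TRUE)
  invisible(config$out_dir)
}

res_config_serializable <- function(config) {
  cfg <- unclass(config)
  cfg$replication_plant <- if (!is.null(cfg$replication_plant))
    as.list(cfg$replication_plant)
  cfg
}
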