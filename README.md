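# famrare

Family-based rare-variant prioritization for hereditary breast/ovarian
cancer (HBOC) cohorts.

About half of familial breast cancer remains unexplained after the known
risk genes are excluded. One productive design sequences the exomes of
multiply-affected families that are negative for known risk variants, then
hunts for rare loss-of-function (LoF) alleles that segregate with disease
and recur in independent patient collections. famrare reimplements that
design as a reusable, fully testable R pipeline for annotated multi-sample
VCFs with pedigrees:

* **Kinship QC** — KING-robust pairwise kinship,
  φ = (N<sub>Aa,Aa</sub> − 2·N<sub>AA,aa</sub>) / (N<sub>Aa</sub><sup>(i)</sup> + N<sub>Aa</sub><sup>(j)</sup>),
  with pedigree-discordance flagging and exclusion of samples genetically
  unrelated to all their declared first-degree relatives.
* **Gene-based discovery** — LoF variants (stop-gain, frameshift, essential
  ±2 bp splice sites) with MAF ≤ 0.1% in two reference panels, carried by
  ≥ 2 affected sequenced patients of one family (one suffices where
  co-segregation cannot be ascertained), with a genotype-QC surrogate
  standing in for visual read inspection.
* **Cross-cohort replication** — a discovery gene replicates when an
  unrelated patient of an independent cohort carries any rare LoF on the
  *same transcript*, both variants outside the last exon.
* **Variant-based strategies** — CGV (cancer-gene list), SVGU (shared
  variants/genes in unrelated patients), FSV (ultra-rare MAF < 0.01%
  family-specific variants), combined with predictor-consensus,
  segregation and QC filters, plus replication-cohort presence lookup.
* **Association** — two-sided Fisher's exact test on alt/total allele-count
  2×2 tables (p = Σ of hypergeometric outcomes no more probable than the
  observed table), cross-product odds ratio ad/bc with Woolf or
  exact-conditional CIs, and per-gene cumulative LoF burden collapsing.
* **Synthetic cohorts** — a deterministic Mendelian gene-dropping simulator
  (pedigrees, genotypes with call metrics, annotations, frequency panels,
  truth manifests) so the whole pipeline runs end-to-end without any
  external data.

Data live in Bioconductor containers: a `VariantCohort` extends
`RangedSummarizedExperiment` (one row per site/alt allele, assays `AC`,
`DP`, `AD`, `GQ`), with S4 `Pedigree` and `SimulationConfig` classes.

## Worked example

Simulate a 17-family / 52-individual discovery cohort with one planted
stop-gain (penetrance 1), shortlist genes, and replicate against 51
simulated unrelated patients carrying a distinct same-transcript
frameshift:

```r
library(famrare)

sim <- simulateCohort(simulationConfig(seed = 1))
discovery <- shortlistGenesDiscovery(sim$cohort)
as.data.frame(discovery)[, c("key", "gene", "consequence",
                             "n_carrier_patients", "carrier_families")]
#>               key     gene             consequence n_carrier_patients carrier_families
#> 1 3:36523307:G:GT GENE0058      frameshift_variant                  1              F15
#> 2 16:24064964:A:G GENE0121 splice_acceptor_variant                  1              F07
#> 3  1:90001000:C:G   RISKG1             stop_gained                  3              F01
```

The planted `RISKG1` stop-gain is carried by three affected relatives of
family F01; two background rare LoF singletons qualify through families
with a single affected sequenced member (the "where ascertainable" rule).
Replication keeps only the gene with independent same-transcript LoF
support:

```r
rep <- simulateReplicationCohort(sim, plant = data.frame(gene = "RISKG1"))
replicateGenes(discovery, rep$cohort)
#>     gene transcript_id replication_keys      stage
#> 1 RISKG1    ENSTR00011  1:90001018:A:AG replicated
```

Association from published-style alt/total allele counts (bundled in
`inst/extdata/published_allele_counts.tsv`):

```r
counts <- readCountsTable(system.file("extdata", "published_allele_counts.tsv",
                                      package = "famrare"))
associationFromCounts(counts)[, c("variant", "case_group", "p_two_sided",
                                  "odds_ratio")]
#>            variant        case_group p_two_sided odds_ratio
#> 1 SETBP1:c.4129G>C          NFE-TCGA  0.01135602  1.2532958
#> 2 SETBP1:c.4129G>C    EUR-UKB-cancer  0.71490305  0.9901872
#> 3 SETBP1:c.4129G>C EUR-UKB-female-BC  0.02205411  1.1342879
#> 4 C7orf34:c.248C>T          NFE-TCGA  0.03246638  1.4634489
#> 5 C7orf34:c.248C>T    EUR-UKB-cancer  0.02154355  1.1405976
#> 6 C7orf34:c.248C>T EUR-UKB-female-BC  0.89554320  1.0108979
```

Each row is one case-vs-control allele-frequency comparison: e.g. the
SETBP1 missense allele is significantly enriched in cancer patients vs
cancer-free individuals of the first panel pair (OR 1.25, p 0.011).
`runPipeline(pipelineConfig(...))` chains all stages and writes TSV/JSON
reports plus a filter-funnel log; `inst/scripts/run_pipeline.R` is a thin
command-line wrapper.

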