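Package: famrare
Title: Family-Based Rare-Variant Prioritization for Hereditary Cancer Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Gene- and variant-based prioritization of candidate hereditary
    breast/ovarian cancer risk variants from annotated multi-sample exome VCFs
    with extended pedigrees. Implements KING-robust pairwise kinship estimation
    with pedigree-discordance flagging, loss-of-function consequence
    classification with the last-exon rule, family-segregation filtering of
    rare variants, three variant-based shortlisting strategies (cancer-gene
    variants, shared variants/genes in unrelated patients, family-specific
    variants), cross-cohort replication restricted to same-transcript
    non-last-exon loss-of-function variants, and case-control allele-count
    association (two-sided Fisher's exact test, odds ratios with Woolf or
    exact-conditional confidence intervals, and per-gene cumulative burden
    collapsing). A deterministic gene-dropping simulator generates complete
    synthetic study inputs (pedigrees, genotypes, annotations, frequency
    panels, truth manifests) so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'annotation.R'
    'association.R'
    'io-ped.R'
    'io-tables.R'
    'io-vcf.R'
    'kinship.R'
    'pipeline.R'
    'prioritize-genes.R'
    'prioritize-variants.R'
    'simulate-replication.R'
    'simulate.R'
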