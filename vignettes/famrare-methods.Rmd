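---
title: "Methods: family-based rare-variant prioritization with famrare"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: family-based rare-variant prioritization with famrare}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scope and model

famrare implements a discovery-and-replication workflow for candidate risk
variants in hereditary breast/ovarian cancer (HBOC) families sequenced by
whole-exome sequencing. The analysis unit is a multi-family cohort: an
annotated multi-sample VCF, an extended pedigree with cancer-affection
phenotype, and two population allele-frequency panels (a 1000-Genomes-like
panel A and a gnomAD-like panel B). The package holds these in a
`VariantCohort`, a `RangedSummarizedExperiment` with one row per (site,
alternate allele) — multi-allelic sites are split on ingest — dosage and
call-quality assays (`AC`, `DP`, `AD`, `GQ`), per-transcript consequence
annotations, and the pedigree.

The workflow has five statistical components.

### Kinship QC

Pairwise relatedness is estimated with the KING-robust within-pair
estimator,

$$\phi_{ij} = \frac{N^{Aa,Aa}_{ij} - 2\,N^{AA,aa}_{ij}}
                   {N^{Aa}_i + N^{Aa}_j},$$

computed over sites where both samples are called, after removing
cohort-monomorphic sites (they contribute nothing to either count and only
destabilize the denominator). The estimator is exact at 0.5 for duplicate
samples and centres on 0.25 / 0.125 / 0 for first-/second-degree/unrelated
pairs; relationship bands use the standard powers-of-two cutoffs (0.354,
0.177, 0.0884, 0.0442). A declared first-degree pair (parent–offspring or
full sibs) whose $\phi$ falls below the unrelated cutoff 0.0442 is flagged
discordant; a sample discordant with *all* of its declared first-degree
relatives is recommended for exclusion, which is how a sample mix-up
(a patient genetically unrelated to her reported mother and sister) is
removed before any carrier counting. The source studies do not state a
site-MAF floor for kinship; we chose to drop only cohort-monomorphic sites,
since any further floor changes $\phi$ negligibly at exome scale.

### Gene-based discovery

A variant enters the gene-based shortlist when

1. it is loss-of-function (LoF: `stop_gained`, `frameshift_variant`, or an
   essential ±2 bp splice site, `splice_acceptor_variant` /
   `splice_donor_variant`) on at least one transcript — every rule operates
   on (variant, transcript) pairs, never on the bare variant;
2. its MAF is ≤ 0.1% in **both** panels. A variant absent from a panel is
   treated as MAF 0 — a private variant must be able to pass the rarity
   filter — but absence is kept distinct from a recorded MAF of 0 and is
   logged whenever the rule is applied;
3. within at least one family it is carried by ≥ 2 affected sequenced
   patients; in families where co-segregation cannot be ascertained because
   only one affected member was sequenced, that single carrier suffices;
4. every counted carrier call passes the genotype-QC surrogate (below).

The thresholds (`mafMax = 0.001`, `minFamilyCarriers = 2`) are exposed; the
MAF bound is inclusive (≤), matching the workflow it reimplements.

### Cross-cohort replication

A discovery gene replicates when at least one patient of an independent
cohort of unrelated index patients carries *any* rare LoF variant on the
**same transcript**, with both the discovery and the replication variant
outside the transcript's last exon (truncating variants in the final exon
often escape nonsense-mediated decay). Unknown exon rank is treated as
last-exon, i.e. conservatively excluded from replication. We apply the
last-exon rule only at the replication stage — the workflow we follow
states it when describing cross-cohort matching — and expose
`lastExonAtDiscovery = TRUE` for the stricter reading.

### Variant-based strategies

The variant-based arm admits a wider consequence universe (LoF plus
in-frame indels, missense, stop-loss) and tags variants by three routes:
CGV (gene symbol in a user-supplied cancer-gene list; symbols matched after
uppercasing), SVGU (identical variant in unrelated patients, or distinct
admitted variants of the same gene and transcript in unrelated patients;
"unrelated" means different family **and** $\phi < 0.0442$), and FSV
(MAF strictly < 0.01% in both panels, carriers confined to a single
family). FSV and SVGU-identical are mutually exclusive by construction and
this is asserted on every run. Tagged variants are then filtered: MAF ≤
0.1% in both panels; LoF or called damaging by ≥ *k* of the seven in-silico
predictor tools (default *k* = 1, because the workflow retained a variant
damaging in only one of seven tools); present in **all** affected sequenced
members of each carrier family (families with one affected sequenced
member pass trivially); and QC-clean counted carriers. SVGU's
distinct-variant route requires same-transcript mapping by default — the
consistent reading alongside the gene-based rule — with a flag to relax it.

### Association

Case–control comparisons use allele-count 2×2 tables built as
`a = alt, b = total − alt` per group: the published odds ratios reproduce
only under alt-inclusive totals, so that convention is adopted throughout.
The two-sided Fisher p-value is the sum of hypergeometric probabilities of
all tables with the observed margins whose point probability is at most
that of the observed table, with ties compared at relative tolerance 1e-7
(common exact-test practice). The point odds ratio is the sample
cross-product $ad/bc$ — it matches all six published values at two
decimals — and the CI is either Woolf's log-normal interval or the
exact-conditional interval from inverting the noncentral hypergeometric
likelihood (default: exact-conditional, which is consistent with the
published intervals even for sparse tables). Zero-cell tables yield a
degenerate OR (0 or ∞) with the CI omitted and flagged; no continuity
correction. No multiple-testing correction is applied by default (the
reference analysis reports nominal p < 0.05); `p_adjust` enables
Bonferroni/BH. Gene-level burden collapsing sums qualifying variants (LoF,
not last-exon, MAF ≤ 0.1% in both panels) into one cumulative table before
testing; a gene with no qualifying variants returns an explicit
empty-burden result rather than a silent p = 1.

## The genotype-QC surrogate

The original workflow inspected carrier calls visually in a genome browser.
famrare replaces that with a deterministic rule: a heterozygous carrier
call passes with depth ≥ 10, genotype quality ≥ 20 and alt-allele balance
in [0.25, 0.75]; a homozygous-alt call needs balance ≥ 0.9 (we apply the
depth and quality floors to homozygous calls as well — a low-depth
homozygote is exactly what visual inspection would reject). Missing calls
("./.") fail and are also excluded from carrier counts and kinship.

## What the simulator emulates

`simulateCohort()` generates the complete study input deterministically
from a seed: identical configuration and seed give byte-identical files.

* **Pedigrees.** Family sizes 2–5 with fixed shapes (mother–daughter pairs,
  trios, two-sister sibships, a three-generation shape), allocated
  deterministically to match the configured cohort scale; defaults are 17
  families / 52 individuals, the scale of the discovery study emulated.
  Children are female with probability 0.9 — male breast cancer is allowed,
  as in the cohort the package models.
* **Genotypes.** Founder genotypes are binomial draws at the configured MAF
  strata; non-founders receive one uniformly chosen allele per parent per
  site (gene dropping). Sites are independent: the pipeline never uses
  linkage, and independence makes the analytic checks (founder-frequency
  calibration, kinship expectations) exact. The default strata mix private
  (0), ultra-rare (0.005%), rare (0.05%), borderline (0.2%), low-frequency
  (1%) and common (25%) variants; the common stratum represents the
  polymorphic backbone of a real exome and is what makes kinship estimation
  informative at a few hundred simulated sites. Panel frequencies equal the
  founder frequency; stratum-0 variants are private — one founder carrier,
  absent from both panels.
* **Planted risk variants.** Each planted variant is seeded as a founder
  mother carrier with a forced transmission to her first child — still one
  of the mother's two alleles, hence Mendelian-consistent — guaranteeing
  the informative two-affected-carrier configuration (the mother–daughter
  and sister-pair patterns of the families the package emulates). Affection
  is then penetrance-driven for carriers, with a sporadic (phenocopy) rate
  of 0.05 for everyone else to reproduce intra-family etiological
  heterogeneity (affected relatives who do not carry the family variant).
  Families with no affected member are ascertained through a forced
  affected child — chosen independently of the forced transmission — since
  every family in such a study enters through an affected index patient.
* **Call metrics.** Depth is Poisson (mean 80), alt depth binomial around
  the expected allele fraction, GQ near 99; `qc_noise_rate` degrades a
  fraction of calls to exercise the QC surrogate and
  `genotype_missing_rate` introduces "./." calls. Defaults are 0: the
  generator emulates post-QC-grade calls. `n_sample_swaps` replaces a
  child's genotypes with unrelated draws to model a sample mix-up.
* **Replication cohorts.** `simulateReplicationCohort()` draws unrelated
  singleton index patients over the same variant universe, optionally
  planting a *distinct* LoF in a candidate gene (same transcript by
  default; last-exon or other-transcript placements are available precisely
  to test the replication rules) or an identical discovery variant for
  presence lookups.

What the simulator does **not** model: linkage disequilibrium, sequencing
error at the read level, population structure or batch effects, and
realistic gene/transcript architecture (genes and exon counts are
synthetic labels). Passing tests therefore demonstrate that the filtering,
kinship and association logic is correct under the stated statistical
assumptions — not that the pipeline is robust to artefacts those phenomena
introduce in real exomes.

## Benchmark configurations and problem sizes

The test suite and the acceptance script use deliberately scaled problem
sizes: exhaustive Fisher verification over all 46,375 tables with total
N ≤ 30 against a brute-force enumeration oracle; kinship calibration on 12
four-member families (48 samples, so every family contributes parent–
offspring and full-sib pairs) at 10,000 independent sites with founder MAF
0.3 and one planted sample swap; planted-truth recovery at the study scale
of 17 families / 52 individuals with a 51-singleton replication cohort; and
threshold-monotonicity sweeps across ≥ 40 (script) / 100 (tests) seeded
six-family cohorts.

In the recovery benchmark the background strata are restricted to
≥ 0.2% (plus common) so that every background variant fails the ≤ 0.1%
rarity filter by construction and the planted set is the exact ground
truth; this mirrors the null-simulation property (common-only background ⇒
empty shortlist) and makes the exact-set assertion deterministic. Rare and
private background strata are exercised in the monotonicity and property
tests, where exact-set recovery is not the claim being tested.

## Numerical and design choices

* Absent-from-panel vs MAF-0-in-panel are stored differently (`NA` vs 0);
  the zero treatment happens inside the filters and is logged there.
* "≤ 0.1%" thresholds are inclusive; FSV's "< 0.01%" is strict, following
  the inequality forms of the workflow being reimplemented.
* Fisher tie comparison uses relative tolerance 1e-7; the implementation
  (direct hypergeometric summation) is verified exactly against a
  from-first-principles enumeration oracle and against
  `stats::fisher.test()`.
* Kinship with a zero denominator is an explicit error for a single pair
  and `NA` (with a warning) inside the all-pairs matrix — never a silent 0.
* Unaffected carriers never count toward `n_carrier_patients`; they are
  reported in the `carriers_in_unaffected` column, so a variant carried by
  a cancer-free relative but absent from an affected one remains visible
  without qualifying.
* Candidate tables are sorted by (gene, chrom, pos) and all report columns
  are fixed, so identical inputs give byte-identical reports.
* The index-patient flag is carried as an extra pedigree column (it cannot
  be derived from genotypes or affection), alongside the two phenotype
  extension columns (affection category, age at diagnosis); sequencing
  status is derived from VCF membership rather than stored.

## Known limitations

* The predictor panel is synthetic metadata: verdicts are read from INFO
  keys, never computed, and only the damaging count enters the filters.
* SKAT-style variance-component burden testing and principal-component
  population-structure analysis are out of scope; the burden test here is
  the cumulative-frequency collapsed Fisher comparison.
* The replication rule requires exact transcript-ID equality; transcript
  IDs are opaque strings, so cross-annotation-version matching is the
  caller's responsibility.
* With very small cohorts the SVGU strategy can be starved of unrelated
  pairs (kinship undefined on pairs without shared heterozygous sites);
  such pairs are treated as not demonstrably unrelated.
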