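---
title: "Methods: sex-stratified exome-wide association screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sex-stratified exome-wide association screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexdiffwes)
```

## Scientific problem

Depressive disorder is roughly twice as prevalent in women as in men, and
part of that asymmetry appears to be genetic: variants and genetic burden
may act differently in the two sexes. `sexdiffwes` implements a complete
analysis framework for testing sex differences in the genetic architecture
of a phenotype from whole-exome sequencing (WES) genotypes, organized
around two complementary questions:

1. **Qualitative** — are there individual variants whose allele
   frequencies differ between affected females and affected males, while
   showing no such difference in unaffected controls?
2. **Quantitative** — do affected males carry a systematically higher
   burden of damaging variation than affected females, consistent with a
   higher genetic threshold for developing the phenotype in males?

The package also provides haplotype-level follow-up of screen hits (EM
phase estimation, linkage disequilibrium, homozygous-carrier
classification), polygenic risk scoring from external summary statistics,
and clinical severity comparisons between carriers and non-carriers.

Because genotype-level data from clinical cohorts generally cannot be
redistributed, the package ships a fully parameterized synthetic cohort
generator whose defaults emulate the study design that motivated it: 1000
cases (707 female, 293 male), a small injury-cohort control set (72
subjects, 26.4% female) and a public reference-panel control set (207
subjects, 50.7% female).

## The qualitative screen

For every screened variant (missense, stop gain, stop lost, or start
lost), `run_screen()` compares genotype counts between female and male
cases with a battery of tests built from the `(ref, het, hom)` counts per
sex:

- **allele model** — Fisher's exact test on the 2×2 table of alternative
  vs reference allele counts (denominators are twice the non-missing
  subjects);
- **dominant model** — carriers (het + hom) vs non-carriers;
- **recessive model** — alternative homozygotes vs everyone else;
- **trend test** — a Cochran–Armitage test with additive scores
  `(0, 1, 2)` across the three genotype classes.

Fisher p-values are two-sided by the probability-mass rule: the sum of
hypergeometric probabilities, over all tables with the observed margins,
that do not exceed the probability of the observed table. The reported
odds ratio is the *sample* odds ratio `ad/bc` (reported as `Inf` when
`bc = 0` with `ad > 0`, and 1 when both products vanish), with the exact
conditional confidence interval alongside.

### The empirical threshold

Rather than a Bonferroni cut-off, the screen derives its significance
threshold from the data: the same female-vs-male allele test is run in
each control cohort, where no true sex difference in allele frequency is
expected, and the *minimum* control p-value across all variants and
control cohorts becomes the threshold. A variant is a **hit** when

- its case allele-test p-value falls below that threshold, and
- its allele-test p-value is at least 0.05 in *every* control cohort
  (non-replication of the difference in controls).

Since Fisher p-values are discrete and super-uniform, this threshold is a
conservative empirical bound on the noise level of the control data. Its
numeric value depends entirely on the genotypes at hand — with the
original study cohort it was on the order of 5 × 10⁻⁵; with a synthetic
cohort it is whatever the simulated controls produce. Tests therefore
validate the *construction* (it is the minimum of the control p-values;
planting the same sex contrast into the controls removes the hit), not
any particular value.

### Covariate adjustment

Demographic differences between the sexes can confound a genotype–sex
association. `table1_report()` compares every clinical/demographic
variable between the sexes (Welch t for numeric variables, Yates-corrected
χ² with a Fisher fallback for binary ones) and shortlists those with
p < 0.1. Screen hits can then be re-tested with
`stratified_tables()` + `cmh_test()` (Cochran–Mantel–Haenszel across
covariate strata) or `logistic_adjusted()` (logistic regression of carrier
status on sex plus covariates, with separation detection).

## The quantitative burden analysis

`classify_variants()` places every variant on three annotation axes:

- **Rarity**: reference-panel allele frequency below 0.1% (variants absent
  from the panel count as rare);
- **Functionality**: missense, splice site, frameshift, stop gained/lost/
  retained, start lost, or in-frame indel; the subset excluding missense
  and in-frame indels is the **protein-truncating (PTV)** class;
- **Deleteriousness**: SIFT ≤ 0.05 *or* CADD ≥ 15 (variants without
  scores count as benign).

Crossing the axes yields eight category combinations (functional,
rare functional, functional deleterious, rare functional deleterious, and
the same four with PTV in place of functional). `compute_burden()` counts,
per subject and combination, carried variants and genes with at least one
carried variant, over all genes and over a candidate gene list — a
32-cell grid (8 combinations × 2 scopes × 2 aggregation levels).

Each cell is compared between the sexes with a Wilcoxon rank-sum test
(mid-ranks under ties; exhaustive enumeration when the combined sample is
small, tie-corrected normal approximation with continuity correction
otherwise). The headline contrast — male excess of deleterious PTVs — is
additionally tested against a **sex-label permutation null**:
`permutation_test()` recomputes the male-vs-female rank-sum statistic `W`
under `T` random relabelings that preserve the observed group sizes and
reports `p = C/T`, where `C` counts permuted statistics at least as large
as the observed one (one-sided, male-excess direction by default). When
the number of distinct male/female splits is small the full set is
enumerated instead, making the p-value exact. A sampled count of zero is
reported as `p = 0` annotated `"< 1/T"` rather than an unqualified zero.

## Haplotype follow-up

Screen hits that cluster within a region are phased jointly with
`em_haplotype_freqs()`, an expectation–maximization estimator of
multilocus haplotype frequencies under Hardy–Weinberg diplotype formation
(this replaces external phasing software; at the ≤ 8 loci the package
supports, EM over the 2^(h−1) compatible diplotypes of an h-fold
heterozygote is exact and fast). Multiple jittered restarts guard against
local maxima, and the log-likelihood trace is checked for monotonicity.
`pairwise_ld()` reports D, D′ and r² between locus pairs, and
`homozygous_carriers()` classifies subjects whose posterior probability of
carrying two copies of a target haplotype exceeds 0.9 — these subjects
feed the clinical severity comparison.

## Polygenic risk scores

`ld_clump()` greedily thins external summary statistics (MAF > 0.01,
ascending p, rejecting variants with r² > 0.1 to an already-kept variant
within 250 kb), and `compute_prs()` scores each subject at eight p-value
thresholds (10⁻⁴ … 1) as the dosage-weighted sum of effect sizes. Effect
alleles are reconciled against the VCF alleles (sign flip when the effect
allele is the reference allele), strand-ambiguous A/T and C/G variants
are dropped, and missing dosages contribute the variant's mean dosage.
`compare_prs_by_sex()` then tests male vs female scores at each threshold.

## Clinical comparisons

`carrier_severity_comparison()` compares seven severity endpoints between
homozygous carriers and everyone else — HAMD, HADS-anxiety and age of
onset by Wilcoxon rank-sum; BPRS suicide item ≥ 4, suicide attempt,
family history and recurrence by Yates χ² (Fisher's exact test when any
expected cell is below 5) — in all subjects and within each sex, with a
Bonferroni threshold of 0.05/7. Populations with no carriers produce rows
explicitly marked non-computable rather than being dropped.

## The synthetic generator

`sim_config()` + `simulate_cohort()` generate case and control cohorts
with known ground truth, recorded in the returned `truth` element:

- a **planted sex-differential variant** (default female AF 0.085 vs male
  AF 0.034 in cases; sex-balanced in controls) for the screen;
- **30 deleterious PTVs** at allele frequency 0.01 with a 1.5× male
  multiplier in cases only, producing a male burden excess;
- **LD blocks** sampled as haplotype pairs (a fully linked 2-locus block
  and a 5-locus block with an 18% all-alternative haplotype, giving a few
  dozen homozygous carriers at study scale);
- **clinical effects** in homozygous carriers (+2.7 HAMD, odds ratio 3.2
  for the dichotomized suicide item);
- eight crafted coverage variants guaranteeing every annotation
  combination is non-empty.

All draws flow from a single seed, so identical configurations give
byte-identical cohorts and pipeline outputs. Generator parameters were
chosen once, from the design being emulated and power calculations, not
adjusted against test outcomes.

### Fidelity and limits

The generator reproduces the *structure* of the motivating study — cohort
sizes and sex ratios, annotation axes, an LD-block architecture and
effect sizes on the published scale — but not its data. Genotypes are
drawn independently per variant under Hardy–Weinberg equilibrium (no
population structure, relatedness, or genotyping error), clinical scores
are Gaussian/logistic idealizations, and external summary statistics are
simulated null effects plus planted signals. Consequently the published
study-level numbers (the empirical threshold value, specific Wilcoxon W
statistics and p-values, the count of male-enriched burden cells) are not
reproducible without the original genotypes; the test suite states this
explicitly and instead verifies the machinery against enumeration
oracles, calibration experiments and parameter-recovery runs on synthetic
data.

## Numerical and design choices

- **Two-sided Fisher p** by probability mass (the R convention), matching
  the published single-variant values exactly.
- **Continuity correction on** for all 2×2 χ² tests; this reproduces the
  published cohort-table statistics exactly.
- **Welch, not pooled, t** for numeric sex comparisons; from rounded
  printed summaries it reproduces printed t statistics within ±0.05.
- **Permutation counting uses ≥** (ties count toward `C`), the
  conservative convention, with an epsilon guard against floating-point
  rank-sum jitter.
- **Splice-region variants** are excluded from the functional set by
  default; `include_splice_region = TRUE` widens the set where an
  annotation source folds splice-region into splice-site. This toggle
  exists because consequence vocabularies differ between annotators.
- **`splice_site` is a PTV**, `splice_region` is not, mirroring common
  loss-of-function definitions.
- **Strict `p < τ`** in risk scoring: a variant with p exactly at the
  threshold is excluded.
- **Problem sizes** (≤ 8 haplotype loci, exhaustive permutation
  enumeration up to 20 000 splits, exact rank-sum up to n = 12) are
  package choices balancing exactness against runtime on one CPU.

## A minimal run

```{r pipeline, eval = FALSE}
cfg <- pipeline_config(seed = 1, sim = sim_config(n_background = 40,
                                                  seed = 1))
res <- run_pipeline(cfg, out_dir = "results")
res$screen$threshold          # empirical threshold from the controls
res$screen$hits               # qualitative hits
glance(res$permutation$variant)  # male deleterious-PTV excess
autoplot(res$relative_burden)    # 32-cell burden grid
```
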