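---
title: "Methods: portal venous blood cfDNA 5hmC analysis"
author: "portal5hmc authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: portal venous blood cfDNA 5hmC analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Background

5-hydroxymethylcytosine (5hmC) is an oxidized DNA methylation mark that can
be read out genome-wide from nanogram quantities of circulating cell-free DNA
(cfDNA) by selective chemical labeling (5hmC-Seal). Because the portal vein
drains the colorectum directly into the liver, portal venous blood cfDNA is
enriched for tumour-derived fragments in colorectal cancer, making it an
attractive liquid-biopsy compartment for anticipating liver metastasis.

The analytical problem this package addresses is the downstream half of such
a study: starting from per-sample hydroxymethylated regions (hMRs; peaks) and
a regions-by-samples read-count matrix, build the analysis region set, call
differentially hydroxymethylated regions (DhMRs) between patient groups
(primary cancer, PC; metachronous liver metastasis, MLM; synchronous liver
metastasis, SLM), distil a small marker panel by stability-consensus
recursive feature elimination, train and validate a penalized logistic
classifier, and profile the data descriptively (metagene coverage,
genomic-feature annotation, PCA, correlation, Kaplan-Meier stratification).
Upstream sequencing, alignment and peak calling are out of scope: peaks and
counts are inputs.

Real cohorts of this kind are controlled-access human data, so the package
ships a seeded synthetic-cohort generator with planted ground truth. Every
statistical claim made by the test suite is a property of the method checked
against that planted truth or against an independent oracle, not a
reproduction of any particular cohort's numbers.

## Data containers

- `HmcExperiment` extends `RangedSummarizedExperiment`: a `counts` assay of
  non-negative integers, hMR coordinates as row ranges, the sample table as
  column data, and per-sample library sizes (total mapped reads — allowed to
  exceed the in-region column sums) in `colData()$library_size`.
- Gene models are a `GRanges` of gene spans with an `exons` `IRangesList`
  column; BED12 I/O round-trips through `readGeneModels()` /
  `writeGeneModels()`. All coordinates follow the Bioconductor convention
  (1-based, closed) internally; BED/bedGraph conversion happens at the file
  boundary.
- `MarkerPanel` and `HmcClassifier` hold the selection and model artifacts,
  including per-round selection frequencies and the frozen training
  standardization.

## Region set construction

Per-sample peak lists are merged with a 0-gap rule (overlapping or abutting
intervals join — the common `bedtools merge` default), and each merged region
records its support: the number of samples contributing at least one
overlapping peak. The retention filter keeps a region iff

- support **strictly exceeds** 10 samples,
- width is **strictly below** 1000 bp, and
- it overlaps a user-supplied blacklist by zero bp.

Both inequalities are deliberately strict; the thresholds are arguments of
`filterRegions()`. No blacklist is bundled (it is a versioned external
resource); any BED can be supplied.

Annotation (`annotateRegions()`) uses a fixed priority ladder for
reproducibility: promoter > exon > intron > downstream (up to 3 kb past the
TTS) > intergenic. The promoter is the TSS ± 2 kb window and wins on *any*
overlap; the other labels are decided by the region midpoint. The nearest
gene minimizes |midpoint − TSS|, ties broken by lexicographic gene name, and
`tss_distance` is signed positive in the direction of transcription.
5'/3'-UTR sub-annotations are collapsed into "exon": annotation tools differ
in their precedence rules across versions, and a fixed documented ladder is
preferable to matching any one of them.

## Differential analysis

The DhMR test is a per-region negative-binomial Wald test, written in-house:

- **Normalization**: median-of-ratios size factors (`medianOfRatios()`),
  computed over regions with nonzero counts in every sample.
- **Dispersion**: a gene-wise method-of-moments estimate on normalized
  counts with group means removed, `alpha = max((v - m)/m^2, 1e-8)` capped
  at 10. There is deliberately no empirical-Bayes shrinkage and no
  fold-change shrinkage: results will differ from shrinkage-based tools in
  small samples. The estimator is validated by simulation (type-I error and
  parameter recovery), not by output-matching another package.
- **Model**: NB GLM with log link, design intercept + group indicator,
  offsets `log(s_j)`, fixed dispersion. The two-group design is saturated,
  so the fit factorises into two one-parameter problems solved by Fisher
  scoring, vectorised across all regions (|step| < 1e-10, at most 100
  iterations, steps clamped to ±5 on the log scale). Standard errors come
  from the observed Fisher information; p-values are two-sided normal.
  All-zero regions are flagged with p = 1 and log2FC = 0; regions with an
  all-zero *group* are flagged `"zero-group"` (their estimates sit at a
  clamped boundary and should not be interpreted).
- **Calling**: up = {log2FC ≥ t, p < 0.01}, down = {log2FC ≤ −t, p < 0.01},
  with the fold-change bound inclusive and the p bound strict. Both presets
  in use, t = 0.35 and t = 0.5, are plain arguments; raw p-values are
  thresholded by design, with a BH-adjusted
  column provided for users who prefer it.

The group given first (or via `reference=`) is the fold-change denominator.
Note that `as.factor()` orders levels alphabetically — for a PC-vs-MLM
contrast pass `reference = "PC"` (or a factor with explicit levels), since
alphabetical order would invert the sign.

Auxiliary tests (`welchT()`, `wilcoxonRankSum()`) wrap the standard
`stats::t.test()` / `stats::wilcox.test()` implementations; the rank-sum
statistic U counts strict wins plus half-ties and uses exact enumeration for
small tie-free samples, the tie-corrected normal approximation otherwise.

## Marker selection and classification

- **Split**: stratified 2:1 training:validation, per-class allocation
  `round(2/3 * n)` (round-half-even). A 70 PC + 32 MLM cohort therefore
  splits 47 + 21 for training; published cohorts of that shape sometimes
  report 44 + 22, which is not reproducible from a 2:1 ratio under any
  standard rounding — the rule, not any specific realization, is the
  contract here.
- **Features**: `log2(normalized count + 1)`, z-scored with training-cohort
  statistics that are frozen into the model; validation data are transformed,
  never re-estimated. Validation size factors are computed against the
  training-derived reference in the pipeline, so no validation statistic
  leaks into training artifacts.
- **Estimator**: L2-penalized logistic regression minimizing
  `sum_i w_i * loss + (lambda/2) ||beta||^2` with an unpenalized intercept
  and balanced class weights `w_i = n/(2 n_class)`. The solver is a damped
  Newton iteration (C++/RcppArmadillo; gradient inf-norm < 1e-8), chosen
  because stability selection performs on the order of 10^5 fits; tests
  verify it against independent numerical minimization of the same
  objective. Lambda is chosen by stratified 2-fold cross-validated accuracy
  over a small grid (10^-2 … 10^2 by default), ties resolved toward the
  stronger penalty.
- **RFE**: at each size the model is fit (lambda re-chosen by internal CV),
  the `ceiling(0.1 * remaining)` features with the smallest |weight| are
  dropped (ties eliminated in lexicographic id order), and the CV accuracy
  is recorded; the selected set is the smallest size whose accuracy is
  within 1e-12 of the maximum. The internal CV fold assignment is drawn once
  per RFE run and reused at every size.
- **Stability consensus**: five rounds; each round draws one stratified 4/5
  subset of the training cohort and repeats RFE 100 times under derived
  seeds (the repeats differ through their internal CV folds). A marker is
  "observed" in a round iff selected in ≥ 50% of that round's repeats; the
  panel keeps markers observed in ≥ 3 of 5 rounds. Both thresholds are
  arguments. An empty panel is a legitimate result and is reported with its
  frequency matrix.
- **Final model**: refit on the full training cohort restricted to the
  panel, lambda again by internal CV; evaluation reports ROC/AUC (trapezoid
  over tie-grouped thresholds — exactly the rank-sum U/(n+ n−)), a 0.5
  probability-threshold confusion matrix, and per-marker AUCs folded to the
  class-1-high orientation with an explicit sign flag.

A property worth knowing: the selected-size rule is parsimony-seeking. When
individual markers are strong (a standardized group separation around 2,
as planted effects of |log2FC| ≥ 1 produce at realistic dispersions),
empirical CV accuracy on a ~50-sample training subset saturates at panel
sizes of 1–4, so the consensus panel is a *minimal predictive subset* of the
truly differential regions, not an exhaustive list of them. Simulations that
expect the panel to recover most of a redundant planted marker set will find
this ceiling; the differential stage, not the panel, is the tool for
enumerating affected regions.

## Metagene profiles

`metageneProfile()` rescales each gene body to 100 bins (mean per-bp
coverage per bin, so unequal gene lengths are comparable), adds 2 kb flanks
in 20 fixed-width bins, reverses minus-strand genes so bin 1 is 5'-most,
averages across genes and converts to RPM. Genes shorter than the body bin
count are skipped with a warning and counted. The bin value is a mean, not a
sum — the profile of a sum of tracks is the sum of profiles, and flipping a
gene's strand while mirroring the track leaves its contribution unchanged;
both properties are tested. Per-sample RPM normalization followed by group
averaging is assumed where groups are compared.

## Survival

`dichotomize()` splits at the median (strictly above = "high"; the quantile
is pluggable) — the natural default when no published cutoff exists.
`kmLogrank()` wraps the product-limit estimator and the unstratified
two-sample log-rank test from the `survival` package.

## The synthetic cohort generator

`simulateCohort()` emulates the *statistical structure* of a
portal-venous-blood cohort, with one RNG stream per stage derived from the
master seed by fixed offsets (so enlarging one stage does not perturb
another):

- **Genome**: a few synthetic chromosomes with non-overlapping stranded
  multi-exon genes; candidate hMRs are placed disjointly so that their
  planted feature label (promoter/exon/intron/intergenic, intron-heavy by
  default as observed for cfDNA hMRs) agrees with the package's own
  annotation rules.
- **Counts**: `NB(mu = q_i * s_j * 2^(beta_i * x_j), alpha_i)` with
  log-normal baseline `q_i` (median ~60 reads), log-normal library factor
  `s_j` (sd 0.25 on the log scale), dispersion uniform on [0.05, 0.3], and a
  planted effect `beta_i` (random sign, |log2FC| in [0.5, 2]) for 5% of
  regions between the PC-like and MLM-like groups; the third (SLM-like)
  group reuses PC-like parameters. Library size is the realized column
  total, matching how RPM/FPKM are computed downstream. Default cohort
  sizes are 70/32/31. No published generative parameters exist for real
  cfDNA counts; these defaults were chosen once for testability and
  realism, and the moment structure (mean q, variance q + alpha q^2) is
  verified by the suite.
- **Peaks**: a sample emits a peak for a region iff its count reaches the
  presence threshold (5 reads by default) — enough structure to exercise
  the merge/filter stage.
- **Coverage**: flat background, elevated gene bodies, and a multiplicative
  dip in a ±1 kb window around each TSS, mirroring the observed gene-body
  5hmC enrichment with TSS depletion.
- **Survival**: exponential event times with hazard
  `h0 * HR^{I(level > median)}` driven by the first planted marker's RPM
  level, independent exponential censoring; EFS uses a 1.5× baseline hazard
  so events precede deaths.

What the generator does **not** emulate: batch effects, GC/mappability
bias, fragment-level structure, correlated regions, or non-proportional
hazards. Passing tests therefore demonstrate correctness of the machinery
under a clean NB world, not robustness to real-data artifacts.

## Numerical choices and degenerate inputs

- Fisher scoring: tolerance 1e-10 on the log-mean step, max 100 iterations,
  steps clamped to ±5; group means floored at 1e-8 for all-zero groups.
- Dispersion floor 1e-8 and cap 10.
- Newton logistic solver: gradient inf-norm < 1e-8, max 100 iterations,
  backtracking line search; with lambda > 0 the objective is strictly
  convex, so separation is harmless.
- Tie-breaks are lexicographic on identifiers everywhere (RFE elimination,
  nearest gene, top-variance rows) so runs are exactly reproducible.
- Median-of-ratios is undefined when no region is positive in all samples;
  the error says so rather than silently falling back.
- `dichotomize()` refuses constant input; `roc()` requires both classes.

## Problem sizes used by the test suite

The suite validates calibration at 2×10^4 null regions (20+20 samples),
fold-change recovery at 2000 regions (50/group), dispersion recovery at
2000 regions (200/group), log-rank level over 1000 replicates of n = 200,
and stability selection over 50 replicates of a 500-region, 44+22-sample
cohort; the end-to-end pipeline runs twice at the default 600-region,
133-sample scale to verify byte-identical outputs. These sizes were chosen
so each property is measured with useful precision while the whole suite
stays comfortably runnable on a laptop.

## Known limitations

- The Wald test with method-of-moments dispersion is anti-conservative for
  very low-count regions at small n; the suite pins the realized type-I
  error at p < 0.01 to [0.005, 0.02] under the default generator.
- Only two-group contrasts and single-factor designs are supported; no
  Cook's-distance outlier handling or independent filtering.
- The stability panel is a minimal predictive subset (see above), so
  panel size is not an estimate of the number of affected regions.
- Raw p-value thresholding is the primary calling rule by design; the BH
  column is advisory.
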