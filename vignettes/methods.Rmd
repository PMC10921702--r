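---
title: "Subtractive organellar proteomics: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subtractive organellar proteomics: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(organsurf)
```

# The analysis problem

Cell-surface proteins are the most accessible drug and antibody targets, but
shotgun proteomics of whole lysates under-samples them. A subtractive
organellar design addresses this: the plasma membrane (PM) is captured with
cationic colloidal silica beads, the remaining compartments (cytosol,
mitochondria, microsomes, nuclei) are isolated by differential
ultracentrifugation, and every fraction is profiled by label-free LC-MS in
replicate. A protein is then called PM-resident not because it is abundant
in the PM capture, but because it is *differentially* abundant there
relative to **every** co-fractionating compartment — the subtraction
removes the contaminants that co-purify with any single enrichment.

`organsurf` implements this workflow end to end: ingestion of
MaxQuant-style protein-group tables, fraction-level quality control,
per-cell-line subtractive testing, a candidate-mining funnel, and a
prognostic evaluation of a chosen marker in a patient cohort. A
synthetic-data generator with planted ground truth makes every stage
testable without access to raw mass-spectrometry or patient data.

# Ingestion model

The quantitative unit is iBAQ intensity per protein group. Processing is a
fixed order — **filter, log2, median-normalize, impute** — because each
step's statistics must not see the artifacts of the later ones:

* *Identification filtering.* Reverse-decoy and potential-contaminant rows
  are dropped, as are proteins identified by fewer than two unique
  peptides. Zero or blank intensities are treated as missing (the MaxQuant
  convention for absent quantification). The protein identifier is the
  first entry of "Majority protein IDs".
* *Median normalization* applies a per-sample shift on the log2 scale so
  every sample's observed median equals the global median of per-sample
  observed medians. The target keeps the intensity scale intact, so imputed
  values near 1 log2 unit remain "low" relative to the data. Statistics are
  computed on observed values only.
* *Low-value imputation* replaces each missing entry with an independent
  uniform draw on [1.0, 1.2] log2 units, reflecting the assumption that
  dropout is missing-not-at-random (MNAR): intensities are absent mostly
  because they fell below detection. Draws are seeded, and the missingness
  mask is retained so downstream consumers can always distinguish observed
  from imputed values. Whether the original analyses drew per-cell values
  or used a constant is not knowable from the processing description, so
  both are offered (`method = "uniform"` (default) or `"constant"`);
  uniform i.i.d. draws are the simplest distribution consistent with an
  interval statement.

# The subtractive test

Within each cell line, PM replicates are compared against each other
fraction's replicates with Welch's unequal-variance *t*-test
(Satterthwaite degrees of freedom). P-values are Benjamini-Hochberg
adjusted **within each (cell line, fraction pair) family** — the analysis
is explicitly per cell line, and each PM-vs-fraction comparison is its own
discovery problem; a pooled per-cell-line family is available as an option
(`bh_family`). A protein is PM-called in a cell line when `q < 0.05` *and*
the signed log2 fold change toward PM exceeds 1 against **every** non-PM
fraction. The signed (rather than absolute) fold-change requirement
encodes the direction of interest; the all-fractions intersection is what
makes the design subtractive.

Both primitives (`welch_t`, `bh_adjust`) are implemented in the package
and cross-checked in the test suite against independent references
(`stats::t.test`, `stats::p.adjust`) and against the brute-force step-up
definition $q_{(i)} = \min_{j \ge i} p_{(j)} \, n / j$.

With two zero-variance groups of equal means the Welch p-value is defined
as 1 (no evidence); a cell line missing a required fraction is skipped
with a warning rather than failing the run.

# Quality control

Sample-level structure is assessed by PCA of the protein-centered matrix;
in a well-behaved experiment samples separate by organelle fraction, not
by cell line, which the package quantifies by comparing mean silhouette
widths of the two groupings in PC space. Protein-level structure is
assessed by Ward (`ward.D2`) hierarchical clustering of Euclidean
distances between per-protein z-scored profiles, cut at *k* = 4 — the
four major compartment classes such fractionations resolve. Linkage and
metric are the standard choices for z-scored abundance heatmaps.

Two numerical choices matter here:

* Constant rows get z = 0 rather than NaN, keeping every detected protein
  in the analysis.
* For the distance computation, z-scores are winsorized at ±3
  (`z_clip`). Low-value imputation leaves isolated spikes of roughly −7 z
  in otherwise clean profiles; un-clipped, those spikes dominate Euclidean
  distances and collect every protein with any dropout into a single
  diffuse cluster regardless of its compartment. Clipping is the same
  saturation a heatmap color scale applies, and results are insensitive to
  the exact bound. The reported `zmatrix` is unclipped.

# The candidate-mining funnel

PM calls feed a four-stage funnel, with every threshold inclusive as
stated: surface-prediction support (GenieScore ≥ 20 and Surface Prediction
Consensus ≥ 3, consumed as annotations — the scoring tool is external),
consistency (PM-called in ≥ 2 cell lines), tumor exclusivity (detected in
≤ 5 of the cancer cell-line panel), and antibody availability. Survivors
are prioritized by normal-tissue expression across four panels: the
proportion of tissues not detected by IHC (ordinal level 0 of 0-3, the
Not-detected/Low/Medium/High convention), medians of two protein-abundance
panels, and the median of an RNA panel. Each panel contributes an
average-tie rank (1 = most tumor-restricted); candidates are ordered by
the rank sum with lexicographic tie-breaking for determinism. A candidate
absent from a continuous panel scores as undetected (best rank) by
default, consistent with favoring absent normal-tissue expression;
`missing = "worst"` and `"exclude"` are available. Panels are used with
all tissues provided; no tissue subset is selected.

# Prognostic evaluation

Marker positivity (percent stained cells) is dichotomized at the upper
tertile: patients strictly above the linear-interpolation (type 7) 2/3
quantile form the "upper" group. The convention is fixed and documented
because tertile membership at small *n* depends on it; labels depend only
on the order statistics. Endpoints (progression-free interval and overall
survival) are compared by Kaplan-Meier curves with a two-sided log-rank
test, and by Cox proportional-hazards fits — univariable (tertile
indicator) and multivariable (adding extent-of-resection and radiotherapy
covariates, accepted as binary or ordinal). Ties use the Efron
approximation, a common default with good small-sample behavior.
Non-convergence or separation is raised as an error, never silently
returned. Site differences in positivity use the two-sided Wilcoxon
rank-sum test. Because the underlying patient-level data of any real
cohort are private, this stage is validated by parameter recovery on
synthetic cohorts rather than by reproducing published hazard ratios.

# What the synthetic generator emulates

`sim_config()` defaults define the study conditions: 5,000 proteins across
4 cell lines × 5 fractions (one PM) × 3 replicates, 50 planted PM
residents at +3 log2 PM enrichment, replicate noise SD 0.5. Around that
stated design, the generator's own modeling choices are:

* **Baseline abundance** per protein ~ N(25, 3) log2-iBAQ — the dynamic
  range typical of deep cell-line proteomes.
* **Compartment structure.** Every background protein has a home fraction
  drawn from the four non-PM compartments and is enriched there by
  `delta_home` = 5 (32-fold); organelle residents in fractionation data
  are routinely enriched beyond the PM-capture effect. Effects are zero
  elsewhere; an optional heterogeneous carryover term (`tau_contam`,
  default 0) can blur this. The planted PM residents are the *only*
  PM-homed proteins, so false PM calls are structurally blocked: for any
  background protein, the comparison against its own home fraction shows a
  large deficit and breaks the all-fractions intersection.
* **Nuisance structure.** Per-(protein, cell line) effects SD 0.3 and
  per-sample loading shifts SD 0.25, the latter removed by median
  normalization.
* **MNAR dropout** via a logistic link on the true log2 abundance
  (midpoint 17, slope 0.9), confining missingness to a narrow
  low-abundance band (a few percent overall), as with iBAQ quantification
  when match-between-runs is disabled. The real data's missingness
  mechanism is not documented; the logistic MNAR model is an assumption
  and both parameters are exposed.
* **Annotations.** Planted PM proteins receive GS ≥ 20 and SPC ∈ {3, 4};
  5% of background proteins pass the surface filter too (annotation
  noise), exercising false-positive filtering. Cancer-panel detection is
  Bernoulli per line — 0.30 background, 0.01 for the planted exclusive
  markers — over a 142-line panel, so exclusivity filtering separates the
  two groups essentially deterministically. Five planted tumor-exclusive
  markers (a subset of the PM residents) are undetected in all normal
  panels and always have usable antibodies: targets are planted where
  follow-up is possible, which is what the funnel's recovery is measured
  against (its top-ranked candidate should be a planted exclusive marker).
* **Cohort.** Positivity ~ 100 × Beta(2, 2); exponential event times with
  log-hazard log(HR)·upper + covariate effects (extent of resection −0.7,
  radiotherapy −0.35 on the log scale); independent exponential censoring
  calibrated to the requested censored fraction (30% by default); 25
  patients, HR 5 by default.

One emergent property deserves note: because non-PM fractions contain
their own +5-enriched residents, their pre-normalization medians sit about
0.8-1 log2 unit above the PM fraction's, and median normalization
transfers that compositional offset into a mild PM-direction inflation of
every fold change. This mirrors the composition bias any real
median-normalized fraction comparison carries. It widens planted fold
changes (which is why planted recovery is evaluated against truth, not
against the nominal +3) and cannot create false calls, again because of
the home-fraction comparison.

What the generator does **not** emulate: peptide-level evidence and razor
peptide logic, correlated (batch-structured) noise, isoform ambiguity,
shared-peptide quantification artifacts, inter-panel correlation of
normal-tissue expression, and informative censoring. Passing recovery
tests here therefore demonstrates that the pipeline's logic and statistics
behave as designed under the stated model — not that any particular real
dataset would yield the same candidate list.

# Validation problem sizes

The test suite validates the pipeline at the full default scale (5,000
proteins × 60 samples) for enrichment recovery, clustering and PCA
structure, and at 20 generator seeds for the null calibration and funnel
recovery properties; survival calibration uses 200 cohorts of 150
patients. The module unit tests use a scaled-down configuration (300
proteins, 8 tissues, 40-line cancer panel) where only contracts, not
power, are at stake. `scripts/acceptance.R` recomputes the same
quantities from scratch under a caller-supplied seed.

# Known limitations

* The subtractive call is all-or-nothing across fractions; a protein
  missing one fraction's comparison (e.g. a skipped cell line) is simply
  not callable there.
* BH families are per comparison by default; with very few truly
  differential proteins per family the Welch 3-vs-3 design has limited
  power at FDR 0.05, and sensitivity claims should be read against the
  generated composition.
* The rank-sum prioritization treats panels as exchangeable evidence;
  no weighting or correlation adjustment is attempted.
* Cox fits report Wald intervals; with very few events (small cohorts,
  heavy censoring) profile-likelihood intervals would be preferable.
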