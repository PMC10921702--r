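# organsurf

Subtractive organellar proteomics and cell-surface target prioritization
in R.

## The problem

Cell-surface proteins are prime therapeutic targets but are hard to
profile: whole-lysate shotgun proteomics under-samples membrane proteins,
and any single enrichment (silica-bead plasma-membrane capture included)
co-purifies contaminants from other compartments. The subtractive design
solves this by fractionating cells into their organelles — plasma membrane
(PM) by cationic colloidal silica-bead capture; cytosol, mitochondria,
microsomes and nuclei by differential ultracentrifugation — quantifying
each fraction by label-free LC-MS (iBAQ), and calling a protein
PM-resident only when it is *differentially* abundant in the PM fraction
against **every** other compartment.

`organsurf` is for proteomics analysts who have such a design (or want to
evaluate one): it takes MaxQuant-style `proteinGroups.txt` tables through
to a ranked list of tumor-restricted surface-target candidates and a
survival evaluation of a chosen marker.

## The statistics at the core

Per cell line $\ell$ and non-PM fraction $f$, each protein is tested with
Welch's unequal-variance *t*-test on log2 intensities,

$$t = \frac{\bar{x}_{PM} - \bar{x}_f}{\sqrt{s_{PM}^2/n_{PM} + s_f^2/n_f}},$$

with Satterthwaite degrees of freedom, and p-values are
Benjamini–Hochberg adjusted within each (cell line, fraction pair)
family, $q_{(i)} = \min_{j \ge i} p_{(j)}\,n/j$. A protein is PM-called
in a cell line iff $q < 0.05$ and $\log_2\mathrm{FC} > 1$ toward PM for
**every** non-PM fraction. Calls feed a candidate funnel — surface
prediction scores (GenieScore ≥ 20, SPC ≥ 3), consistency (≥ 2 cell
lines), cancer cell-line exclusivity (detected in ≤ 5 of a 142-line
panel), antibody availability — and survivors are ordered by the sum of
their average-tie ranks across four normal-tissue panels (IHC
not-detected proportion, two protein-abundance medians, one RNA median;
lower rank sum = more tumor-restricted). A marker's prognostic value is
assessed by splitting patients at the upper tertile of stain positivity
and fitting Kaplan–Meier/log-rank and Cox proportional-hazards models
(univariable, and multivariable with resection-extent and radiotherapy
covariates; Efron ties).

A synthetic-data generator (`sim_config()`, `simulate_study()`) emits all
pipeline inputs with planted ground truth — PM residents, compartment
structure, MNAR dropout, a tumor-exclusive marker, a planted hazard
effect — so the whole pipeline is testable without raw MS or patient
data. See the methods vignette (`vignettes/methods.Rmd`) for the models
and design choices.

## Worked example

```r
library(organsurf)

cfg <- sim_config(n_proteins = 1000, n_planted_pm = 30,
                  n_patients = 80, seed = 42)
sim <- simulate_study(cfg)

ds <- impute_low(median_normalize(sim$dataset), seed = 1)
enr <- run_subtractive(ds)
enr
#> Subtractive PM enrichment: 1000 proteins x 4 cell lines (FDR < 0.05, log2FC > 1)
#>   PM calls per cell line: CL1 = 26, CL2 = 23, CL3 = 22, CL4 = 24
#>   proteins called in >= 1 line: 28; in >= 2 lines: 27

fun <- run_funnel(enr$calls, sim$bundle, sim$panels)
fun
#> Candidate-mining funnel
#>   surface filter: 27 -> exclusivity: 5 -> antibody: 5
#>   top candidates (rank_sum): SIM00024 (12), SIM00074 (12), SIM00212 (12)

pr <- run_prognosis(sim$cohort)
pr
#> Prognostic evaluation (80 patients; 27 upper tertile)
#>   PFI: log-rank p = 6.88e-10 | univariable HR 6.54 (3.35-12.77) | multivariable HR 8.73 (4.20-18.13)
#>   OS: log-rank p = 5.96e-09 | univariable HR 6.46 (3.21-13.01) | multivariable HR 6.68 (3.31-13.47)
#>   site comparison: W = 754, p = 0.889
```

Reading the output: of 1000 simulated proteins, 27 are PM-called in ≥ 2
cell lines (30 were planted); the funnel's exclusivity and antibody
stages cut these to the 5 planted tumor-exclusive markers, which tie at
the minimal rank sum because they are undetected in every normal-tissue
panel. In the 80-patient cohort the planted hazard ratio of 5 is
recovered with confidence intervals covering the truth in both
univariable and covariate-adjusted models.

The same stages are available from the shell via the thin CLI at
`inst/cli/organsurf.R`
(`simulate | ingest | qc | enrich | mine | prognosis`), which reads and
writes the standard TSV/JSON artifacts deterministically.

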