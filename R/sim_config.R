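#' Simulation configuration for the synthetic study generator
#'
#' Builds and validates the parameter set that defines the synthetic study:
#' a multi-cell-line organelle-fractionation design with planted
#' plasma-membrane (PM) residents, abundance-dependent (MNAR) missingness,
#' annotation panels carrying planted tumor-exclusive markers, and a patient
#' cohort with a planted hazard effect. The defaults define the study
#' conditions used throughout the package's validation: 5,000 proteins
#' quantified across 4 cell lines x 5 fractions x 3 replicates with 50
#' planted PM residents at +3 log2 enrichment.
#'
#' @param n_proteins Number of quantified (non-junk) proteins.
#' @param cell_lines Character vector of cell-line labels.
#' @param fractions Character vector of fraction labels; must contain
#'   `pm_fraction`.
#' @param pm_fraction Label of the plasma-membrane (silica-bead) fraction.
#' @param n_replicates Replicates per (cell line, fraction).
#' @param n_planted_pm Number of true PM-resident proteins.
#' @param delta_pm log2 enrichment of planted PM proteins in the PM fraction.
#' @param delta_home log2 enrichment of background compartment residents in
#'   their home fraction. Organelle markers in fractionation data are
#'   typically enriched well beyond the PM-capture effect; the default of 5
#'   (32-fold) reflects that.
#' @param tau_contam Optional SD (log2) of per-protein, per-fraction
#'   cross-contamination effects on the non-home fractions of background
#'   proteins (heterogeneous carryover). The default 0 gives each protein a
#'   clean home-fraction profile; compartment composition alone already
#'   makes a realistic share of each comparison family truly differential.
#' @param sigma_noise Replicate noise SD (log2).
#' @param sigma_line SD (log2) of per-(protein, cell line) effects.
#' @param sample_shift_sd SD (log2) of per-sample loading shifts (removed by
#'   median normalization downstream).
#' @param baseline_mean,baseline_sd Mean and SD of per-protein baseline
#'   log2 iBAQ abundance.
#' @param mnar_midpoint,mnar_slope Logistic missingness parameters: an entry
#'   with log2 abundance `x` is masked with probability
#'   `plogis((mnar_midpoint - x) * mnar_slope)`; a slope of 0 disables
#'   missingness entirely.
#' @param n_decoy,n_contaminant,n_single_peptide Numbers of junk rows
#'   (reverse decoys, contaminants, single-peptide identifications) appended
#'   to the emitted protein-groups table to exercise ingestion filters.
#' @param n_exclusive Number of planted tumor-exclusive surface markers
#'   (a subset of the planted PM proteins).
#' @param annotation_noise Fraction of non-PM proteins that nevertheless pass
#'   the surface-prediction filter (false-positive annotations).
#' @param n_cancer_lines Size of the cancer cell-line detection panel.
#' @param cancer_rate_bg Per-line detection probability for non-exclusive
#'   proteins.
#' @param cancer_rate_exclusive Per-line detection probability for planted
#'   exclusive markers.
#' @param antibody_rate Probability that a non-exclusive protein has a
#'   validated antibody; planted exclusive markers always do (targets are
#'   only planted where follow-up is possible).
#' @param n_tissues Number of normal tissues per expression panel.
#' @param ihc_level_probs Probabilities of IHC levels 0:3 for background
#'   proteins.
#' @param panel_meanlog,panel_sdlog Log-normal parameters of background
#'   protein/RNA panel values.
#' @param n_patients Cohort size.
#' @param true_hr Planted hazard ratio of the upper-tertile marker group.
#' @param censor_rate Expected fraction of censored patients.
#' @param base_hazard Baseline event rate (per time unit) for
#'   progression-free interval; overall survival uses 0.6x this rate.
#' @param beta_eor,beta_rt Log-hazard effects of extent-of-resection and
#'   radiotherapy covariates.
#' @param prob_eor,prob_rt,prob_skull_base Covariate prevalences.
#' @param seed Integer RNG seed; all generator randomness derives from it.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(n_proteins = 200, n_planted_pm = 10, seed = 1)
#' cfg$fractions
#' @export
sim_config <- function(n_proteins = 5000,
                       cell_lines = paste0("CL", 1:4),
                       fractions = c("PM", "cytosol", "mitochondria",
                                     "microsome", "nuclear"),
                       pm_fraction = "PM",
                       n_replicates = 3,
                       n_planted_pm = 50,
                       delta_pm = 3.0,
                       delta_home = 5.0,
                       tau_contam = 0,
                       sigma_noise = 0.5,
                       sigma_line = 0.3,
                       sample_shift_sd = 0.25,
                       baseline_mean = 25,
                       baseline_sd = 3,
                       mnar_midpoint = 17,
                       mnar_slope = 0.9,
                       n_decoy = 100,
                       n_contaminant = 30,
                       n_single_peptide = 50,
                       n_exclusive = 5,
                       annotation_noise = 0.05,
                       n_cancer_lines = 142,
                       cancer_rate_bg = 0.3,
                       cancer_rate_exclusive = 0.01,
                       antibody_rate = 0.7,
                       n_tissues = 30,
                       ihc_level_probs = c(0.25, 0.30, 0.30, 0.15),
                       panel_meanlog = log(10),
                       panel_sdlog = 1,
                       n_patients = 25,
                       true_hr = 5,
                       censor_rate = 0.3,
                       base_hazard = 0.15,
                       beta_eor = -0.7,
                       beta_rt = -0.35,
                       prob_eor = 0.6,
                       prob_rt = 0.5,
                       prob_skull_base = 0.6,
                       seed = 7) {
  cfg <- as.list(environment())
  .check(length(pm_fraction) == 1L && sum(fractions == pm_fraction) == 1L,
         "`fractions` must contain exactly one PM fraction label")
  .check(!anyDuplicated(fractions), "duplicate fraction labels")
  .check(!anyDuplicated(cell_lines), "duplicate cell-line labels")
  .check(n_planted_pm >= 0 && n_planted_pm < n_proteins,
         "`n_planted_pm` must be in [0, n_proteins)")
  .check(n_exclusive >= 0 && n_exclusive <= n_planted_pm,
         "`n_exclusive` must be <= `n_planted_pm`")
  .check(delta_pm >= 0, "`delta_pm` must be >= 0")
  .check(sigma_noise > 0, "`sigma_noise` must be > 0")
  .check(mnar_slope >= 0, "`mnar_slope` must be >= 0")
  .check(n_replicates >= 1, "zero replicates are not allowed")
  counts <- c(n_proteins = n_proteins, n_tissues = n_tissues,
              n_cancer_lines = n_cancer_lines, n_patients = n_patients)
  .check(all(counts > 0), "all design counts must be positive")
  .check(length(fractions) >= 2, "need at least one non-PM fraction")
  .check(true_hr > 0, "`true_hr` must be > 0")
  .check(censor_rate >= 0 && censor_rate < 1,
         "`censor_rate` must be in [0, 1)")
  .check(abs(sum(ihc_level_probs) - 1) < 1e-8 && length(ihc_level_probs) == 4,
         "`ihc_level_probs` must be 4 probabilities summing to 1")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic study configuration\n")
  cat(sprintf("  proteins: %d (planted PM: %d, exclusive markers: %d)\n",
              x$n_proteins, x$n_planted_pm, x$n_exclusive))
  cat(sprintf("  design: %d cell lines x %d fractions (PM = '%s') x %d replicates\n",
              length(x$cell_lines), length(x$fractions), x$pm_fraction,
              x$n_replicates))
  cat(sprintf("  effects: delta_pm = %.2f, delta_home = %.2f, tau_contam = %.2f, sigma = %.2f\n",
              x$delta_pm, x$delta_home, x$tau_contam, x$sigma_noise))
  cat(sprintf("  MNAR: midpoint %.1f, slope %.2f | cohort: n = %d, HR = %.1f\n",
              x$mnar_midpoint, x$mnar_slope, x$n_patients, x$true_hr))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
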