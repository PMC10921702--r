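#' Generate a synthetic organelle-fractionation quantification dataset
#'
#' Simulates log2 iBAQ-style abundances for `n_proteins` proteins across a
#' cell line x fraction x replicate design with known ground truth. Each
#' protein has a home compartment: planted PM residents gain `delta_pm` in
#' the PM fraction; background residents gain `delta_home` in their home
#' fraction and carry protein-specific cross-contamination offsets
#' (N(0, tau_contam)) in every other fraction. Per-(protein, line) effects,
#' per-sample loading shifts and replicate noise are added, then entries are
#' masked missing-not-at-random with probability
#' `plogis((mnar_midpoint - abundance) * mnar_slope)`.
#'
#' @param config A [sim_config()].
#' @return A list with elements:
#'   \describe{
#'     \item{dataset}{A [quant_dataset] of log2 abundances with `NA` at
#'       masked entries and the missingness mask.}
#'     \item{truth}{A `ground_truth` list: `pm_protein_ids`,
#'       `compartment_of` (named character), `exclusive_marker_ids`.}
#'     \item{latent}{Diagnostics: the noise-free expected log2 abundance
#'       matrix and the pre-masking observed matrix.}
#'   }
#' Deterministic given `config$seed`.
#' @examples
#' sim <- generate_quant_dataset(sim_config(n_proteins = 100,
#'                                          n_planted_pm = 5, seed = 1))
#' dim(sim$dataset$values)
#' @export
generate_quant_dataset <- function(config) {
  .check(inherits(config, "sim_config"), "`config` must be a sim_config")
  with_seed(config$seed, {
    n <- config$n_proteins
    proteins <- sprintf("SIM%05d", seq_len(n))
    fr <- config$fractions
    pm <- config$pm_fraction
    nonpm <- setdiff(fr, pm)

    pm_ids <- sort(sample(proteins, config$n_planted_pm))
    excl_ids <- sort(sample(pm_ids, config$n_exclusive))
    home <- stats::setNames(sample(nonpm, n, replace = TRUE), proteins)
    home[pm_ids] <- pm

    # fraction-effect matrix: home enrichment + contamination offsets
    eff <- matrix(0, n, length(fr), dimnames = list(proteins, fr))
    for (f in fr) {
      resident <- home == f
      eff[resident, f] <- if (f == pm) config$delta_pm else config$delta_home
      bg_nonres <- !resident & !(proteins %in% pm_ids)
      eff[bg_nonres, f] <- stats::rnorm(sum(bg_nonres), 0, config$tau_contam)
    }

    baseline <- stats::rnorm(n, config$baseline_mean, config$baseline_sd)
    samples <- expand.grid(replicate = seq_len(config$n_replicates),
                           fraction = fr, cell_line = config$cell_lines,
                           stringsAsFactors = FALSE)[, 3:1]
    samples$sample_id <- sprintf("%s_%s_R%d", samples$cell_line,
                                 samples$fraction, samples$replicate)
    ns <- nrow(samples)

    line_eff <- matrix(stats::rnorm(n * length(config$cell_lines), 0,
                                    config$sigma_line),
                       n, length(config$cell_lines),
                       dimnames = list(proteins, config$cell_lines))
    shift <- stats::rnorm(ns, 0, config$sample_shift_sd)

    mu <- baseline + eff[, samples$fraction, drop = FALSE] +
      line_eff[, samples$cell_line, drop = FALSE] +
      matrix(shift, n, ns, byrow = TRUE)
    x <- mu + matrix(stats::rnorm(n * ns, 0, config$sigma_noise), n, ns)
    # mnar_slope = 0 disables missingness entirely (noise-free limit)
    p_miss <- if (config$mnar_slope > 0) {
      stats::plogis((config$mnar_midpoint - x) * config$mnar_slope)
    } else {
      0
    }
    mask <- matrix(stats::runif(n * ns) < p_miss, n, ns)
    full <- x
    x[mask] <- NA_real_
    dimnames(x) <- dimnames(mask) <- list(proteins, samples$sample_id)

    ds <- quant_dataset(values = x, mask = mask, samples = samples,
                        pm_fraction = pm)
    truth <- structure(list(pm_protein_ids = pm_ids,
                            compartment_of = home,
                            exclusive_marker_ids = excl_ids),
                       class = "ground_truth")
    dimnames(mu) <- dimnames(full) <- dimnames(x)
    list(dataset = ds, truth = truth,
         latent = list(expected_mu = mu, observed_full = full))
  })
}

#' Generate per-protein annotation data with planted surface truth
#'
#' Produces GenieScore (GS) and Surface Prediction Consensus (SPC)
#' annotations, a cancer cell-line detection matrix and antibody
#' availability flags. Planted PM residents receive GS >= 20 and SPC in
#' {3, 4}; a configurable fraction of background proteins also passes the
#' surface filter (annotation noise). Planted exclusive markers are detected
#' in cancer lines at `cancer_rate_exclusive`, everything else at
#' `cancer_rate_bg`.
#'
#' @param config A [sim_config()].
#' @param truth Ground truth from [generate_quant_dataset()].
#' @return A list of class `annotation_bundle`: `annotations` (data.frame
#'   with protein, genie_score, spc, antibody_ok), `cancer_detection`
#'   (logical protein x line matrix).
#' @export
generate_annotation_bundle <- function(config, truth) {
  .check(inherits(config, "sim_config"), "`config` must be a sim_config")
  .check(inherits(truth, "ground_truth"), "`truth` must be a ground_truth")
  with_seed(config$seed + 1L, {
    proteins <- names(truth$compartment_of)
    n <- length(proteins)
    is_pm <- proteins %in% truth$pm_protein_ids
    is_excl <- proteins %in% truth$exclusive_marker_ids

    gs <- stats::runif(n, 0, 20)
    spc <- sample(0:2, n, replace = TRUE)
    passers <- is_pm | (!is_pm & stats::runif(n) < config$annotation_noise)
    gs[passers] <- stats::runif(sum(passers), 20, 60)
    spc[passers] <- sample(3:4, sum(passers), replace = TRUE)

    rate <- ifelse(is_excl, config$cancer_rate_exclusive,
                   config$cancer_rate_bg)
    det <- matrix(stats::runif(n * config$n_cancer_lines) < rate,
                  n, config$n_cancer_lines,
                  dimnames = list(proteins,
                                  sprintf("CCL%03d",
                                          seq_len(config$n_cancer_lines))))
    antibody <- stats::runif(n) < config$antibody_rate
    antibody[is_excl] <- TRUE

    structure(list(
      annotations = data.frame(protein = proteins, genie_score = gs,
                               spc = spc, antibody_ok = antibody,
                               stringsAsFactors = FALSE),
      cancer_detection = det), class = "annotation_bundle")
  })
}

#' Generate the four normal-tissue expression panels
#'
#' One ordinal IHC panel (levels 0-3 per tissue), two continuous
#' protein-abundance panels and one continuous RNA panel, each protein x
#' tissue. Planted exclusive markers are undetected everywhere (IHC level 0,
#' value 0 in the continuous panels); background proteins draw log-normal
#' values.
#'
#' @param config A [sim_config()].
#' @param truth Ground truth from [generate_quant_dataset()].
#' @return Named list of matrices: `ihc`, `prot_a`, `prot_b`, `rna`.
#' @export
generate_normal_panels <- function(config, truth) {
  .check(inherits(config, "sim_config"), "`config` must be a sim_config")
  .check(inherits(truth, "ground_truth"), "`truth` must be a ground_truth")
  with_seed(config$seed + 2L, {
    proteins <- names(truth$compartment_of)
    n <- length(proteins)
    nt <- config$n_tissues
    tissues <- sprintf("tissue%02d", seq_len(nt))
    is_excl <- proteins %in% truth$exclusive_marker_ids

    ihc <- matrix(sample(0:3, n * nt, replace = TRUE,
                         prob = config$ihc_level_probs),
                  n, nt, dimnames = list(proteins, tissues))
    cont <- function() {
      m <- matrix(stats::rlnorm(n * nt, config$panel_meanlog,
                                config$panel_sdlog),
                  n, nt, dimnames = list(proteins, tissues))
      m[is_excl, ] <- 0
      m
    }
    prot_a <- cont()
    prot_b <- cont()
    rna <- cont()
    ihc[is_excl, ] <- 0L
    list(ihc = ihc, prot_a = prot_a, prot_b = prot_b, rna = rna)
  })
}

#' Generate a synthetic patient cohort with a planted hazard effect
#'
#' Marker stain positivity is drawn from a scaled Beta(2, 2); patients above
#' the 2/3 quantile form the upper tertile, whose event hazard is multiplied
#' by `true_hr`. Event times are exponential with log-hazard
#' `log(true_hr) * upper + beta_eor * eor + beta_rt * rt`; censoring is by an
#' independent exponential competing time calibrated so that the expected
#' censored fraction equals `censor_rate`. Both progression-free-interval
#' (PFI) and overall-survival (OS) endpoints are emitted.
#'
#' @param config A [sim_config()].
#' @param truth Optional ground truth; when supplied, the patient risk-group
#'   map is attached to it in the returned value.
#' @return List with `cohort` (data.frame: patient_id, stain_pct, pfi_time,
#'   pfi_event, os_time, os_event, eor, rt, site) and `risk_group` (named
#'   "upper"/"lower" vector).
#' @export
generate_survival_cohort <- function(config, truth = NULL) {
  .check(inherits(config, "sim_config"), "`config` must be a sim_config")
  .check(config$true_hr > 0, "`true_hr` must be > 0")
  .check(config$n_patients >= 9, "need n_patients >= 9 for stable tertiles")
  with_seed(config$seed + 3L, {
    n <- config$n_patients
    stain <- 100 * stats::rbeta(n, 2, 2)
    group <- tertile_split(stain)
    upper <- group == "upper"
    eor <- stats::rbinom(n, 1, config$prob_eor)
    rt <- stats::rbinom(n, 1, config$prob_rt)
    site <- ifelse(stats::runif(n) < config$prob_skull_base,
                   "skull_base", "spine")

    draw_endpoint <- function(base_rate) {
      rate <- base_rate * exp(log(config$true_hr) * upper +
                                config$beta_eor * eor + config$beta_rt * rt)
      t_event <- stats::rexp(n, rate)
      if (config$censor_rate > 0) {
        c_rate <- rate * config$censor_rate / (1 - config$censor_rate)
        t_cens <- stats::rexp(n, c_rate)
        list(time = pmin(t_event, t_cens),
             event = as.integer(t_event <= t_cens))
      } else {
        list(time = t_event, event = rep(1L, n))
      }
    }
    pfi <- draw_endpoint(config$base_hazard)
    os <- draw_endpoint(0.6 * config$base_hazard)

    cohort <- data.frame(patient_id = sprintf("PT%03d", seq_len(n)),
                         stain_pct = stain,
                         pfi_time = pfi$time, pfi_event = pfi$event,
                         os_time = os$time, os_event = os$event,
                         eor = eor, rt = rt, site = site,
                         stringsAsFactors = FALSE)
    risk <- stats::setNames(group, cohort$patient_id)
    if (!is.null(truth)) truth$patient_risk_group <- risk
    list(cohort = cohort, risk_group = risk, truth = truth)
  })
}

#' Generate the full synthetic study
#'
#' Convenience wrapper running all four generators with a shared
#' configuration.
#'
#' @param config A [sim_config()].
#' @return List: `dataset`, `truth` (with `patient_risk_group` attached),
#'   `latent`, `bundle`, `panels`, `cohort`.
#' @export
simulate_study <- function(config = sim_config()) {
  q <- generate_quant_dataset(config)
  bundle <- generate_annotation_bundle(config, q$truth)
  panels <- generate_normal_panels(config, q$truth)
  surv <- generate_survival_cohort(config, q$truth)
  truth <- q$truth
  truth$patient_risk_group <- surv$risk_group
  list(dataset = q$dataset, truth = truth, latent = q$latent,
       bundle = bundle, panels = panels, cohort = surv$cohort)
}

#' Write a simulated study to disk in the pipeline's input formats
#'
#' Emits a MaxQuant-dialect `proteinGroups.txt` (linear-scale iBAQ columns,
#' blanks encoded as 0, plus decoy/contaminant/single-peptide junk rows), a
#' sample sheet, annotation and cancer-detection tables, the four
#' normal-tissue panels, the patient cohort and a ground-truth JSON.
#'
#' @param sim Result of [simulate_study()].
#' @param outdir Output directory (created if needed).
#' @param config The [sim_config()] used (for junk-row counts).
#' @return Invisibly, the named vector of written paths.
#' @export
write_simulation <- function(sim, outdir, config) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  ds <- sim$dataset
  n <- nrow(ds$values)
  linear <- ifelse(is.na(ds$values), 0, 2^ds$values)

  with_seed(config$seed + 4L, {
    junk_n <- config$n_decoy + config$n_contaminant + config$n_single_peptide
    junk_ids <- c(sprintf("REV_Q%05d", seq_len(config$n_decoy)),
                  sprintf("CON_P%05d", seq_len(config$n_contaminant)),
                  sprintf("LP%05d", seq_len(config$n_single_peptide)))
    junk <- matrix(2^stats::rnorm(junk_n * ncol(linear), 20, 2),
                   junk_n, ncol(linear), dimnames = list(junk_ids, colnames(linear)))
    pg <- data.frame(
      `Majority protein IDs` = c(ds$proteins, junk_ids),
      `Unique peptides` = c(sample(2:40, n, replace = TRUE),
                            sample(2:40, config$n_decoy + config$n_contaminant,
                                   replace = TRUE),
                            rep(1L, config$n_single_peptide)),
      Reverse = c(rep("", n),
                  rep("+", config$n_decoy),
                  rep("", config$n_contaminant + config$n_single_peptide)),
      `Potential contaminant` = c(rep("", n + config$n_decoy),
                                  rep("+", config$n_contaminant),
                                  rep("", config$n_single_peptide)),
      check.names = FALSE, stringsAsFactors = FALSE)
    ib <- as.data.frame(rbind(linear, junk), check.names = FALSE)
    names(ib) <- paste("iBAQ", colnames(linear))
    pg <- cbind(pg, ib)
    # interleave junk rows deterministically through the table
    ord <- order(stats::runif(nrow(pg)))
    pg <- pg[ord, , drop = FALSE]

    paths <- c(
      protein_groups = file.path(outdir, "proteinGroups.txt"),
      samples = file.path(outdir, "samples.tsv"),
      annotations = file.path(outdir, "annotations.tsv"),
      cancer = file.path(outdir, "cancer_detection.tsv"),
      ihc = file.path(outdir, "panel_ihc.tsv"),
      prot_a = file.path(outdir, "panel_prot_a.tsv"),
      prot_b = file.path(outdir, "panel_prot_b.tsv"),
      rna = file.path(outdir, "panel_rna.tsv"),
      cohort = file.path(outdir, "cohort.tsv"),
      truth = file.path(outdir, "truth.json"))
    write_tsv(pg, paths["protein_groups"])
    write_tsv(ds$samples[, c("sample_id", "cell_line", "fraction",
                             "replicate")], paths["samples"])
    write_tsv(sim$bundle$annotations, paths["annotations"])
    write_matrix_tsv(sim$bundle$cancer_detection * 1L, paths["cancer"])
    write_matrix_tsv(sim$panels$ihc, paths["ihc"])
    write_matrix_tsv(sim$panels$prot_a, paths["prot_a"])
    write_matrix_tsv(sim$panels$prot_b, paths["prot_b"])
    write_matrix_tsv(sim$panels$rna, paths["rna"])
    write_tsv(sim$cohort, paths["cohort"])
    write_json_file(list(
      pm_protein_ids = sim$truth$pm_protein_ids,
      compartment_of = as.list(sim$truth$compartment_of),
      exclusive_marker_ids = sim$truth$exclusive_marker_ids,
      patient_risk_group = as.list(sim$truth$patient_risk_group)),
      paths["truth"])
    invisible(paths)
  })
}
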