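# File-based stage runners. Each reads the standard TSV inputs, calls the
# in-memory API, and writes deterministic TSV/JSON outputs, so that a fixed
# config + seed reproduces byte-identical artifacts.

#' Run the simulation stage to disk
#'
#' @param outdir Output directory.
#' @param config A [sim_config()].
#' @return Invisibly, named vector of written paths.
#' @export
run_simulate_stage <- function(outdir, config = sim_config()) {
  sim <- simulate_study(config)
  write_simulation(sim, outdir, config)
}

#' Run the ingestion stage to disk
#'
#' @param protein_groups,samples Input file paths.
#' @param outdir Output directory.
#' @param pm_fraction PM fraction label.
#' @param seed Imputation seed.
#' @return Invisibly, the processed [quant_dataset].
#' @export
run_ingest_stage <- function(protein_groups, samples, outdir,
                             pm_fraction = "PM", seed = 1L) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  res <- ingest_protein_groups(protein_groups, samples,
                               pm_fraction = pm_fraction, seed = seed)
  ds <- res$dataset
  write_matrix_tsv(ds$values, file.path(outdir, "matrix.tsv"))
  write_matrix_tsv(ds$mask * 1L, file.path(outdir, "mask.tsv"))
  write_tsv(ds$samples, file.path(outdir, "samples.tsv"))
  write_json_file(res$log, file.path(outdir, "processing_log.json"))
  invisible(ds)
}

# Rebuild a quant_dataset from matrix/mask/sample files written by
# run_ingest_stage (or any files in the same layout).
read_quant_dataset <- function(matrix_path, samples_path, mask_path = NULL,
                               pm_fraction = "PM") {
  values <- read_matrix_tsv(matrix_path)
  samples <- read_tsv(samples_path)
  mask <- if (!is.null(mask_path) && file.exists(mask_path)) {
    read_matrix_tsv(mask_path) == 1
  } else {
    matrix(FALSE, nrow(values), ncol(values), dimnames = dimnames(values))
  }
  quant_dataset(values = values, mask = mask, samples = samples,
                pm_fraction = pm_fraction)
}

#' Run the QC stage to disk
#'
#' @param matrix_path,samples_path,annotations_path Input files (annotations
#'   optional).
#' @param outdir Output directory.
#' @param k Number of protein clusters.
#' @param n_components PCA components to write.
#' @param pm_fraction PM fraction label.
#' @return Invisibly, list with the `pca_result` and `cluster_result`.
#' @export
run_qc_stage <- function(matrix_path, samples_path, outdir,
                         annotations_path = NULL, k = 4L,
                         n_components = 5L, pm_fraction = "PM") {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  ds <- read_quant_dataset(matrix_path, samples_path,
                           pm_fraction = pm_fraction)
  pca <- pca_samples(ds, n_components = n_components)
  cl <- cluster_proteins(ds, k = k)
  scores <- data.frame(sample_id = rownames(pca$scores), pca$scores,
                       check.names = FALSE)
  write_tsv(scores, file.path(outdir, "pca_scores.tsv"))
  write_tsv(data.frame(component = seq_along(pca$explained),
                       explained = pca$explained),
            file.path(outdir, "pca_explained.tsv"))
  write_tsv(data.frame(protein = names(cl$cluster_of),
                       cluster = unname(cl$cluster_of)),
            file.path(outdir, "clusters.tsv"))
  if (!is.null(annotations_path)) {
    ann <- read_tsv(annotations_path)
    flags <- data.frame(protein = ann$protein,
                        surface = ann$genie_score >= 20 & ann$spc >= 3)
    write_tsv(summarize_cluster_annotations(cl, flags),
              file.path(outdir, "cluster_summary.tsv"))
  }
  invisible(list(pca = pca, clusters = cl))
}

#' Run the subtractive-enrichment stage to disk
#'
#' @param matrix_path,samples_path Input files.
#' @param outdir Output directory.
#' @param fdr,min_log2fc Call thresholds.
#' @param pm_fraction PM fraction label.
#' @return Invisibly, the `enrichment_result`.
#' @export
run_enrich_stage <- function(matrix_path, samples_path, outdir,
                             fdr = 0.05, min_log2fc = 1.0,
                             pm_fraction = "PM") {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  ds <- read_quant_dataset(matrix_path, samples_path,
                           pm_fraction = pm_fraction)
  res <- run_subtractive(ds, fdr = fdr, min_log2fc = min_log2fc)
  write_tsv(res$table, file.path(outdir, "enrichment_table.tsv"))
  write_matrix_tsv(res$calls * 1L, file.path(outdir, "pm_calls.tsv"))
  invisible(res)
}

#' Run the candidate-mining stage to disk
#'
#' @param pm_calls_path,annotations_path,cancer_path Input files.
#' @param panel_paths Named list/vector with `ihc`, `prot_a`, `prot_b`,
#'   `rna` file paths.
#' @param outdir Output directory.
#' @param ... Thresholds passed to [run_funnel()].
#' @return Invisibly, the `funnel_report`.
#' @export
run_mine_stage <- function(pm_calls_path, annotations_path, cancer_path,
                           panel_paths, outdir, ...) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  calls <- read_matrix_tsv(pm_calls_path) == 1
  ann <- read_tsv(annotations_path)
  ann$antibody_ok <- as.logical(ann$antibody_ok)
  bundle <- structure(list(annotations = ann,
                           cancer_detection = read_matrix_tsv(cancer_path) == 1),
                      class = "annotation_bundle")
  panels <- lapply(panel_paths[c("ihc", "prot_a", "prot_b", "rna")],
                   read_matrix_tsv)
  report <- run_funnel(calls, bundle, panels, ...)
  write_json_file(as.list(report$stage_counts),
                  file.path(outdir, "funnel_counts.json"))
  stage_df <- data.frame(
    stage = rep(names(report$stages), lengths(report$stages)),
    protein = unlist(report$stages, use.names = FALSE))
  write_tsv(stage_df, file.path(outdir, "funnel_stages.tsv"))
  if (!is.null(report$ranking)) {
    write_tsv(as.data.frame(report$ranking),
              file.path(outdir, "candidate_ranking.tsv"))
  }
  invisible(report)
}

#' Run the prognostic-evaluation stage to disk
#'
#' @param cohort_path Cohort TSV.
#' @param outdir Output directory.
#' @param marker_col Marker positivity column.
#' @return Invisibly, the `prognosis_report`.
#' @export
run_prognosis_stage <- function(cohort_path, outdir,
                                marker_col = "stain_pct") {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cohort <- read_tsv(cohort_path)
  report <- run_prognosis(cohort, marker_col = marker_col)
  res <- lapply(names(report$cox_uni), function(e) {
    list(logrank_p = report$km[[e]]$p,
         univariable = report$cox_uni[[e]][c("hr", "ci_low", "ci_high", "p")],
         multivariable = report$cox_multi[[e]][c("hr", "ci_low", "ci_high",
                                              "p")])
  })
  names(res) <- names(report$cox_uni)
  if (!is.null(report$site_test)) res$site_test <- report$site_test
  write_json_file(res, file.path(outdir, "prognosis.json"))
  curves <- do.call(rbind, lapply(names(report$km), function(e) {
    cbind(endpoint = e, report$km[[e]]$curves)
  }))
  write_tsv(curves, file.path(outdir, "km_curves.tsv"))
  invisible(report)
}
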