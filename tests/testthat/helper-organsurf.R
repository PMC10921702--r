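# Shared fixtures: a scaled-down study configuration and writers for tiny
# protein-groups tables built in code.

small_config <- function(...) {
  defaults <- list(n_proteins = 300, n_planted_pm = 15, n_exclusive = 3,
                   n_tissues = 8, n_cancer_lines = 40, n_patients = 50,
                   n_decoy = 10, n_contaminant = 5, n_single_peptide = 8,
                   seed = 11)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# Deterministic, effectively noise-free configuration (no missingness, no
# nuisance effects) for separability-limit checks.
clean_config <- function(...) {
  small_config(sigma_noise = 1e-9, sigma_line = 0, sample_shift_sd = 0,
               tau_contam = 1e-9, mnar_slope = 0, annotation_noise = 0, ...)
}

# Write a small proteinGroups.txt-dialect file; `ibaq` is a matrix with
# sample ids as column names, NA encodes a blank cell.
write_pg_fixture <- function(ibaq, unique_peptides = NULL, reverse = NULL,
                             contaminant = NULL, ids = NULL,
                             dir = withr::local_tempdir(.local_envir = parent.frame())) {
  n <- nrow(ibaq)
  if (is.null(ids)) ids <- sprintf("P%03d", seq_len(n))
  if (is.null(unique_peptides)) unique_peptides <- rep(5L, n)
  if (is.null(reverse)) reverse <- rep("", n)
  if (is.null(contaminant)) contaminant <- rep("", n)
  pg <- data.frame(`Majority protein IDs` = ids,
                   `Unique peptides` = unique_peptides,
                   Reverse = reverse, `Potential contaminant` = contaminant,
                   check.names = FALSE)
  ib <- as.data.frame(ibaq)
  names(ib) <- paste("iBAQ", colnames(ibaq))
  pg <- cbind(pg, ib)
  pg_path <- file.path(dir, "proteinGroups.txt")
  utils::write.table(pg, pg_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  pg_path
}

# Sample sheet for a set of sample ids named "<line>_<fraction>_R<rep>".
sheet_for <- function(sample_ids,
                      dir = withr::local_tempdir(.local_envir = parent.frame())) {
  parts <- strsplit(sample_ids, "_")
  sheet <- data.frame(sample_id = sample_ids,
                      cell_line = vapply(parts, `[`, "", 1),
                      fraction = vapply(parts, `[`, "", 2),
                      replicate = as.integer(sub("R", "",
                                                 vapply(parts, `[`, "", 3))))
  path <- file.path(dir, "samples.tsv")
  utils::write.table(sheet, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

# Independent average-rank oracle: rank by counting, ties get the mean of
# the positions they occupy.
oracle_rank <- function(x) {
  vapply(seq_along(x), function(i) {
    sum(x < x[i]) + (1 + sum(x == x[i])) / 2
  }, 0)
}
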