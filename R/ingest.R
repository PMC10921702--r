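#' Quantification dataset container
#'
#' Holds a log2 protein x sample abundance matrix together with the
#' missingness mask and sample metadata. The mask records which entries were
#' originally missing; it is retained for provenance after imputation.
#'
#' @param values Numeric matrix (proteins x samples), log2 scale; `NA` where
#'   missing.
#' @param mask Logical matrix of the same shape, `TRUE` at originally
#'   missing entries.
#' @param samples Data frame with columns `sample_id`, `cell_line`,
#'   `fraction`, `replicate`, one row per column of `values`, in order.
#' @param pm_fraction Label of the plasma-membrane fraction.
#' @return An object of class `quant_dataset`.
#' @export
quant_dataset <- function(values, mask, samples, pm_fraction = "PM") {
  .check(is.matrix(values) && is.numeric(values), "`values` must be a numeric matrix")
  .check(is.matrix(mask) && is.logical(mask) && all(dim(mask) == dim(values)),
         "`mask` must be a logical matrix matching `values`")
  need <- c("sample_id", "cell_line", "fraction", "replicate")
  .check(all(need %in% names(samples)),
         paste("`samples` needs columns:", paste(need, collapse = ", ")))
  .check(nrow(samples) == ncol(values),
         "`samples` rows must match `values` columns")
  .check(!anyDuplicated(rownames(values)), "duplicate protein identifiers")
  .check(!anyDuplicated(samples$sample_id), "duplicate sample ids")
  key <- paste(samples$cell_line, samples$fraction, samples$replicate)
  .check(!anyDuplicated(key),
         "(cell_line, fraction, replicate) combinations must be unique")
  .check(pm_fraction %in% samples$fraction,
         sprintf("PM fraction '%s' absent from samples", pm_fraction))
  samples <- samples[, union(need, names(samples)), drop = FALSE]
  colnames(values) <- colnames(mask) <- samples$sample_id
  structure(list(values = values, mask = mask,
                 proteins = rownames(values), samples = samples,
                 pm_fraction = pm_fraction),
            class = "quant_dataset")
}

#' @export
print.quant_dataset <- function(x, ...) {
  cat(sprintf("quant_dataset: %d proteins x %d samples (%d cell lines, %d fractions, PM = '%s')\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$samples$cell_line)),
              length(unique(x$samples$fraction)), x$pm_fraction))
  cat(sprintf("  missing entries: %d (%.1f%%); values %s\n", sum(x$mask),
              100 * mean(x$mask),
              if (anyNA(x$values)) "not yet imputed" else "complete"))
  invisible(x)
}

#' @export
dim.quant_dataset <- function(x) dim(x$values)

#' Parse a MaxQuant-style protein-groups table
#'
#' Reads a `proteinGroups.txt`-dialect TSV and a sample sheet mapping every
#' `iBAQ <sample>` column to its cell line, fraction and replicate. Returns
#' linear-scale intensities with zero/blank cells treated as missing
#' (MaxQuant's convention for absent quantification). The protein identifier
#' is the first entry of "Majority protein IDs".
#'
#' @param path Path to the protein-groups TSV.
#' @param sample_sheet Path to a TSV with columns `sample_id`, `cell_line`,
#'   `fraction`, `replicate`; or a data.frame of the same shape.
#' @param pm_fraction Label of the PM fraction (must occur in the sheet).
#' @return A list of class `pg_table`: `intensities` (linear, `NA` missing),
#'   `unique_peptides`, `reverse`, `contaminant`, `samples`.
#' @export
parse_protein_groups <- function(path, sample_sheet, pm_fraction = "PM") {
  tab <- read_tsv(path)
  need <- c("Majority protein IDs", "Unique peptides", "Reverse",
            "Potential contaminant")
  missing_cols <- setdiff(need, names(tab))
  .check(length(missing_cols) == 0,
         paste("protein-groups table lacks columns:",
               paste(missing_cols, collapse = ", ")))
  sheet <- if (is.data.frame(sample_sheet)) sample_sheet else read_tsv(sample_sheet)
  .check(all(c("sample_id", "cell_line", "fraction", "replicate") %in%
               names(sheet)), "malformed sample sheet")
  .check(!anyDuplicated(sheet$sample_id), "duplicate sample ids in sheet")

  ibaq_cols <- grep("^iBAQ ", names(tab), value = TRUE)
  .check(length(ibaq_cols) > 0, "no 'iBAQ <sample>' columns found")
  col_sample <- sub("^iBAQ ", "", ibaq_cols)
  unmapped <- setdiff(col_sample, sheet$sample_id)
  .check(length(unmapped) == 0,
         paste("iBAQ columns absent from sample sheet:",
               paste(unmapped, collapse = ", ")))
  absent <- setdiff(sheet$sample_id, col_sample)
  .check(length(absent) == 0,
         paste("sample sheet entries without an iBAQ column:",
               paste(absent, collapse = ", ")))

  ids <- vapply(strsplit(as.character(tab[["Majority protein IDs"]]), ";"),
                `[`, "", 1L)
  .check(!anyDuplicated(ids), "duplicate protein identifiers after parsing")
  m <- as.matrix(tab[, ibaq_cols, drop = FALSE])
  mode(m) <- "numeric"
  m[!is.finite(m) | m <= 0] <- NA_real_
  # order columns by the sheet
  ord <- match(sheet$sample_id, col_sample)
  m <- m[, ord, drop = FALSE]
  dimnames(m) <- list(ids, sheet$sample_id)
  structure(list(intensities = m,
                 unique_peptides = as.integer(tab[["Unique peptides"]]),
                 reverse = as.character(tab[["Reverse"]]),
                 contaminant = as.character(tab[["Potential contaminant"]]),
                 samples = sheet, pm_fraction = pm_fraction),
            class = "pg_table")
}

#' Remove decoy, contaminant and low-evidence identifications
#'
#' Drops rows flagged as reverse decoys or potential contaminants and rows
#' identified with fewer than `min_unique_peptides` unique peptides
#' (default 2, i.e. proteins with two or more unique peptides are carried
#' forward). Row order is otherwise preserved.
#'
#' @param pg A `pg_table` from [parse_protein_groups()].
#' @param min_unique_peptides Minimum unique peptides to retain a row.
#' @return The filtered `pg_table`, with a `filter_log` attribute recording
#'   counts dropped per rule.
#' @export
filter_identifications <- function(pg, min_unique_peptides = 2L) {
  .check(inherits(pg, "pg_table"), "`pg` must come from parse_protein_groups()")
  is_rev <- pg$reverse == "+"
  is_con <- pg$contaminant == "+"
  low <- pg$unique_peptides < min_unique_peptides
  keep <- !is_rev & !is_con & !low
  out <- pg
  out$intensities <- pg$intensities[keep, , drop = FALSE]
  out$unique_peptides <- pg$unique_peptides[keep]
  out$reverse <- pg$reverse[keep]
  out$contaminant <- pg$contaminant[keep]
  attr(out, "filter_log") <- list(
    input = nrow(pg$intensities),
    dropped_reverse = sum(is_rev),
    dropped_contaminant = sum(is_con & !is_rev),
    dropped_low_peptides = sum(low & !is_rev & !is_con),
    retained = sum(keep))
  out
}

#' log2-transform a filtered protein-groups table
#'
#' @param pg A filtered `pg_table` with linear intensities.
#' @return A [quant_dataset] of log2 values with `NA` preserved as missing.
#' @export
log2_transform <- function(pg) {
  .check(inherits(pg, "pg_table"), "`pg` must come from parse_protein_groups()")
  m <- pg$intensities
  .check(all(m[!is.na(m)] > 0), "negative or zero intensity cannot be log2-transformed")
  quant_dataset(values = log2(m), mask = is.na(m), samples = pg$samples,
                pm_fraction = pg$pm_fraction)
}

#' Median-normalize a quantification dataset
#'
#' Applies a per-sample shift on the log2 scale so that every sample's
#' observed median equals the global median of per-sample observed medians.
#' Normalization statistics use observed values only; the mask is unchanged
#' and within-sample differences between observed entries are preserved
#' exactly.
#'
#' @param ds A [quant_dataset].
#' @return The normalized [quant_dataset].
#' @export
median_normalize <- function(ds) {
  .check(inherits(ds, "quant_dataset"), "`ds` must be a quant_dataset")
  med <- apply(ds$values, 2, stats::median, na.rm = TRUE)
  .check(all(is.finite(med)), "a sample has no observed values")
  target <- stats::median(med)
  ds$values <- sweep(ds$values, 2, med - target)
  ds
}

#' Impute missing values with low draws
#'
#' Replaces every masked entry with an independent uniform draw on
#' `[low, high]` log2 units (default 1.0-1.2), emulating low-value
#' imputation for missing-not-at-random dropout. Observed entries are
#' bit-identical to the input; the mask is retained for provenance.
#' With `method = "constant"` the midpoint `(low + high)/2` is used instead
#' of uniform draws.
#'
#' @param ds A [quant_dataset].
#' @param low,high Bounds of the imputation interval (log2).
#' @param seed Integer seed for the uniform draws.
#' @param method `"uniform"` (default) or `"constant"`.
#' @return The imputed [quant_dataset] (no `NA` left).
#' @export
impute_low <- function(ds, low = 1.0, high = 1.2, seed = 1L,
                       method = c("uniform", "constant")) {
  .check(inherits(ds, "quant_dataset"), "`ds` must be a quant_dataset")
  .check(low <= high, "`low` must be <= `high`")
  method <- match.arg(method)
  idx <- which(ds$mask)
  if (length(idx) == 0) return(ds)
  ds$values[idx] <- if (method == "uniform") {
    with_seed(seed, stats::runif(length(idx), low, high))
  } else {
    (low + high) / 2
  }
  ds
}

#' Run the full ingestion pipeline
#'
#' parse -> filter -> log2 -> median-normalize -> impute, the fixed
#' processing order. Normalization statistics are computed on observed
#' values only (pre-imputation).
#'
#' @inheritParams parse_protein_groups
#' @inheritParams impute_low
#' @param min_unique_peptides Minimum unique peptides to retain a row.
#' @return A list: `dataset` (processed [quant_dataset]) and `log`
#'   (per-filter drop counts).
#' @export
ingest_protein_groups <- function(path, sample_sheet, pm_fraction = "PM",
                                  min_unique_peptides = 2L,
                                  low = 1.0, high = 1.2, seed = 1L,
                                  method = c("uniform", "constant")) {
  pg <- parse_protein_groups(path, sample_sheet, pm_fraction)
  pg <- filter_identifications(pg, min_unique_peptides)
  ds <- log2_transform(pg)
  ds <- median_normalize(ds)
  ds <- impute_low(ds, low = low, high = high, seed = seed,
                   method = match.arg(method))
  list(dataset = ds, log = attr(pg, "filter_log"))
}
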