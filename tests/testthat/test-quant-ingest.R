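make_samples <- function() {
  ids <- as.vector(outer(c("A_PM", "A_cytosol"), paste0("_R", 1:2),
                         paste0))
  ids
}

test_that("parsing maps iBAQ columns through the sample sheet and masks blanks", {
  ids <- make_samples()
  ibaq <- matrix(c(1024, 2048, 4096, 512,
                   NA, 100, 200, 300,
                   8, 16, 32, 64), nrow = 3, byrow = TRUE,
                 dimnames = list(NULL, ids))
  dir <- withr::local_tempdir()
  pg_path <- write_pg_fixture(ibaq, dir = dir)
  sheet <- sheet_for(ids, dir = dir)
  pg <- parse_protein_groups(pg_path, sheet)
  expect_identical(dim(pg$intensities), c(3L, 4L))
  expect_true(is.na(pg$intensities["P002", ids[1]]))
  expect_identical(sum(is.na(pg$intensities)), 1L)
  # zero intensity is missing by convention
  ibaq0 <- ibaq
  ibaq0[1, 2] <- 0
  pg0 <- parse_protein_groups(write_pg_fixture(ibaq0, dir = dir), sheet)
  expect_true(is.na(pg0$intensities["P001", ids[2]]))
})

test_that("sheet/column mismatches and missing columns are errors", {
  ids <- make_samples()
  ibaq <- matrix(1:8, 2, 4, dimnames = list(NULL, ids))
  dir <- withr::local_tempdir()
  pg_path <- write_pg_fixture(ibaq, dir = dir)
  sheet3 <- sheet_for(ids[1:3], dir = dir)       # one iBAQ column unmapped
  expect_error(parse_protein_groups(pg_path, sheet3), "absent from sample")
  # sheet entry without a column
  ibaq3 <- ibaq[, 1:3]
  sheet4 <- sheet_for(ids, dir = dir)
  expect_error(parse_protein_groups(write_pg_fixture(ibaq3, dir = dir),
                                    sheet4), "without an iBAQ column")
  # required column missing
  tab <- utils::read.delim(pg_path, check.names = FALSE)
  tab[["Unique peptides"]] <- NULL
  bad <- file.path(dir, "bad.txt")
  utils::write.table(tab, bad, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(parse_protein_groups(bad, sheet4), "Unique peptides")
})

test_that("identification filters drop decoys, contaminants and low-evidence rows", {
  ids <- make_samples()
  ibaq <- matrix(2^stats::rnorm(40, 20), 10, 4,
                 dimnames = list(NULL, ids))
  dir <- withr::local_tempdir()
  pg_path <- write_pg_fixture(
    ibaq,
    unique_peptides = c(5, 1, 5, 2, 1, 5, 5, 1, 5, 5),
    reverse = c("", "", "+", "", "", "", "+", "", "", ""),
    contaminant = c("", "", "", "", "", "+", "", "", "", ""),
    dir = dir)
  pg <- parse_protein_groups(pg_path, sheet_for(ids, dir = dir))
  filt <- filter_identifications(pg)
  log <- attr(filt, "filter_log")
  expect_identical(log$dropped_reverse, 2L)
  expect_identical(log$dropped_contaminant, 1L)
  expect_identical(log$dropped_low_peptides, 3L)
  expect_identical(nrow(filt$intensities), 4L)
  # two unique peptides retained, one removed; order preserved
  expect_identical(rownames(filt$intensities),
                   c("P001", "P004", "P009", "P010"))
})

test_that("log2 transform maps known values and preserves missingness", {
  ids <- make_samples()
  ibaq <- matrix(c(1024, 1, 2, NA), 1, 4, dimnames = list(NULL, ids))
  dir <- withr::local_tempdir()
  pg <- parse_protein_groups(write_pg_fixture(ibaq, dir = dir),
                             sheet_for(ids, dir = dir))
  ds <- log2_transform(pg)
  expect_equal(unname(ds$values[1, 1:3]), c(10, 0, 1))
  expect_true(is.na(ds$values[1, 4]) && ds$mask[1, 4])
})

test_that("median normalization equalizes observed sample medians as a pure shift", {
  ids <- make_samples()
  v <- matrix(c(9, 10, 11, 11, 12, 13, 9, 10, 11, 10, 11, 12), 3, 4,
              dimnames = list(c("a", "b", "c"), ids))
  sheet <- utils::read.delim(sheet_for(ids), check.names = FALSE)
  ds <- quant_dataset(v, matrix(FALSE, 3, 4), sheet)
  nds <- median_normalize(ds)
  med <- apply(nds$values, 2, stats::median)
  expect_equal(unname(med), rep(stats::median(c(10, 12, 10, 11)), 4))
  # shift-only: within-sample differences preserved
  expect_equal(diff(nds$values[, 1]), diff(ds$values[, 1]))
  # idempotent once medians agree
  expect_equal(median_normalize(nds)$values, nds$values)

  # random fixture: medians equal within 1e-12
  set.seed(42)
  v2 <- matrix(stats::rnorm(50 * 4, 20, 3), 50, 4,
               dimnames = list(sprintf("Q%02d", 1:50), ids))
  ds2 <- quant_dataset(v2, matrix(FALSE, 50, 4), sheet)
  m2 <- apply(median_normalize(ds2)$values, 2, stats::median)
  expect_lt(max(m2) - min(m2), 1e-12)
})

test_that("imputation draws lie in [low, high], never touch observed values, and are seeded", {
  sim <- generate_quant_dataset(small_config())
  ds <- median_normalize(sim$dataset)
  imp1 <- impute_low(ds, seed = 3)
  imp2 <- impute_low(ds, seed = 3)
  imp3 <- impute_low(ds, seed = 4)
  expect_false(anyNA(imp1$values))
  expect_true(all(imp1$values[ds$mask] >= 1.0 & imp1$values[ds$mask] <= 1.2))
  expect_identical(imp1$values[!ds$mask], ds$values[!ds$mask])
  expect_identical(imp1$values, imp2$values)
  expect_false(identical(imp1$values, imp3$values))
  expect_identical(imp1$mask, ds$mask)  # provenance retained
  expect_error(impute_low(ds, low = 2, high = 1))
  # constant method uses the midpoint
  impc <- impute_low(ds, method = "constant")
  expect_true(all(impc$values[ds$mask] == 1.1))
  # a dataset without missing entries is returned untouched
  clean <- quant_dataset(ds$values * 0 + 5,
                         ds$mask & FALSE, ds$samples)
  expect_identical(impute_low(clean, seed = 9)$values, clean$values)
})

test_that("simulated datasets round-trip through serialization and parsing", {
  cfg <- small_config()
  sim <- simulate_study(cfg)
  dir <- withr::local_tempdir()
  paths <- write_simulation(sim, dir, cfg)
  pg <- parse_protein_groups(paths["protein_groups"], paths["samples"])
  filt <- filter_identifications(pg)
  ds <- log2_transform(filt)
  shared <- sim$dataset$proteins
  expect_setequal(rownames(ds$values), shared)
  v <- ds$values[shared, colnames(sim$dataset$values)]
  obs <- !sim$dataset$mask
  expect_equal(v[obs], sim$dataset$values[obs], tolerance = 1e-9)
  expect_identical(is.na(v), sim$dataset$mask)
})

test_that("the ingestion pipeline runs filter -> log2 -> normalize -> impute", {
  cfg <- small_config()
  sim <- simulate_study(cfg)
  dir <- withr::local_tempdir()
  paths <- write_simulation(sim, dir, cfg)
  res <- ingest_protein_groups(paths["protein_groups"], paths["samples"],
                               seed = 2)
  expect_equal(res$log$retained, cfg$n_proteins)
  expect_false(anyNA(res$dataset$values))
  # observed medians equal post-normalization (mask-aware)
  obs_med <- vapply(seq_len(ncol(res$dataset$values)), function(j) {
    stats::median(res$dataset$values[!res$dataset$mask[, j], j])
  }, 0)
  expect_lt(max(obs_med) - min(obs_med), 1e-12)
})
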