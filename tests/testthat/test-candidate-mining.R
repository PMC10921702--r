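mk_bundle <- function(ann, det) {
  structure(list(annotations = ann, cancer_detection = det),
            class = "annotation_bundle")
}

mk_calls <- function(ids, n_lines) {
  m <- matrix(FALSE, length(ids), 4, dimnames = list(ids, paste0("CL", 1:4)))
  for (i in seq_along(ids)) m[i, seq_len(n_lines[i])] <- TRUE
  m
}

test_that("surface filter applies inclusive GS/SPC/line thresholds", {
  ids <- c("A", "B", "C", "D", "E")
  ann <- data.frame(protein = ids,
                    genie_score = c(20, 19.9, 50, 25, 30),
                    spc = c(3, 4, 2, 3, 4),
                    antibody_ok = TRUE)
  calls <- mk_calls(ids, c(2, 2, 2, 1, 4))
  got <- surface_filter(calls, ann)
  expect_setequal(got, c("A", "E"))  # B fails GS, C fails SPC, D fails lines
  # unknown PM-called protein excluded with warning
  calls2 <- mk_calls(c(ids, "GHOST"), c(2, 2, 2, 1, 4, 3))
  expect_warning(got2 <- surface_filter(calls2, ann), "missing")
  expect_setequal(got2, got)
})

test_that("exclusivity and antibody filters use inclusive caps and commute", {
  ids <- sprintf("P%02d", 1:15)
  det <- matrix(FALSE, 15, 10, dimnames = list(ids, NULL))
  det[2, 1:5] <- TRUE   # exactly 5: kept
  det[3, 1:6] <- TRUE   # 6: dropped
  ab <- stats::setNames(rep(TRUE, 15), ids)
  ab[c(4, 7, 9, 12)] <- FALSE
  expect_setequal(exclusivity_filter(ids, det), ids[-3])
  expect_length(antibody_filter(ids, ab), 11)
  expect_setequal(antibody_filter(exclusivity_filter(ids, det), ab),
                  exclusivity_filter(antibody_filter(ids, ab), det))
  # all-false detection row is kept
  expect_true("P01" %in% exclusivity_filter(ids, det))
})

test_that("normal-tissue rank-sum matches a brute-force oracle with ties", {
  set.seed(20)
  ids <- sprintf("C%02d", 1:15)
  nt <- 7  # odd, so per-protein medians are order statistics
  ihc <- matrix(sample(0:3, 15 * nt, replace = TRUE), 15, nt,
                dimnames = list(ids, NULL))
  p1 <- matrix(stats::rlnorm(15 * nt), 15, nt, dimnames = list(ids, NULL))
  p2 <- p1[sample(15), ]  # reuse values to create cross-protein structure
  rownames(p2) <- ids
  rna <- matrix(stats::rlnorm(15 * nt), 15, nt, dimnames = list(ids, NULL))
  # force ties in every panel
  ihc[3, ] <- ihc[5, ]
  p1[2, ] <- p1[9, ]
  rna[1, ] <- rna[14, ]

  rk <- rank_normal_tissue(ids, ihc, p1, p2, rna)
  # independent oracle: counting ranks + summation + lexicographic ties
  o_ihc <- oracle_rank(-apply(ihc, 1, function(r) mean(r == 0)))
  o_p1 <- oracle_rank(apply(p1, 1, stats::median))
  o_p2 <- oracle_rank(apply(p2, 1, stats::median))
  o_rna <- oracle_rank(apply(rna, 1, stats::median))
  o_sum <- o_ihc + o_p1 + o_p2 + o_rna
  o_order <- ids[order(o_sum, ids)]
  got <- rk[match(ids, rk$protein), ]
  expect_equal(got$rank_ihc, o_ihc)
  expect_equal(got$rank_prot1, o_p1)
  expect_equal(got$rank_prot2, o_p2)
  expect_equal(got$rank_rna, o_rna)
  expect_equal(got$rank_sum, o_sum)
  expect_identical(rk$protein, o_order)
  # average-tie ranks sum to n(n+1)/2 per panel
  n <- length(ids)
  for (col in c("rank_ihc", "rank_prot1", "rank_prot2", "rank_rna")) {
    expect_equal(sum(rk[[col]]), n * (n + 1) / 2)
  }
  # invariance under strictly monotone transforms of panel values
  rk2 <- rank_normal_tissue(ids, ihc, exp(p1), p2^3, 10 * rna + 1)
  expect_identical(rk2$protein, rk$protein)
  expect_equal(rk2$rank_sum, rk$rank_sum)
})

test_that("an everywhere-undetected candidate ranks first in every panel", {
  ids <- c("MARK", sprintf("B%02d", 1:9))
  nt <- 5
  ihc <- matrix(sample(1:3, 10 * nt, replace = TRUE), 10, nt,
                dimnames = list(ids, NULL))
  cont <- matrix(stats::rlnorm(10 * nt, 2), 10, nt,
                 dimnames = list(ids, NULL))
  ihc["MARK", ] <- 0
  cont["MARK", ] <- 0
  rk <- rank_normal_tissue(ids, ihc, cont, cont, cont)
  top <- rk[rk$protein == "MARK", ]
  expect_equal(top$final_rank, 1L)
  expect_equal(unlist(top[c("rank_ihc", "rank_prot1", "rank_prot2",
                            "rank_rna")], use.names = FALSE), rep(1, 4))
  # identical candidates tie and break deterministically by id
  ids2 <- c("AA", "AB")
  same <- matrix(1, 2, 3, dimnames = list(ids2, NULL))
  rk2 <- rank_normal_tissue(ids2, matrix(0L, 2, 3, dimnames = list(ids2, NULL)),
                            same, same, same)
  expect_identical(rk2$protein, c("AA", "AB"))
  expect_equal(rk2$rank_sum[1], rk2$rank_sum[2])
})

test_that("candidates absent from a panel follow the missing-value policy", {
  ids <- c("X", "Y", "Z")
  nt <- 4
  full <- matrix(stats::rlnorm(3 * nt, 2), 3, nt, dimnames = list(ids, NULL))
  partial <- full[c("X", "Y"), , drop = FALSE]
  ihc <- matrix(1L, 3, nt, dimnames = list(ids, NULL))
  expect_warning(best <- rank_normal_tissue(ids, ihc, partial, full, full,
                                            missing = "best"), "absent")
  expect_equal(best$median_prot1[best$protein == "Z"], 0)
  expect_warning(worst <- rank_normal_tissue(ids, ihc, partial, full, full,
                                             missing = "worst"), "absent")
  expect_equal(worst$rank_prot1[worst$protein == "Z"], 3)
  excl <- rank_normal_tissue(ids, ihc, partial, full, full,
                             missing = "exclude")
  expect_setequal(excl$protein, c("X", "Y"))
  # absent from every panel is a contract violation
  expect_error(rank_normal_tissue(c(ids, "W"), ihc, partial, full, full),
               "absent from every panel")
})

test_that("the funnel filters compose with non-increasing survivor counts", {
  cfg <- clean_config(n_cancer_lines = 142)
  sim <- simulate_study(cfg)
  ds <- impute_low(median_normalize(sim$dataset), seed = 1)
  res <- run_subtractive(ds)
  fr <- run_funnel(res$calls, sim$bundle, sim$panels)
  expect_true(all(diff(fr$stage_counts) <= 0))
  # zero annotation noise: surface survivors = planted PM called in >= 2 lines
  called2 <- rownames(res$calls)[rowSums(res$calls) >= 2]
  expect_setequal(fr$stages$surface,
                  intersect(sim$truth$pm_protein_ids, called2))
  # exclusivity stage keeps exactly the planted exclusive markers
  expect_setequal(fr$stages$exclusivity, sim$truth$exclusive_marker_ids)
  expect_true(fr$ranking$protein[1] %in% sim$truth$exclusive_marker_ids)

  # degenerate thresholds: ranking covers every PM-called protein
  all_pass <- run_funnel(res$calls, sim$bundle, sim$panels, gs_min = -Inf,
                         spc_min = 0, min_lines = 1,
                         max_cancer_lines = ncol(sim$bundle$cancer_detection))
  expect_equal(all_pass$stage_counts[["surface"]],
               sum(rowSums(res$calls) >= 1))

  # empty survivor set yields a valid empty report
  none <- run_funnel(res$calls, sim$bundle, sim$panels, gs_min = Inf)
  expect_null(none$ranking)
  expect_equal(unname(none$stage_counts), rep(0L, 4),
               ignore_attr = TRUE)
})
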