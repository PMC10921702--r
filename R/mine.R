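#' Surface-candidate filter
#'
#' Keeps proteins with GenieScore >= `gs_min`, Surface Prediction Consensus
#' >= `spc_min` and a PM-enrichment call in at least `min_lines` cell lines
#' (all thresholds inclusive). Proteins with PM calls but no annotation row
#' are excluded with a warning.
#'
#' @param pm_calls Logical protein x cell line call matrix (e.g.
#'   `enrichment_result$calls`).
#' @param bundle An `annotation_bundle` (or its `annotations` data frame).
#' @param gs_min,spc_min,min_lines Inclusive thresholds.
#' @return Character vector of candidate protein ids (sorted).
#' @export
surface_filter <- function(pm_calls, bundle, gs_min = 20, spc_min = 3,
                           min_lines = 2L) {
  ann <- if (inherits(bundle, "annotation_bundle")) bundle$annotations else bundle
  .check(all(c("protein", "genie_score", "spc") %in% names(ann)),
         "annotations need protein, genie_score, spc columns")
  consistent <- rownames(pm_calls)[rowSums(pm_calls) >= min_lines]
  unknown <- setdiff(consistent, ann$protein)
  if (length(unknown) > 0) {
    warning(sprintf("%d PM-called proteins missing from annotations; excluded",
                    length(unknown)))
    consistent <- setdiff(consistent, unknown)
  }
  idx <- match(consistent, ann$protein)
  keep <- ann$genie_score[idx] >= gs_min & ann$spc[idx] >= spc_min
  sort(consistent[keep])
}

#' Cancer-panel exclusivity filter
#'
#' Keeps candidates detected in at most `max_lines` cancer cell lines.
#'
#' @param candidates Character vector of protein ids.
#' @param cancer_detection Logical protein x cancer-line matrix.
#' @param max_lines Inclusive detection cap (default 5).
#' @return Filtered candidate vector.
#' @export
exclusivity_filter <- function(candidates, cancer_detection, max_lines = 5L) {
  .check(all(candidates %in% rownames(cancer_detection)),
         "detection matrix does not cover all candidates")
  counts <- rowSums(cancer_detection[candidates, , drop = FALSE])
  candidates[counts <= max_lines]
}

#' Antibody-availability filter
#'
#' Keeps candidates with a usable antibody (flag `TRUE`).
#'
#' @param candidates Character vector of protein ids.
#' @param antibody_ok Named logical vector, or an annotations data frame
#'   with `protein` and `antibody_ok` columns.
#' @return Filtered candidate vector.
#' @export
antibody_filter <- function(candidates, antibody_ok) {
  if (is.data.frame(antibody_ok)) {
    antibody_ok <- stats::setNames(antibody_ok$antibody_ok,
                                   antibody_ok$protein)
  }
  .check(all(candidates %in% names(antibody_ok)),
         "antibody flags do not cover all candidates")
  candidates[antibody_ok[candidates]]
}

# average ranks (1 = best); direction = 1 ranks ascending values best,
# direction = -1 ranks descending values best
.avg_rank <- function(x, direction = 1) {
  rank(direction * x, ties.method = "average")
}

#' Normal-tissue rank-sum prioritization
#'
#' Ranks candidates within four normal-tissue panels: (i) proportion of
#' tissues where the protein is not detected by IHC (level 0), ranked
#' descending (more undetected tissues is better); (ii, iii) median
#' abundance across tissues in two protein panels, ranked ascending;
#' (iv) median RNA across tissues, ranked ascending. Ties receive average
#' ranks; the final order is ascending by the sum of the four ranks, ties
#' broken lexicographically by protein id.
#'
#' Candidates absent from a panel are treated per `missing`: `"best"`
#' (default; absence is taken as not detected, value 0 / undetected in all
#' tissues), `"worst"` (value `Inf` / detected everywhere), or `"exclude"`
#' (drop the candidate from the ranking).
#'
#' @param candidates Character vector of protein ids.
#' @param ihc_panel Integer matrix (protein x tissue) of IHC levels 0-3.
#' @param prot_panel_1,prot_panel_2,rna_panel Numeric protein x tissue
#'   matrices.
#' @param missing Handling of candidates absent from a panel.
#' @return Data frame of class `candidate_ranking`: protein, ihc_undetected,
#'   median_prot1, median_prot2, median_rna, rank_ihc, rank_prot1,
#'   rank_prot2, rank_rna, rank_sum, final_rank; ordered by final_rank.
#' @export
rank_normal_tissue <- function(candidates, ihc_panel, prot_panel_1,
                               prot_panel_2, rna_panel,
                               missing = c("best", "worst", "exclude")) {
  missing <- match.arg(missing)
  .check(length(candidates) > 0, "no candidates to rank")
  .check(!anyDuplicated(candidates), "duplicate candidate ids")
  panels <- list(ihc_panel, prot_panel_1, prot_panel_2, rna_panel)
  present <- Reduce(`|`, lapply(panels, function(p) candidates %in% rownames(p)))
  .check(all(present), "candidates absent from every panel")

  if (missing == "exclude") {
    in_all <- Reduce(`&`, lapply(panels,
                                 function(p) candidates %in% rownames(p)))
    candidates <- candidates[in_all]
    .check(length(candidates) > 0, "no candidate present in all panels")
  }

  panel_values <- function(panel, fun, fill) {
    v <- rep(fill, length(candidates))
    hit <- candidates %in% rownames(panel)
    v[hit] <- apply(panel[candidates[hit], , drop = FALSE], 1, fun)
    if (any(!hit)) {
      warning(sprintf("%d candidate(s) absent from a panel; scored as '%s'",
                      sum(!hit), missing))
    }
    v
  }
  fill_prop <- if (missing == "worst") 0 else 1     # proportion undetected
  fill_med <- if (missing == "worst") Inf else 0    # median abundance
  undet <- panel_values(ihc_panel, function(r) mean(r == 0), fill_prop)
  med1 <- panel_values(prot_panel_1, stats::median, fill_med)
  med2 <- panel_values(prot_panel_2, stats::median, fill_med)
  medr <- panel_values(rna_panel, stats::median, fill_med)

  out <- data.frame(protein = candidates,
                    ihc_undetected = undet,
                    median_prot1 = med1, median_prot2 = med2,
                    median_rna = medr,
                    rank_ihc = .avg_rank(undet, -1),
                    rank_prot1 = .avg_rank(med1, 1),
                    rank_prot2 = .avg_rank(med2, 1),
                    rank_rna = .avg_rank(medr, 1),
                    stringsAsFactors = FALSE)
  out$rank_sum <- out$rank_ihc + out$rank_prot1 + out$rank_prot2 +
    out$rank_rna
  ord <- order(out$rank_sum, out$protein)
  out <- out[ord, , drop = FALSE]
  out$final_rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("candidate_ranking", "data.frame")
  out
}

#' Run the full candidate-mining funnel
#'
#' surface filter -> cancer-panel exclusivity -> antibody availability ->
#' normal-tissue rank-sum prioritization, with per-stage survivor counts.
#' An empty survivor set at any stage yields a valid empty report.
#'
#' @param pm_calls Logical protein x cell line call matrix.
#' @param bundle An `annotation_bundle`.
#' @param panels Named list with `ihc`, `prot_a`, `prot_b`, `rna` matrices.
#' @param gs_min,spc_min,min_lines,max_cancer_lines Funnel thresholds
#'   (all inclusive).
#' @param missing Passed to [rank_normal_tissue()].
#' @return List of class `funnel_report`: `stage_counts` (named integer
#'   vector), `stages` (survivor id lists), `ranking` (a
#'   `candidate_ranking` or NULL if empty).
#' @export
run_funnel <- function(pm_calls, bundle, panels, gs_min = 20, spc_min = 3,
                       min_lines = 2L, max_cancer_lines = 5L,
                       missing = "best") {
  .check(inherits(bundle, "annotation_bundle"),
         "`bundle` must be an annotation_bundle")
  .check(all(c("ihc", "prot_a", "prot_b", "rna") %in% names(panels)),
         "`panels` must contain ihc, prot_a, prot_b, rna")
  s1 <- surface_filter(pm_calls, bundle, gs_min, spc_min, min_lines)
  s2 <- exclusivity_filter(s1, bundle$cancer_detection, max_cancer_lines)
  s3 <- antibody_filter(s2, bundle$annotations)
  ranking <- if (length(s3) > 0) {
    rank_normal_tissue(s3, panels$ihc, panels$prot_a, panels$prot_b,
                       panels$rna, missing = missing)
  } else {
    NULL
  }
  structure(list(
    stage_counts = c(surface = length(s1), exclusivity = length(s2),
                     antibody = length(s3),
                     ranked = if (is.null(ranking)) 0L else nrow(ranking)),
    stages = list(surface = s1, exclusivity = s2, antibody = s3),
    ranking = ranking), class = "funnel_report")
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("Candidate-mining funnel\n")
  cat(sprintf("  surface filter: %d -> exclusivity: %d -> antibody: %d\n",
              x$stage_counts["surface"], x$stage_counts["exclusivity"],
              x$stage_counts["antibody"]))
  if (!is.null(x$ranking) && nrow(x$ranking) > 0) {
    top <- utils::head(x$ranking, 3)
    cat("  top candidates (rank_sum):",
        paste(sprintf("%s (%g)", top$protein, top$rank_sum),
              collapse = ", "), "\n")
  } else {
    cat("  no candidates survived to ranking\n")
  }
  invisible(x)
}
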