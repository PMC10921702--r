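#' Welch's unequal-variance t-test
#'
#' Two-sided unpaired Welch test with Satterthwaite degrees of freedom. When
#' both groups have zero variance and equal means the p-value is 1 by
#' contract (no evidence of difference).
#'
#' @param a,b Numeric vectors of replicate values (length >= 2 each).
#' @return List: `t`, `df`, `p`.
#' @examples
#' welch_t(c(1, 2, 3), c(2, 3, 4))
#' @export
welch_t <- function(a, b) {
  .check(length(a) >= 2 && length(b) >= 2,
         "each group needs at least 2 values")
  n1 <- length(a); n2 <- length(b)
  m1 <- mean(a); m2 <- mean(b)
  v1 <- stats::var(a); v2 <- stats::var(b)
  se2 <- v1 / n1 + v2 / n2
  if (se2 == 0) {
    return(list(t = 0, df = n1 + n2 - 2,
                p = if (m1 == m2) 1 else 0))
  }
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = tstat, df = df, p = 2 * stats::pt(-abs(tstat), df))
}

# Vectorized Welch over rows of two matrices (one test per protein).
welch_t_rows <- function(a, b) {
  n1 <- ncol(a); n2 <- ncol(b)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- rowSums((a - m1)^2) / (n1 - 1)
  v2 <- rowSums((b - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  degenerate <- se2 == 0
  if (any(degenerate)) {
    tstat[degenerate] <- 0
    df[degenerate] <- n1 + n2 - 2
    p[degenerate] <- ifelse(m1[degenerate] == m2[degenerate], 1, 0)
  }
  list(t = tstat, df = df, p = p, log2fc = m1 - m2)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusted p-values `q(i) = min_{j >= i} p(j) * n / j` over the sorted
#' vector, clipped at 1 and returned in the input order. Guarantees
#' `q >= p` elementwise and monotonicity in sorted-p order.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, same length and order as the input.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(pvals) {
  .check(is.numeric(pvals) && all(pvals >= 0 & pvals <= 1, na.rm = FALSE),
         "p-values must lie in [0, 1]")
  n <- length(pvals)
  if (n == 0) return(numeric(0))
  ord <- order(pvals)
  ranked <- pvals[ord] * n / seq_len(n)
  q_sorted <- rev(cummin(rev(ranked)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(n)
  q[ord] <- q_sorted
  q
}

#' Subtractive plasma-membrane enrichment analysis
#'
#' The subtractive-proteomics core: separately within each cell line, the PM
#' (silica-bead) fraction replicates are tested against every other
#' organelle fraction with Welch's t-test; p-values are BH-adjusted across
#' proteins within each (cell line, fraction pair) family. A protein is
#' called PM-enriched in a cell line when `q < fdr` and the signed log2 fold
#' change toward PM exceeds `min_log2fc` against EVERY non-PM fraction.
#'
#' @param ds An imputed [quant_dataset].
#' @param fdr BH-adjusted significance cutoff (default 0.05).
#' @param min_log2fc Minimum signed log2 fold change toward PM (default 1).
#' @param bh_family `"per_comparison"` (default: adjust within each cell
#'   line x fraction pair) or `"per_cell_line"` (pool all fraction pairs of
#'   a cell line into one family).
#' @return List of class `enrichment_result`:
#'   \describe{
#'     \item{table}{Data frame: protein, cell_line, fraction_vs, log2fc, p, q.}
#'     \item{calls}{Logical protein x cell line matrix of PM calls.}
#'     \item{n_comparisons_passed}{Integer protein x cell line matrix.}
#'     \item{skipped_cell_lines}{Cell lines lacking a required fraction.}
#'   }
#' @export
run_subtractive <- function(ds, fdr = 0.05, min_log2fc = 1.0,
                            bh_family = c("per_comparison", "per_cell_line")) {
  .check(inherits(ds, "quant_dataset"), "`ds` must be a quant_dataset")
  .check(!anyNA(ds$values), "run_subtractive requires an imputed dataset")
  bh_family <- match.arg(bh_family)
  pm <- ds$pm_fraction
  fractions <- unique(ds$samples$fraction)
  nonpm <- setdiff(fractions, pm)
  lines <- unique(ds$samples$cell_line)
  proteins <- ds$proteins

  cols_of <- function(line, fraction) {
    which(ds$samples$cell_line == line & ds$samples$fraction == fraction)
  }
  skipped <- character(0)
  recs <- list()
  calls <- matrix(NA, length(proteins), length(lines),
                  dimnames = list(proteins, lines))
  npass <- matrix(NA_integer_, length(proteins), length(lines),
                  dimnames = list(proteins, lines))

  for (line in lines) {
    pm_cols <- cols_of(line, pm)
    other_cols <- lapply(nonpm, function(f) cols_of(line, f))
    if (length(pm_cols) < 2 || any(vapply(other_cols, length, 1L) < 2)) {
      warning(sprintf("cell line '%s' lacks >= 2 replicates of every fraction; skipped",
                      line))
      skipped <- c(skipped, line)
      next
    }
    a <- ds$values[, pm_cols, drop = FALSE]
    line_recs <- lapply(seq_along(nonpm), function(i) {
      w <- welch_t_rows(a, ds$values[, other_cols[[i]], drop = FALSE])
      data.frame(protein = proteins, cell_line = line,
                 fraction_vs = nonpm[i], log2fc = w$log2fc, p = w$p,
                 stringsAsFactors = FALSE)
    })
    if (bh_family == "per_comparison") {
      line_recs <- lapply(line_recs, function(d) {
        d$q <- bh_adjust(d$p)
        d
      })
      line_tab <- do.call(rbind, line_recs)
    } else {
      line_tab <- do.call(rbind, line_recs)
      line_tab$q <- bh_adjust(line_tab$p)
    }
    pass <- line_tab$q < fdr & line_tab$log2fc > min_log2fc
    np <- rowSums(matrix(pass, nrow = length(proteins)))
    npass[, line] <- as.integer(np)
    calls[, line] <- np == length(nonpm)
    recs[[line]] <- line_tab
  }
  .check(length(recs) > 0, "no cell line had complete fraction coverage")
  structure(list(table = do.call(rbind, c(recs, make.row.names = FALSE)),
                 calls = calls[, setdiff(lines, skipped), drop = FALSE],
                 n_comparisons_passed = npass[, setdiff(lines, skipped),
                                              drop = FALSE],
                 fdr = fdr, min_log2fc = min_log2fc,
                 skipped_cell_lines = skipped),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  per_line <- colSums(x$calls)
  cat(sprintf("Subtractive PM enrichment: %d proteins x %d cell lines (FDR < %g, log2FC > %g)\n",
              nrow(x$calls), ncol(x$calls), x$fdr, x$min_log2fc))
  cat("  PM calls per cell line:",
      paste(sprintf("%s = %d", names(per_line), per_line), collapse = ", "),
      "\n")
  cat(sprintf("  proteins called in >= 1 line: %d; in >= 2 lines: %d\n",
              sum(rowSums(x$calls) >= 1), sum(rowSums(x$calls) >= 2)))
  invisible(x)
}

#' Evaluate PM calls against planted ground truth
#'
#' A protein counts as PM-called when it is called in at least `min_lines`
#' cell lines (default 1, the unit used for null-calibration checks).
#'
#' @param result An `enrichment_result`.
#' @param truth A `ground_truth` with `pm_protein_ids`.
#' @param min_lines Minimum cell lines for a protein-level call.
#' @return List: `sensitivity`, `fdp`, `n_called`, `per_line_sensitivity`.
#' @export
evaluate_pm_calls <- function(result, truth, min_lines = 1L) {
  .check(inherits(result, "enrichment_result"),
         "`result` must come from run_subtractive()")
  called <- rownames(result$calls)[rowSums(result$calls) >= min_lines]
  planted <- truth$pm_protein_ids
  sens <- if (length(planted)) mean(planted %in% called) else NA_real_
  fdp <- if (length(called)) mean(!called %in% planted) else 0
  per_line <- colMeans(result$calls[rownames(result$calls) %in% planted, ,
                                    drop = FALSE])
  list(sensitivity = sens, fdp = fdp, n_called = length(called),
       per_line_sensitivity = per_line)
}
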