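#' Principal component analysis of fraction proteomes
#'
#' Projects samples onto the principal axes of the protein-centered log2
#' abundance matrix. Used to check that samples separate by organelle
#' fraction rather than by cell line.
#'
#' @param ds An imputed [quant_dataset] (no missing values).
#' @param n_components Number of components to return.
#' @return List of class `pca_result`: `scores` (sample x component matrix),
#'   `explained` (variance ratios, non-increasing, summing to <= 1),
#'   `samples` (metadata).
#' @export
pca_samples <- function(ds, n_components = 5L) {
  .check(inherits(ds, "quant_dataset"), "`ds` must be a quant_dataset")
  .check(!anyNA(ds$values), "PCA requires an imputed (complete) dataset")
  x <- t(ds$values)  # samples x proteins; centering is per protein
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > max(pc$sdev) * 1e-12)
  .check(n_components <= rank,
         sprintf("n_components (%d) exceeds matrix rank (%d)", n_components,
                 rank))
  explained <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = pc$x[, seq_len(n_components), drop = FALSE],
                 explained = explained[seq_len(n_components)],
                 samples = ds$samples),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("PCA of %d samples: %d components, explained %s\n",
              nrow(x$scores), ncol(x$scores),
              paste(sprintf("%.1f%%", 100 * x$explained), collapse = ", ")))
  invisible(x)
}

#' Mean silhouette width of a sample grouping
#'
#' Computes the mean silhouette width of samples in PCA score space under a
#' given grouping (e.g. fraction or cell line). Higher values mean the
#' grouping explains the sample geometry better.
#'
#' @param pca A `pca_result` from [pca_samples()].
#' @param labels Grouping vector, one entry per sample (or the name of a
#'   column of the sample metadata).
#' @return Mean silhouette width (scalar).
#' @export
group_silhouette <- function(pca, labels) {
  .check(inherits(pca, "pca_result"), "`pca` must come from pca_samples()")
  if (is.character(labels) && length(labels) == 1L) {
    .check(labels %in% names(pca$samples), "unknown metadata column")
    labels <- pca$samples[[labels]]
  }
  .check(length(labels) == nrow(pca$scores),
         "one label per sample required")
  sil <- cluster::silhouette(as.integer(factor(labels)),
                             stats::dist(pca$scores))
  mean(sil[, "sil_width"])
}

#' Row z-score a matrix
#'
#' Centers and scales each row to mean 0, SD 1. Constant rows (zero
#' variance) are set to 0 rather than NaN so that every protein stays in the
#' clustering.
#'
#' @param m Numeric matrix.
#' @return The z-scored matrix.
#' @export
zscore_rows <- function(m) {
  mu <- rowMeans(m)
  s <- sqrt(rowSums((m - mu)^2) / (ncol(m) - 1))
  z <- (m - mu) / ifelse(s == 0, 1, s)
  z[s == 0, ] <- 0
  z
}

#' Hierarchical clustering of proteins into compartment clusters
#'
#' Row z-scores the abundance matrix, then applies agglomerative clustering
#' (Ward linkage on Euclidean distances by default) cut at `k` clusters.
#' Deterministic for fixed input.
#'
#' @param ds An imputed [quant_dataset].
#' @param k Number of clusters (>= 2; the default 4 reflects the four major
#'   compartment classes these fractionations resolve).
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @param z_clip Winsorization bound for the distance computation: z-scores
#'   are clipped to `[-z_clip, z_clip]` before Euclidean distances, so that
#'   the extreme spikes left by low-value imputation of dropout do not
#'   dominate a protein's profile (the same saturation a heatmap color
#'   scale applies). `Inf` disables clipping. The returned `zmatrix` is
#'   unclipped.
#' @return List of class `cluster_result`: `cluster_of` (named integer
#'   vector), `linkage` (the `hclust` object), `zmatrix`.
#' @export
cluster_proteins <- function(ds, k = 4L, linkage = "ward.D2", z_clip = 3) {
  .check(inherits(ds, "quant_dataset"), "`ds` must be a quant_dataset")
  .check(!anyNA(ds$values), "clustering requires an imputed dataset")
  .check(k >= 2, "`k` must be at least 2")
  .check(k <= nrow(ds$values), "`k` exceeds the number of proteins")
  .check(z_clip > 0, "`z_clip` must be positive")
  z <- zscore_rows(ds$values)
  hc <- stats::hclust(stats::dist(pmin(pmax(z, -z_clip), z_clip)),
                      method = linkage)
  cl <- stats::cutree(hc, k = k)
  names(cl) <- rownames(ds$values)
  structure(list(cluster_of = cl, linkage = hc, zmatrix = z, k = k),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: %d proteins in %d clusters (sizes: %s)\n",
              length(x$cluster_of), x$k,
              paste(tabulate(x$cluster_of, x$k), collapse = ", ")))
  invisible(x)
}

#' Summarize annotation composition per cluster
#'
#' For each cluster, counts and fractions of proteins carrying each logical
#' annotation flag (surface, nuclear, ...). Annotation rows for unknown
#' proteins are ignored with a warning.
#'
#' @param result A `cluster_result`.
#' @param annotations Data frame with a `protein` column and one or more
#'   logical flag columns.
#' @return Data frame: cluster, n, then `<flag>_count` / `<flag>_fraction`
#'   per flag.
#' @export
summarize_cluster_annotations <- function(result, annotations) {
  .check(inherits(result, "cluster_result"),
         "`result` must come from cluster_proteins()")
  .check("protein" %in% names(annotations),
         "`annotations` needs a 'protein' column")
  unknown <- setdiff(annotations$protein, names(result$cluster_of))
  if (length(unknown) > 0) {
    warning(sprintf("ignoring %d annotation rows for unknown proteins",
                    length(unknown)))
    annotations <- annotations[!annotations$protein %in% unknown, ,
                               drop = FALSE]
  }
  flags <- names(annotations)[vapply(annotations, is.logical, TRUE)]
  ks <- sort(unique(result$cluster_of))
  out <- data.frame(cluster = ks,
                    n = as.integer(tabulate(result$cluster_of,
                                            max(result$cluster_of))[ks]))
  idx <- match(annotations$protein, names(result$cluster_of))
  for (fl in flags) {
    cnt <- vapply(ks, function(k) {
      sum(annotations[[fl]][result$cluster_of[idx] == k], na.rm = TRUE)
    }, 0)
    out[[paste0(fl, "_count")]] <- as.integer(cnt)
    out[[paste0(fl, "_fraction")]] <- ifelse(out$n > 0, cnt / out$n, 0)
  }
  out
}
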