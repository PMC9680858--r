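#' Hierarchical clustering of samples
#'
#' Clusters the samples of a log2-scale expression matrix with Ward linkage on
#' Euclidean distances between full gene vectors (no gene pre-filtering). The
#' `ward.D2` method operates on the distances themselves and matches the usual
#' Ward/Euclidean convention of scientific Python's linkage routine.
#'
#' @param m Log2-scale `expr_matrix` with at least two samples.
#' @return An [stats::hclust] object; leaves are sample IDs, merge heights are
#'   non-decreasing.
#' @export
sample_clustering <- function(m) {
  if (expr_scale(m) != "log2") {
    coex_abort("Clustering expects a log2-scale matrix; run log_transform() first.",
               class = "coexnet_scale_error")
  }
  if (ncol(m) < 2L) coex_abort("Need at least two samples to cluster.")
  if (any(!is.finite(m))) coex_abort("Non-finite values in matrix.",
                                     class = "coexnet_value_error")
  hclust(dist(t(unclass(m)), method = "euclidean"), method = "ward.D2")
}

#' Principal component analysis of samples
#'
#' PCA on samples in gene space: per-gene mean centering, no unit-variance
#' scaling. The sign of each component is fixed by forcing its
#' largest-magnitude gene loading to be positive, making coordinates
#' deterministic across platforms.
#'
#' @param m Log2-scale `expr_matrix`.
#' @param k Number of components, `1 <= k <= min(genes, samples)`.
#' @return A `coex_pca` list: `scores` (tibble of `sample_id` and `PC1..PCk`),
#'   `explained_variance` (fractions, non-increasing), `loadings`
#'   (gene x k matrix), `k`.
#' @export
sample_pca <- function(m, k = 2L) {
  if (expr_scale(m) != "log2") {
    coex_abort("PCA expects a log2-scale matrix; run log_transform() first.",
               class = "coexnet_scale_error")
  }
  if (!is.numeric(k) || length(k) != 1L || k <= 0 || k != round(k)) {
    coex_abort("`k` must be a positive integer.")
  }
  k <- as.integer(k)
  if (k > min(dim(m))) {
    coex_abort(sprintf("`k` = %d exceeds min(genes, samples) = %d.", k, min(dim(m))))
  }
  fit <- prcomp(t(unclass(m)), center = TRUE, scale. = FALSE)
  keep <- seq_len(k)
  rot <- fit$rotation[, keep, drop = FALSE]
  scores <- fit$x[, keep, drop = FALSE]
  # deterministic sign: largest-|loading| gene positive on each axis
  flip <- vapply(seq_len(k), function(j) {
    l <- rot[, j]
    sign(l[which.max(abs(l))]) < 0
  }, logical(1))
  rot[, flip] <- -rot[, flip, drop = FALSE]
  scores[, flip] <- -scores[, flip, drop = FALSE]
  ev <- fit$sdev^2 / sum(fit$sdev^2)
  structure(list(
    scores = dplyr::bind_cols(tibble(sample_id = colnames(m)),
                              as_tibble(scores, .name_repair = "minimal")),
    explained_variance = ev[keep],
    loadings = rot,
    k = k
  ), class = "coex_pca")
}

#' @export
print.coex_pca <- function(x, ...) {
  cat(sprintf("<coex_pca> %d components; explained variance: %s\n", x$k,
              toString(sprintf("%.1f%%", 100 * x$explained_variance))))
  print(x$scores)
  invisible(x)
}

#' @rdname sample_pca
#' @param x A `coex_pca` object.
#' @param ... Unused.
#' @export
#' @exportS3Method generics::tidy
tidy.coex_pca <- function(x, ...) x$scores

#' @rdname sample_pca
#' @export
#' @exportS3Method generics::glance
glance.coex_pca <- function(x, ...) {
  tibble(component = paste0("PC", seq_len(x$k)),
         explained_variance = x$explained_variance)
}
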