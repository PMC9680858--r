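#' Median-of-ratios size factors
#'
#' Per-sample normalization constants: each gene with positive counts in all
#' samples contributes the ratio of its count to its geometric mean across
#' samples, and a sample's factor is the median of these ratios. Factors are
#' equivariant: scaling one sample's counts by c scales its factor by c.
#'
#' @param counts `count_matrix`.
#' @param pseudo_reference When no gene has positive counts in every sample
#'   (common with many zero-inflated libraries), set `TRUE` to build the
#'   geometric-mean reference from each gene's positive counts only.
#' @return Named numeric vector of positive size factors, one per sample.
#' @export
size_factors <- function(counts, pseudo_reference = FALSE) {
  cts <- unclass(counts)
  all_pos <- rowSums(cts > 0) == ncol(cts)
  if (!any(all_pos) && !pseudo_reference) {
    coex_abort(paste("No gene has positive counts in every sample;",
                     "re-run with `pseudo_reference = TRUE`."),
               class = "coexnet_value_error")
  }
  if (pseudo_reference) {
    log_gm <- apply(cts, 1L, function(x) mean(log(x[x > 0])))
    use <- is.finite(log_gm)
  } else {
    log_gm <- rowMeans(log(cts))
    use <- all_pos
  }
  ratios <- log(cts[use, , drop = FALSE]) - log_gm[use]
  sf <- apply(ratios, 2L, function(r) exp(median(r[is.finite(r)])))
  if (any(!is.finite(sf) | sf <= 0)) {
    coex_abort("Degenerate size factor; counts too sparse to normalize.",
               class = "coexnet_value_error")
  }
  setNames(sf, colnames(cts))
}

#' Gene-wise NB dispersion by the method of moments
#'
#' Estimates a single dispersion per gene from size-factor-normalized counts,
#' pooling variance within replicate groups:
#' `alpha = max((pooled_var - pooled_mean) / pooled_mean^2, 1e-8)`.
#' Genes at or below the Poisson variance land on the floor. Each group must
#' have at least three replicates for the pooled variance to be meaningful.
#'
#' @param counts `count_matrix`.
#' @param groups Character/factor vector assigning each sample (column) to a
#'   group.
#' @param sf Size factors from [size_factors()]; computed if missing.
#' @return Named numeric vector of dispersions (>= 1e-8), one per gene.
#' @export
estimate_dispersions <- function(counts, groups, sf = NULL) {
  cts <- unclass(counts)
  if (length(groups) != ncol(cts)) {
    coex_abort("`groups` must assign every sample to a group.")
  }
  sizes <- table(groups)
  if (any(sizes < 3L)) {
    coex_abort(sprintf(
      "Group(s) with fewer than 3 replicates: %s. Differential analysis requires >= 3 biological replicates per group.",
      toString(names(sizes)[sizes < 3L])), class = "coexnet_replicate_error")
  }
  sf <- sf %||% size_factors(counts)
  norm <- sweep(cts, 2L, sf, "/")
  pooled_mean <- rowMeans(norm)
  ss <- 0
  for (g in unique(groups)) {
    sub <- norm[, groups == g, drop = FALSE]
    ss <- ss + rowSums((sub - rowMeans(sub))^2)
  }
  pooled_var <- ss / (ncol(norm) - length(unique(groups)))
  alpha <- (pooled_var - pooled_mean) / pooled_mean^2
  alpha[!is.finite(alpha)] <- 0
  setNames(pmax(alpha, 1e-8), rownames(cts))
}

# vectorized two-column IRLS for the NB GLM  log mu = offset + b0 + b1 * x
# with fixed per-gene dispersion; returns coefficients, SEs and convergence
nb_irls <- function(cts, offset, x, alpha, max_iter = 50L, tol = 1e-8) {
  ng <- nrow(cts)
  nsamp <- ncol(cts)
  # moment start: log of group means of offset-corrected counts
  adj <- sweep(cts, 2L, exp(offset), "/")
  m1 <- rowMeans(adj[, x == 0, drop = FALSE])
  m2 <- rowMeans(adj[, x == 1, drop = FALSE])
  overall <- rowMeans(adj)
  b0 <- log(pmax(m1, overall * 0.1, 1e-8))
  b1 <- log(pmax(m2, 1e-8)) - b0
  converged <- rep(FALSE, ng)
  active <- rep(TRUE, ng)
  for (iter in seq_len(max_iter)) {
    if (!any(active)) break
    eta <- outer(b0, rep(1, nsamp)) + outer(b1, x) +
      matrix(offset, ng, nsamp, byrow = TRUE)
    eta <- pmin(eta, 30)            # cap to keep mu finite
    mu <- pmax(exp(eta), 1e-10)
    w <- mu / (1 + alpha * mu)      # NB working weights, log link
    z <- eta - matrix(offset, ng, nsamp, byrow = TRUE) + (cts - mu) / mu
    sw <- rowSums(w)
    swx <- rowSums(w * matrix(x, ng, nsamp, byrow = TRUE))
    swxx <- rowSums(w * matrix(x^2, ng, nsamp, byrow = TRUE))
    swz <- rowSums(w * z)
    swxz <- rowSums(w * z * matrix(x, ng, nsamp, byrow = TRUE))
    det <- sw * swxx - swx^2
    det[det <= 0] <- NA_real_
    nb0 <- (swxx * swz - swx * swxz) / det
    nb1 <- (sw * swxz - swx * swz) / det
    step_ok <- is.finite(nb0) & is.finite(nb1) & active
    delta <- pmax(abs(nb0 - b0), abs(nb1 - b1)) /
      pmax(pmax(abs(b0), abs(b1)), 1)
    b0[step_ok] <- nb0[step_ok]
    b1[step_ok] <- nb1[step_ok]
    newly <- step_ok & delta < tol
    converged[newly] <- TRUE
    active <- active & !newly & step_ok
  }
  # expected information at the solution for the Wald SE of b1
  eta <- outer(b0, rep(1, nsamp)) + outer(b1, x) +
    matrix(offset, ng, nsamp, byrow = TRUE)
  mu <- pmax(exp(pmin(eta, 30)), 1e-10)
  w <- mu / (1 + alpha * mu)
  sw <- rowSums(w)
  swx <- rowSums(w * matrix(x, ng, nsamp, byrow = TRUE))
  swxx <- rowSums(w * matrix(x^2, ng, nsamp, byrow = TRUE))
  det <- sw * swxx - swx^2
  se_b1 <- sqrt(sw / det)
  list(b0 = b0, b1 = b1, se_b1 = se_b1, converged = converged)
}

#' Two-group negative-binomial Wald test
#'
#' The differential-expression stage: for two replicate groups it computes
#' median-of-ratios size factors on the selected samples only, moment
#' dispersions, fits a per-gene NB GLM with log link (intercept + group
#' indicator, log size factors as offsets) by iteratively reweighted least
#' squares, and tests the group coefficient with a Wald statistic from the
#' expected information, referred to a t distribution with `n - 2` residual
#' degrees of freedom (the dispersion is estimated from few replicates, so a
#' normal reference would be anticonservative at typical replicate counts).
#' P-values are BH-adjusted across all tested genes; genes with
#' zero counts in every selected sample are skipped, and non-converged fits
#' get `NA` p-values and are excluded from the BH family. This is a
#' deliberately simple stage — no dispersion shrinkage, outlier handling, or
#' independent filtering.
#'
#' @param counts `count_matrix`.
#' @param samples [sample_table()] covering the counts' columns.
#' @param group1,group2 The two group labels to compare (log2 fold changes
#'   are group2 relative to group1); each needs >= 3 replicates.
#' @param dispersions Optional named per-gene dispersions; estimated by
#'   [estimate_dispersions()] when `NULL`.
#' @param alpha Significance threshold used for volcano classification.
#' @param lfc_threshold Absolute log2-fold-change threshold for
#'   classification.
#' @return A `deg_result` tibble: `gene_id`, `base_mean`, `log2fc`, `se`,
#'   `wald_z`, `p`, `padj`, `class` (`up` / `down` / `ns`), plus skipped
#'   all-zero genes and the comparison recorded as attributes.
#' @export
nb_wald <- function(counts, samples, group1, group2, dispersions = NULL,
                    alpha = 0.05, lfc_threshold = 0) {
  grp_all <- samples$group[match(colnames(counts), samples$sample_id)]
  if (anyNA(grp_all)) {
    coex_abort("Every count column must appear in the sample table.")
  }
  for (g in c(group1, group2)) {
    if (!g %in% grp_all) coex_abort(sprintf("Group '%s' has no samples.", g))
  }
  sel <- grp_all %in% c(group1, group2)
  cts <- unclass(counts)[, sel, drop = FALSE]
  grp <- grp_all[sel]
  sizes <- table(grp)
  if (any(sizes < 3L)) {
    coex_abort(sprintf(
      "Group(s) with fewer than 3 replicates: %s. Differential analysis requires >= 3 biological replicates per group.",
      toString(names(sizes)[sizes < 3L])), class = "coexnet_replicate_error")
  }
  nonzero <- rowSums(cts) > 0
  skipped <- rownames(cts)[!nonzero]
  cts <- cts[nonzero, , drop = FALSE]
  sf <- size_factors(count_matrix(cts))
  disp <- dispersions %||% estimate_dispersions(count_matrix(cts), grp, sf)
  disp <- disp[rownames(cts)]
  x <- as.numeric(grp == group2)
  fit <- nb_irls(cts, offset = log(sf), x = x, alpha = disp)
  norm <- sweep(cts, 2L, sf, "/")
  wald_z <- fit$b1 / fit$se_b1
  # t reference with residual df: the gene-wise dispersion is estimated from
  # few replicates, and treating it as known (normal reference) is
  # anticonservative at typical 3-5 replicate designs
  p <- 2 * stats::pt(-abs(wald_z), df = length(x) - 2L)
  p[!fit$converged] <- NA_real_
  padj <- rep(NA_real_, length(p))
  padj[!is.na(p)] <- bh_adjust(p[!is.na(p)])
  out <- tibble(
    gene_id = rownames(cts),
    base_mean = unname(rowMeans(norm)),
    log2fc = unname(fit$b1 / log(2)),
    se = unname(fit$se_b1 / log(2)),
    wald_z = unname(wald_z),
    p = unname(p),
    padj = unname(padj)
  )
  out <- classify(out, alpha = alpha, lfc_threshold = lfc_threshold)
  attr(out, "skipped_genes") <- skipped
  attr(out, "comparison") <- c(group1 = group1, group2 = group2)
  attr(out, "alpha") <- alpha
  attr(out, "lfc_threshold") <- lfc_threshold
  out
}

#' Volcano classification of DE results
#'
#' Labels each gene `up` (padj < alpha and log2fc > lfc_threshold), `down`
#' (padj < alpha and log2fc < -lfc_threshold), or `ns`, and attaches the
#' `-log10(padj)` column used by volcano plots.
#'
#' @param results Tibble with `log2fc` and `padj` columns (e.g. from
#'   [nb_wald()]).
#' @param alpha Adjusted-p threshold (strict); default 0.05.
#' @param lfc_threshold Absolute log2 fold-change threshold; default 0.
#' @return The input with `class` and `neg_log10_padj` columns; class
#'   `deg_result`.
#' @export
classify <- function(results, alpha = 0.05, lfc_threshold = 0) {
  assert_scalar_number(alpha, "alpha", 0, 1)
  assert_scalar_number(lfc_threshold, "lfc_threshold", lower = 0)
  cls <- rep("ns", nrow(results))
  sig <- !is.na(results$padj) & results$padj < alpha
  cls[sig & results$log2fc > lfc_threshold] <- "up"
  cls[sig & results$log2fc < -lfc_threshold] <- "down"
  results$class <- cls
  results$neg_log10_padj <- -log10(results$padj)
  class(results) <- unique(c("deg_result", class(results)))
  results
}

#' @rdname nb_wald
#' @param x A `deg_result`.
#' @param ... Unused.
#' @export
#' @exportS3Method generics::glance
glance.deg_result <- function(x, ...) {
  tibble(n_tested = if ("p" %in% names(x)) sum(!is.na(x$p)) else sum(!is.na(x$padj)),
         n_skipped = length(attr(x, "skipped_genes") %||% character()),
         n_up = sum(x$class == "up"),
         n_down = sum(x$class == "down"),
         alpha = attr(x, "alpha") %||% NA_real_,
         lfc_threshold = attr(x, "lfc_threshold") %||% NA_real_)
}

#' Write DE results as CSV files
#'
#' Writes the full table plus separate `up` and `down` gene lists, mirroring
#' the usual downloadable outputs of a DE analysis.
#'
#' @param results `deg_result`.
#' @param prefix Output path prefix; files `<prefix>_all.csv`,
#'   `<prefix>_up.txt`, `<prefix>_down.txt` are written.
#' @return Character vector of the written paths, invisibly.
#' @export
write_deg_results <- function(results, prefix) {
  paths <- c(all = paste0(prefix, "_all.csv"),
             up = paste0(prefix, "_up.txt"),
             down = paste0(prefix, "_down.txt"))
  readr::write_csv(results[c("gene_id", "log2fc", "p", "padj", "class")],
                   paths[["all"]], progress = FALSE)
  readr::write_lines(results$gene_id[results$class == "up"], paths[["up"]])
  readr::write_lines(results$gene_id[results$class == "down"], paths[["down"]])
  invisible(paths)
}
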