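#' Volcano plot of differential-expression results
#'
#' @param object `deg_result` from [nb_wald()] / [classify()].
#' @param ... Unused.
#' @return A ggplot: log2 fold change against -log10 adjusted p, colored by
#'   class (up red, down blue, ns black).
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.deg_result <- function(object, ...) {
  dat <- object[!is.na(object$padj), , drop = FALSE]
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$log2fc, y = .data$neg_log10_padj,
                                    color = .data$class)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_color_manual(values = c(up = "#d62728", down = "#1f77b4",
                                           ns = "black")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 adjusted p",
                  color = NULL) +
    ggplot2::theme_minimal()
}

#' PCA scatter of samples
#'
#' @param object `coex_pca` from [sample_pca()].
#' @param groups Optional named vector or [sample_table()] used to color
#'   samples.
#' @param ... Unused.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.coex_pca <- function(object, groups = NULL, ...) {
  dat <- object$scores
  if (inherits(groups, "data.frame")) {
    dat$group <- groups$group[match(dat$sample_id, groups$sample_id)]
  } else if (!is.null(groups)) {
    dat$group <- unname(groups[dat$sample_id])
  }
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$explained_variance[1L]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$explained_variance[2L])) +
    ggplot2::theme_minimal()
  if ("group" %in% names(dat)) {
    p + ggplot2::geom_point(ggplot2::aes(color = .data$group), size = 2)
  } else {
    p + ggplot2::geom_point(size = 2)
  }
}

#' Two-gene expression scatter
#'
#' @param object `pair_profile` from [pair_profile()].
#' @param ... Unused.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.pair_profile <- function(object, ...) {
  genes <- attr(object, "genes")
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$value_a, y = .data$value_b))
  if (any(!is.na(object$group))) {
    p <- p + ggplot2::geom_point(ggplot2::aes(color = .data$group), size = 2)
  } else {
    p <- p + ggplot2::geom_point(size = 2)
  }
  p + ggplot2::labs(x = genes[1L], y = genes[2L],
                    subtitle = sprintf("PCC = %.3f", attr(object, "pcc"))) +
    ggplot2::theme_minimal()
}

#' Enrichment bar plot
#'
#' @param object `enrichment_result` from [enrich()].
#' @param fdr_cutoff Show terms below this FDR; default 0.05.
#' @param top Maximum number of terms drawn.
#' @param ... Unused.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.enrichment_result <- function(object, fdr_cutoff = 0.05, top = 20L, ...) {
  dat <- head(object[!is.na(object$fdr) & object$fdr < fdr_cutoff, , drop = FALSE], top)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$study_count,
                                    y = stats::reorder(.data$name, -.data$fdr),
                                    fill = .data$fdr)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "study genes with term", y = NULL, fill = "FDR") +
    ggplot2::theme_minimal()
}

#' Per-group expression bar chart for one gene
#'
#' @param summary Group summary from [aggregate_by_group()].
#' @param gene Gene ID to display.
#' @return A ggplot with group means and SD error bars.
#' @export
plot_group_profile <- function(summary, gene) {
  dat <- summary[summary$gene_id == gene, , drop = FALSE]
  if (nrow(dat) == 0L) coex_abort(sprintf("Gene '%s' not in summary.", gene))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_col(fill = "#2ca02c") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.2) +
    ggplot2::labs(title = gene, x = NULL, y = "expression") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' UpSet-style bar chart of exclusive intersections
#'
#' @param object `set_relation` from [exclusive_intersections()].
#' @param ... Unused.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.set_relation <- function(object, ...) {
  dat <- object$regions
  dat$region <- factor(dat$region, levels = dat$region)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$region, y = .data$size)) +
    ggplot2::geom_col(fill = "#444444") +
    ggplot2::labs(x = "exclusive intersection", y = "genes") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
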