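#' Pairwise Pearson correlation with p-values
#'
#' Computes the gene-by-gene Pearson correlation matrix of a log2-scale
#' expression matrix over a chosen sample subset, together with two-sided
#' p-values from the exact t transform `t = r * sqrt((n - 2) / (1 - r^2))` on
#' n - 2 degrees of freedom. Genes with zero variance over the selected
#' samples have undefined correlations: their rows/columns are `NA` and they
#' are flagged.
#'
#' @param m Log2-scale `expr_matrix`.
#' @param sample_subset Optional character vector of sample IDs restricting
#'   the computation (a condition subset); at least 3 samples.
#' @return A `coex_correlation` list: `gene_ids`, `pcc` (symmetric, unit
#'   diagonal), `pvalue` (symmetric, zero diagonal by convention),
#'   `n_samples`, `zero_variance` (logical per gene).
#' @export
correlation_matrix <- function(m, sample_subset = NULL) {
  if (expr_scale(m) != "log2") {
    coex_abort("Correlation expects a log2-scale matrix; run log_transform() first.",
               class = "coexnet_scale_error")
  }
  vals <- unclass(m)
  if (!is.null(sample_subset)) {
    unknown <- setdiff(sample_subset, colnames(vals))
    if (length(unknown) > 0L) {
      coex_abort(sprintf("Unknown sample ID(s): %s.", toString(head(unknown))))
    }
    vals <- vals[, sample_subset, drop = FALSE]
  }
  n <- ncol(vals)
  if (n < 3L) coex_abort("Need at least 3 samples for correlation.",
                         class = "coexnet_value_error")
  zv <- apply(vals, 1L, function(x) var(x) == 0)
  pcc <- suppressWarnings(cor(t(vals), method = "pearson"))
  pcc[zv, ] <- NA_real_
  pcc[, zv] <- NA_real_
  diag(pcc) <- ifelse(zv, NA_real_, 1)
  # guard against |r| marginally above 1 from round-off
  pcc[!is.na(pcc) & pcc > 1] <- 1
  pcc[!is.na(pcc) & pcc < -1] <- -1
  tstat <- pcc * sqrt((n - 2) / pmax(1 - pcc^2, 0))
  pval <- 2 * pt(-abs(tstat), df = n - 2)
  pval[!is.na(pcc) & abs(pcc) == 1] <- 0
  diag(pval) <- ifelse(zv, NA_real_, 0)
  structure(list(gene_ids = rownames(vals), pcc = pcc, pvalue = pval,
                 n_samples = n, zero_variance = setNames(zv, rownames(vals))),
            class = "coex_correlation")
}

#' @export
print.coex_correlation <- function(x, ...) {
  cat(sprintf("<coex_correlation> %d genes over %d samples (%d zero-variance)\n",
              length(x$gene_ids), x$n_samples, sum(x$zero_variance)))
  invisible(x)
}

#' Co-expression ranks, HRR and MR
#'
#' For each gene A, every other gene B is ranked by descending correlation
#' with A (rank 1 = most correlated partner; a gene's rank against itself is
#' 0). Ties receive fractional (average) ranks, so scores are deterministic
#' and stable under gene relabeling. From the two directed ranks the
#' symmetric scores are
#' \deqn{HRR(A,B) = \max(rank_A(B), rank_B(A)), \quad
#'       MR(A,B) = \sqrt{rank_A(B) \cdot rank_B(A)}}
#' so `MR <= HRR` everywhere. Genes with undefined correlation to A are
#' ranked below every finite partner.
#'
#' @param correlation A `coex_correlation` from [correlation_matrix()] with at
#'   least 3 genes.
#' @return A `coex_scores` list: `gene_ids`, `rank` (directed, zero diagonal),
#'   `hrr` and `mr` (symmetric, zero diagonal).
#' @export
coexpression_scores <- function(correlation) {
  if (!inherits(correlation, "coex_correlation")) {
    coex_abort("`correlation` must come from correlation_matrix().")
  }
  pcc <- correlation$pcc
  ng <- nrow(pcc)
  if (ng < 3L) coex_abort("Need at least 3 genes to rank.",
                          class = "coexnet_value_error")
  rk <- matrix(0, ng, ng, dimnames = dimnames(pcc))
  for (i in seq_len(ng)) {
    row <- pcc[i, -i]
    if (all(is.na(row))) {
      coex_abort(sprintf("Gene '%s' has no defined correlations; cannot rank.",
                         rownames(pcc)[i]),
                 class = "coexnet_value_error")
    }
    row[is.na(row)] <- -Inf  # undefined partners sort below all finite PCCs
    rk[i, -i] <- rank(-row, ties.method = "average")
  }
  structure(list(gene_ids = correlation$gene_ids, rank = rk,
                 hrr = pmax(rk, t(rk)), mr = sqrt(rk * t(rk))),
            class = "coex_scores")
}

#' @export
print.coex_scores <- function(x, ...) {
  cat(sprintf("<coex_scores> %d genes; MR range [%.3g, %.3g] off-diagonal\n",
              length(x$gene_ids), min(x$mr[x$mr > 0]), max(x$mr)))
  invisible(x)
}

# collapse one namespace's descriptions per gene into a single string
collapse_annotation <- function(annotations, ns) {
  sub <- annotations[annotations$namespace == ns, , drop = FALSE]
  if (nrow(sub) == 0L) return(tibble(gene_id = character(), !!ns := character()))
  sub %>%
    group_by(.data$gene_id) %>%
    summarise(!!ns := paste(unique(.data$description), collapse = "; "),
              .groups = "drop")
}

#' Rank table of co-expressed genes
#'
#' Lists every gene whose Mutual Rank against the query falls below a cutoff,
#' sorted by ascending MR (ties broken by gene ID), optionally joined to gene
#' names and KOG/KEGG/Pfam descriptions.
#'
#' @param scores `coex_scores`.
#' @param correlation Matching `coex_correlation` (for the PCC column).
#' @param query_gene Gene ID to query.
#' @param mr_cutoff Keep genes with `mr < mr_cutoff` (strict); default 1000.
#' @param annotations Optional annotation table (see [annotation_table()]).
#' @return A tibble: `gene_id`, `name`, `hrr`, `mr`, `pcc`, and `kog` /
#'   `kegg` / `pfam` description columns when annotations are supplied.
#' @export
rank_table <- function(scores, correlation, query_gene, mr_cutoff = 1000,
                       annotations = NULL) {
  assert_scalar_number(mr_cutoff, "mr_cutoff", lower = 1e-12, allow_inf = TRUE)
  genes <- scores$gene_ids
  if (!query_gene %in% genes) {
    coex_abort(sprintf("Unknown gene '%s'. Did you mean: %s?", query_gene,
                       toString(near_matches(query_gene, genes))),
               class = "coexnet_unknown_gene")
  }
  mr <- scores$mr[query_gene, ]
  keep <- genes != query_gene & mr < mr_cutoff
  out <- tibble(
    gene_id = genes[keep],
    name = NA_character_,
    hrr = scores$hrr[query_gene, keep],
    mr = mr[keep],
    pcc = correlation$pcc[query_gene, keep]
  )
  if (!is.null(annotations)) {
    annotations <- annotation_table(annotations)
    nm <- collapse_annotation(annotations, "NAME") %>% rename(name2 = "NAME")
    out <- out %>%
      left_join(nm, by = "gene_id") %>%
      mutate(name = .data$name2) %>%
      select(-"name2") %>%
      left_join(collapse_annotation(annotations, "KOG") %>% rename(kog = "KOG"),
                by = "gene_id") %>%
      left_join(collapse_annotation(annotations, "KEGG") %>% rename(kegg = "KEGG"),
                by = "gene_id") %>%
      left_join(collapse_annotation(annotations, "Pfam") %>% rename(pfam = "Pfam"),
                by = "gene_id")
  }
  out <- arrange(out, .data$mr, .data$gene_id)
  attr(out, "query_gene") <- query_gene
  attr(out, "mr_cutoff") <- mr_cutoff
  out
}

#' Paired expression profile of two genes
#'
#' The data behind a two-gene scatter view: per-sample expression of both
#' genes with optional group labels, plus their Pearson correlation
#' (consistent with [correlation_matrix()]).
#'
#' @param m Log2-scale `expr_matrix`.
#' @param gene_a,gene_b Distinct gene IDs present in `m`.
#' @param samples Optional [sample_table()] supplying group labels.
#' @return A `pair_profile` tibble (`sample_id`, `group`, `value_a`,
#'   `value_b`) with `pcc` (NA when either gene has zero variance) and gene
#'   IDs as attributes.
#' @export
pair_profile <- function(m, gene_a, gene_b, samples = NULL) {
  if (identical(gene_a, gene_b)) coex_abort("The two genes must differ.")
  for (g in c(gene_a, gene_b)) {
    if (!g %in% rownames(m)) {
      coex_abort(sprintf("Unknown gene '%s'. Did you mean: %s?", g,
                         toString(near_matches(g, rownames(m)))),
                 class = "coexnet_unknown_gene")
    }
  }
  va <- unclass(m)[gene_a, ]
  vb <- unclass(m)[gene_b, ]
  pcc <- if (var(va) == 0 || var(vb) == 0) NA_real_ else cor(va, vb)
  grp <- if (is.null(samples)) NA_character_ else
    samples$group[match(colnames(m), samples$sample_id)]
  out <- tibble(sample_id = colnames(m), group = grp, value_a = va, value_b = vb)
  class(out) <- c("pair_profile", class(tibble()))
  attr(out, "pcc") <- pcc
  attr(out, "genes") <- c(gene_a, gene_b)
  out
}

#' Long-format co-expression scores
#'
#' @param x A `coex_scores` object.
#' @param ... Unused.
#' @return A tibble of unordered gene pairs with `hrr` and `mr`.
#' @export
#' @exportS3Method generics::tidy
tidy.coex_scores <- function(x, ...) {
  idx <- which(upper.tri(x$mr), arr.ind = TRUE)
  tibble(gene_a = x$gene_ids[idx[, 1L]], gene_b = x$gene_ids[idx[, 2L]],
         hrr = x$hrr[idx], mr = x$mr[idx])
}

#' Long-format correlation results
#'
#' @param x A `coex_correlation` object.
#' @param ... Unused.
#' @return A tibble of unordered gene pairs with `pcc` and `pvalue`.
#' @export
#' @exportS3Method generics::tidy
tidy.coex_correlation <- function(x, ...) {
  idx <- which(upper.tri(x$pcc), arr.ind = TRUE)
  tibble(gene_a = x$gene_ids[idx[, 1L]], gene_b = x$gene_ids[idx[, 2L]],
         pcc = x$pcc[idx], pvalue = x$pvalue[idx])
}
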