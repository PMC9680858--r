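#' Construct an expression matrix
#'
#' The central container for abundance data: a numeric gene-by-sample matrix
#' with genes in rows and samples in columns, tagged with the scale its values
#' live on. TPM-scale matrices must be non-negative; log2-scale matrices hold
#' `log2(TPM + pseudocount)` values and may be negative. Orientation is always
#' explicit — nothing is auto-detected.
#'
#' @param values Numeric matrix with unique, non-empty rownames (gene IDs) and
#'   colnames (sample IDs). All values must be finite.
#' @param scale Either `"tpm"` (linear abundance) or `"log2"`.
#' @return An `expr_matrix`: the validated matrix carrying a `scale` attribute.
#' @examples
#' m <- expression_matrix(
#'   matrix(c(1, 2, 0, 4), nrow = 2, byrow = TRUE,
#'          dimnames = list(c("g1", "g2"), c("s1", "s2"))),
#'   scale = "tpm")
#' expr_scale(m)
#' @export
expression_matrix <- function(values, scale = c("tpm", "log2")) {
  scale <- arg_match(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    coex_abort("`values` must be a numeric matrix (genes in rows, samples in columns).")
  }
  validate_dimnames(values)
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    coex_abort(sprintf("Non-finite value at gene '%s', sample '%s'.",
                       rownames(values)[bad[1L]], colnames(values)[bad[2L]]),
               class = "coexnet_value_error")
  }
  if (scale == "tpm" && any(values < 0)) {
    coex_abort("TPM-scale values must be non-negative.", class = "coexnet_value_error")
  }
  structure(values, scale = scale, class = c("expr_matrix", "matrix", "array"))
}

validate_dimnames <- function(values) {
  genes <- rownames(values)
  samples <- colnames(values)
  if (is.null(genes) || is.null(samples) || any(!nzchar(genes)) || any(!nzchar(samples))) {
    coex_abort("Matrix must carry gene IDs as rownames and sample IDs as colnames.")
  }
  if (anyDuplicated(genes)) {
    coex_abort(sprintf("Duplicated gene ID(s): %s.",
                       toString(unique(genes[duplicated(genes)]))),
               class = "coexnet_duplicate_id")
  }
  if (anyDuplicated(samples)) {
    coex_abort(sprintf("Duplicated sample ID(s): %s.",
                       toString(unique(samples[duplicated(samples)]))),
               class = "coexnet_duplicate_id")
  }
  invisible(values)
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples, scale = %s\n",
              nrow(x), ncol(x), expr_scale(x)))
  print(utils::head(unclass(x)[, seq_len(min(ncol(x), 6L)), drop = FALSE]))
  invisible(x)
}

#' Scale of an expression matrix
#' @param m An `expr_matrix`.
#' @return `"tpm"` or `"log2"`.
#' @export
expr_scale <- function(m) attr(m, "scale") %||% "tpm"

#' Construct a count matrix
#'
#' Raw (non-normalized) sequencing counts, genes in rows and samples in
#' columns. Values must be non-negative integers (an integer stored as
#' double is accepted).
#'
#' @param counts Numeric matrix of non-negative integer counts with unique
#'   gene rownames and sample colnames.
#' @return A `count_matrix`.
#' @export
count_matrix <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    coex_abort("`counts` must be a numeric matrix.")
  }
  validate_dimnames(counts)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(abs(counts - round(counts)) > 1e-8)) {
    coex_abort("Counts must be finite non-negative integers.",
               class = "coexnet_value_error")
  }
  structure(counts, class = c("count_matrix", "matrix", "array"))
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d genes x %d samples\n", nrow(x), ncol(x)))
  print(utils::head(unclass(x)[, seq_len(min(ncol(x), 6L)), drop = FALSE]))
  invisible(x)
}

read_matrix_body <- function(path, delim) {
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           name_repair = "minimal", progress = FALSE)
  probs <- readr::problems(raw)
  if (nrow(probs) > 0L) {
    coex_abort(sprintf("Malformed table '%s': %s (row %d).",
                       path, probs$expected[1L], probs$row[1L]))
  }
  if (ncol(raw) < 2L) coex_abort("Matrix file needs a gene-ID column plus >= 1 sample column.")
  genes <- raw[[1L]]
  samples <- names(raw)[-1L]
  body <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  bad <- which(is.na(num) & !is.na(body), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    coex_abort(sprintf("Non-numeric cell '%s' at gene '%s', sample '%s'.",
                       body[bad[1L, 1L], bad[1L, 2L]], genes[bad[1L, 1L]],
                       samples[bad[1L, 2L]]),
               class = "coexnet_value_error")
  }
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    coex_abort(sprintf("Missing value at gene '%s', sample '%s' (ragged row?).",
                       genes[bad[1L]], samples[bad[2L]]))
  }
  dimnames(num) <- list(genes, samples)
  num
}

#' Read an expression matrix from TSV/CSV
#'
#' First column holds gene IDs, the header row holds sample IDs; the body is
#' numeric. Row and column order are preserved exactly as in the file.
#' `.gz`-compressed files are read transparently; the delimiter defaults to
#' the file extension (`.csv` gives comma, anything else tab).
#'
#' @param path File path.
#' @param delim Field delimiter; inferred from the extension when `NULL`.
#' @param scale Scale flag to attach, `"tpm"` (default) or `"log2"`.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, delim = NULL, scale = c("tpm", "log2")) {
  scale <- arg_match(scale)
  expression_matrix(read_matrix_body(path, delim %||% infer_delim(path)), scale = scale)
}

#' Read a raw count matrix from TSV/CSV
#' @inheritParams read_expression_matrix
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(path, delim = NULL) {
  count_matrix(read_matrix_body(path, delim %||% infer_delim(path)))
}

#' Write a gene-by-sample matrix to TSV/CSV
#'
#' Inverse of [read_expression_matrix()]: gene IDs in the first column
#' (`gene_id`), sample IDs in the header.
#'
#' @param m An `expr_matrix` or `count_matrix`.
#' @param path Output path; `.csv` extension writes comma-separated.
#' @param delim Delimiter override.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path, delim = NULL) {
  out <- tibble::as_tibble(unclass(m), .name_repair = "minimal")
  out <- dplyr::bind_cols(tibble(gene_id = rownames(m)), out)
  readr::write_delim(out, path, delim = delim %||% infer_delim(path), progress = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Long-format TSV with columns `sample_id`, `group`, optional `study` and
#' optional `qc_value` (a quality metric in \[0, 1\], e.g. a mapping rate).
#'
#' @param path File path.
#' @return A tibble with those columns (`study` / `qc_value` filled with NA
#'   when absent).
#' @export
read_sample_table <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"), progress = FALSE)
  sample_table(
    sample_id = tab[["sample_id"]],
    group = tab[["group"]],
    study = tab[["study"]] %||% NA_character_,
    qc_value = if (is.null(tab[["qc_value"]])) NA_real_ else as.numeric(tab[["qc_value"]])
  )
}

#' Construct a sample metadata table
#'
#' @param sample_id Unique sample identifiers.
#' @param group Replicate-group label (tissue, condition, genotype...).
#' @param study Optional free-text study label.
#' @param qc_value Optional per-sample QC metric in \[0, 1\]; `NA` allowed.
#' @return A tibble with class `sample_table`.
#' @export
sample_table <- function(sample_id, group, study = NA_character_, qc_value = NA_real_) {
  if (is.null(sample_id) || anyDuplicated(sample_id)) {
    coex_abort("`sample_id` must be present and unique.", class = "coexnet_duplicate_id")
  }
  if (is.null(group)) coex_abort("`group` column is required.")
  qc <- as.numeric(qc_value)
  if (any(!is.na(qc) & (qc < 0 | qc > 1))) {
    coex_abort("`qc_value` must lie in [0, 1].", class = "coexnet_value_error")
  }
  out <- tibble(sample_id = as.character(sample_id), group = as.character(group),
                study = as.character(study), qc_value = qc)
  class(out) <- c("sample_table", class(tibble()))
  out
}

#' Read a gene annotation table
#'
#' Long-format TSV with columns `gene_id`, `namespace`, `term_id`,
#' `description`. The namespace must come from the closed set GO / KEGG /
#' KOG / Pfam / NAME; (gene, namespace, term) triples must be unique.
#'
#' @param path File path.
#' @return An annotation tibble.
#' @export
read_annotation_table <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"), progress = FALSE)
  annotation_table(tab)
}

annotation_namespaces <- c("GO", "KEGG", "KOG", "Pfam", "NAME")

#' Validate an annotation table
#'
#' @param x Data frame with columns `gene_id`, `namespace`, `term_id`,
#'   `description`.
#' @return The validated tibble.
#' @export
annotation_table <- function(x) {
  need <- c("gene_id", "namespace", "term_id", "description")
  if (!all(need %in% names(x))) {
    coex_abort(sprintf("Annotation table needs columns: %s.", toString(need)))
  }
  x <- as_tibble(x)[need]
  bad_ns <- setdiff(unique(x$namespace), annotation_namespaces)
  if (length(bad_ns) > 0L) {
    coex_abort(sprintf("Unknown annotation namespace(s): %s (allowed: %s).",
                       toString(bad_ns), toString(annotation_namespaces)))
  }
  if (anyDuplicated(x[c("gene_id", "namespace", "term_id")])) {
    coex_abort("Duplicate (gene, namespace, term) annotation records.",
               class = "coexnet_duplicate_id")
  }
  x
}

#' Log-transform a TPM matrix
#'
#' Applies `log2(TPM + pseudocount)` cell-wise. The default pseudocount of
#' 0.25 maps zero abundance to -2 and keeps the transform strictly monotone
#' and invertible.
#'
#' @param m TPM-scale `expr_matrix`.
#' @param pseudo Positive pseudocount added before taking log2.
#' @return A log2-scale `expr_matrix` with `pseudo` recorded as an attribute.
#' @seealso [inverse_log_transform()]
#' @export
log_transform <- function(m, pseudo = 0.25) {
  assert_scalar_number(pseudo, "pseudo", lower = .Machine$double.xmin)
  if (expr_scale(m) != "tpm") {
    coex_abort("Matrix is already log2-scale; refusing to double-transform.",
               class = "coexnet_scale_error")
  }
  out <- expression_matrix(log2(unclass(m) + pseudo), scale = "log2")
  attr(out, "pseudo") <- pseudo
  out
}

#' Invert a log2(TPM + pseudo) transform
#'
#' @param m Log2-scale `expr_matrix`.
#' @param pseudo Pseudocount used in the forward transform; defaults to the
#'   one recorded by [log_transform()].
#' @return A TPM-scale `expr_matrix`; tiny negative values from floating-point
#'   round-off are clipped to zero.
#' @export
inverse_log_transform <- function(m, pseudo = NULL) {
  if (expr_scale(m) != "log2") coex_abort("Matrix is not log2-scale.",
                                          class = "coexnet_scale_error")
  pseudo <- pseudo %||% attr(m, "pseudo") %||% 0.25
  tpm <- 2^unclass(m) - pseudo
  tpm[tpm < 0 & tpm > -1e-9] <- 0
  expression_matrix(tpm, scale = "tpm")
}

#' Drop samples failing a QC threshold
#'
#' Removes matrix columns whose `qc_value` in the sample table falls below
#' `qc_threshold`. Samples without a QC value are retained (absence of
#' evidence is not treated as failure). Genes are untouched.
#'
#' @param m `expr_matrix` or `count_matrix`.
#' @param samples [sample_table()] covering every column of `m`.
#' @param qc_threshold Threshold in \[0, 1\]; default 0.5, i.e. a 50% mapping
#'   rate.
#' @return The matrix restricted to passing samples.
#' @export
filter_samples <- function(m, samples, qc_threshold = 0.5) {
  assert_scalar_number(qc_threshold, "qc_threshold", 0, 1)
  missing_meta <- setdiff(colnames(m), samples$sample_id)
  if (length(missing_meta) > 0L) {
    coex_abort(sprintf("Samples absent from metadata: %s.", toString(head(missing_meta))))
  }
  qc <- samples$qc_value[match(colnames(m), samples$sample_id)]
  keep <- is.na(qc) | qc >= qc_threshold
  if (!any(keep)) coex_abort("QC filtering removed every sample.",
                             class = "coexnet_value_error")
  m[, keep, drop = FALSE]
}

#' Per-group expression summaries
#'
#' Aggregates each gene's expression over the samples of each replicate group:
#' the data behind bar/line/clustergram displays. The SD convention is the
#' population SD (denominator n) so that single-sample groups report 0 rather
#' than an undefined value; pass `sd_type = "sample"` for the n-1 convention
#' (single-sample groups then report `NA`).
#'
#' @param m `expr_matrix`.
#' @param samples [sample_table()]; every column of `m` must be assigned a
#'   group.
#' @param group_key Metadata column holding the grouping label (default
#'   `"group"`).
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return A tibble with one row per (gene, group): `gene_id`, `group`,
#'   `mean`, `sd`, `n`.
#' @export
aggregate_by_group <- function(m, samples, group_key = "group",
                               sd_type = c("population", "sample")) {
  sd_type <- arg_match(sd_type)
  if (!group_key %in% names(samples)) {
    coex_abort(sprintf("Column '%s' not found in sample table.", group_key))
  }
  idx <- match(colnames(m), samples$sample_id)
  if (anyNA(idx)) {
    coex_abort(sprintf("Samples absent from metadata: %s.",
                       toString(head(colnames(m)[is.na(idx)]))))
  }
  grp <- samples[[group_key]][idx]
  if (anyNA(grp)) coex_abort("Every sample must be assigned a group.")
  vals <- unclass(m)
  out <- purrr::map(split(seq_along(grp), grp), function(cols) {
    sub <- vals[, cols, drop = FALSE]
    nm <- ncol(sub)
    mu <- rowMeans(sub)
    ss <- rowSums((sub - mu)^2)
    s <- if (sd_type == "population") sqrt(ss / nm) else {
      if (nm > 1L) sqrt(ss / (nm - 1L)) else rep(NA_real_, nrow(sub))
    }
    tibble(gene_id = rownames(sub), mean = unname(mu), sd = unname(s), n = nm)
  })
  out <- dplyr::bind_rows(out, .id = "group")
  out <- out[order(match(out$gene_id, rownames(m)), out$group), ]
  out <- out[c("gene_id", "group", "mean", "sd", "n")]
  class(out) <- c("group_summary", class(tibble()))
  out
}
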