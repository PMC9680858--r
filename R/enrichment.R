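#' Parse a GO ontology in OBO 1.2 format
#'
#' Reads `[Term]` stanzas, keeping non-obsolete terms and their `is_a` and
#' `relationship: part_of` parents — the two relations conventionally used
#' for annotation propagation. The result is validated: every parent must
#' exist and the parent relation must be acyclic.
#'
#' @param path Path to an OBO file.
#' @return A `go_dag`: list with `terms` (tibble `term_id`, `name`,
#'   `namespace`) and `parents` (named list of parent term IDs).
#' @export
parse_obo <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  stanza_starts <- grep("^\\[", lines)
  terms <- list()
  for (i in seq_along(stanza_starts)) {
    if (lines[stanza_starts[i]] != "[Term]") next
    from <- stanza_starts[i] + 1L
    to <- if (i < length(stanza_starts)) stanza_starts[i + 1L] - 1L else length(lines)
    block <- lines[from:to]
    field <- function(key) {
      v <- block[startsWith(block, paste0(key, ":"))]
      stringr::str_trim(sub(paste0("^", key, ":"), "", v))
    }
    if (any(field("is_obsolete") == "true")) next
    id <- field("id")[1L]
    if (is.na(id) || !nzchar(id)) next
    isa <- sub("\\s*!.*$", "", field("is_a"))
    rel <- field("relationship")
    partof <- sub("\\s*!.*$", "", sub("^part_of\\s+", "", rel[grepl("^part_of\\s", rel)]))
    terms[[id]] <- list(name = field("name")[1L] %||% NA_character_,
                        namespace = field("namespace")[1L] %||% NA_character_,
                        parents = unique(c(isa, partof)))
  }
  if (length(terms) == 0L) coex_abort(sprintf("No [Term] stanzas found in '%s'.", path))
  ids <- names(terms)
  parents <- lapply(terms, `[[`, "parents")
  dangling <- setdiff(unique(unlist(parents)), ids)
  if (length(dangling) > 0L) {
    coex_abort(sprintf("Parent term(s) not defined in the ontology: %s.",
                       toString(head(dangling))),
               class = "coexnet_obo_error")
  }
  dag <- structure(list(
    terms = tibble(term_id = ids,
                   name = vapply(terms, function(t) t$name[1L] %||% NA_character_,
                                 character(1)),
                   namespace = vapply(terms, function(t) t$namespace[1L] %||% NA_character_,
                                      character(1))),
    parents = parents
  ), class = "go_dag")
  check_acyclic(dag)
  dag
}

# Kahn's algorithm on the child -> parent relation; leftovers mean a cycle
check_acyclic <- function(dag) {
  remaining <- dag$parents
  repeat {
    resolved <- names(remaining)[lengths(remaining) == 0L]
    if (length(resolved) == 0L) break
    remaining <- remaining[!names(remaining) %in% resolved]
    remaining <- lapply(remaining, setdiff, resolved)
  }
  if (length(remaining) > 0L) {
    coex_abort(sprintf("Cycle detected in ontology involving: %s.",
                       toString(head(names(remaining)))),
               class = "coexnet_obo_error")
  }
  invisible(dag)
}

#' @export
print.go_dag <- function(x, ...) {
  cat(sprintf("<go_dag> %d terms, %d parent links\n",
              nrow(x$terms), sum(lengths(x$parents))))
  invisible(x)
}

#' Ancestors of an ontology term
#'
#' @param dag A `go_dag`.
#' @param term_id Single term ID.
#' @return Character vector of all (transitive) ancestors, excluding the term
#'   itself.
#' @export
go_ancestors <- function(dag, term_id) {
  if (!term_id %in% names(dag$parents)) {
    coex_abort(sprintf("Term '%s' not in the ontology.", term_id))
  }
  out <- character()
  frontier <- dag$parents[[term_id]]
  while (length(frontier) > 0L) {
    out <- union(out, frontier)
    frontier <- setdiff(unique(unlist(dag$parents[frontier], use.names = FALSE)), out)
  }
  out
}

# ancestors for every term at once, walking the DAG in topological order
all_ancestors <- function(dag) {
  anc <- setNames(vector("list", length(dag$parents)), names(dag$parents))
  pending <- names(dag$parents)
  done <- character()
  while (length(pending) > 0L) {
    ready <- pending[vapply(dag$parents[pending],
                            function(p) all(p %in% done), logical(1))]
    for (id in ready) {
      p <- dag$parents[[id]]
      anc[[id]] <- unique(c(p, unlist(anc[p], use.names = FALSE)))
    }
    done <- c(done, ready)
    pending <- setdiff(pending, ready)
  }
  anc
}

#' Write a `go_dag` back to OBO 1.2
#'
#' All parents are emitted as `is_a` links (the parser does not distinguish
#' them from `part_of` for propagation purposes).
#'
#' @param dag A `go_dag`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(dag, path) {
  lines <- c("format-version: 1.2", "")
  for (i in seq_len(nrow(dag$terms))) {
    id <- dag$terms$term_id[i]
    p <- dag$parents[[id]]
    lines <- c(lines, "[Term]", paste0("id: ", id),
               paste0("name: ", dag$terms$name[i]),
               paste0("namespace: ", dag$terms$namespace[i]),
               if (length(p) > 0L) paste0("is_a: ", p), "")
  }
  readr::write_lines(lines, path)
  invisible(path)
}

#' Propagate GO annotations up the ontology
#'
#' Standard GO enrichment semantics: a gene annotated to a term is implicitly
#' annotated to all of that term's ancestors. Only GO-namespace records are
#' propagated; records for terms absent from the DAG are dropped with a
#' warning. The operation is idempotent.
#'
#' @param annotations Annotation table (see [annotation_table()]).
#' @param dag A `go_dag`.
#' @return The annotation table with ancestor records added (descriptions
#'   taken from the DAG's term names).
#' @export
propagate_annotations <- function(annotations, dag) {
  annotations <- annotation_table(annotations)
  go <- annotations[annotations$namespace == "GO", , drop = FALSE]
  other <- annotations[annotations$namespace != "GO", , drop = FALSE]
  unknown <- setdiff(unique(go$term_id), dag$terms$term_id)
  if (length(unknown) > 0L) {
    warn(sprintf("Dropping %d GO record(s) with terms absent from the ontology: %s.",
                 sum(go$term_id %in% unknown), toString(head(unknown))))
    go <- go[!go$term_id %in% unknown, , drop = FALSE]
  }
  anc <- all_ancestors(dag)
  name_of <- setNames(dag$terms$name, dag$terms$term_id)
  extra <- go %>%
    mutate(term_id = purrr::map(.data$term_id, ~ c(.x, anc[[.x]]))) %>%
    tidyr::unnest("term_id") %>%
    mutate(description = unname(name_of[.data$term_id]))
  out <- bind_rows(distinct(extra, .data$gene_id, .data$namespace, .data$term_id,
                            .keep_all = TRUE),
                   other)
  annotation_table(out)
}

# two-sided Fisher exact p by summing hypergeometric point masses no larger
# than the observed one (with the customary relative tolerance)
fisher_two_sided <- function(k, K, n, N) {
  support <- max(0L, n - (N - K)):min(n, K)
  d <- dhyper(support, K, N - K, n)
  d_obs <- dhyper(k, K, N - K, n)
  min(1, sum(d[d <= d_obs * (1 + 1e-7)]))
}

#' Functional term enrichment by Fisher's exact test
#'
#' For each annotation term in a namespace, tests whether study genes carry
#' the term more (or less) often than the background using the two-sided
#' Fisher's exact test on the 2x2 table (k, n-k; K-k, N-K-n+k), then adjusts
#' across all tested terms of the namespace with Benjamini-Hochberg. A term's
#' direction is `"over"` when the study fraction k/n is at least the
#' background fraction K/N (equality counts as "over"), `"under"` otherwise.
#'
#' The default background is every gene with at least one annotation in the
#' tested namespace; supply `background` (e.g. the full gene universe) to
#' override — this changes N and K and therefore the p-values.
#'
#' @param study_genes Character vector of study gene IDs (non-empty, all in
#'   the background).
#' @param annotations Annotation table.
#' @param namespace One of GO, KEGG, KOG, Pfam.
#' @param dag Optional `go_dag`; with `propagate = TRUE` (default) GO
#'   annotations are propagated to ancestors before testing. KEGG/KOG/Pfam
#'   are flat and never propagated.
#' @param background Optional character vector of background gene IDs.
#' @param propagate Propagate GO annotations up the DAG first.
#' @return An `enrichment_result` tibble sorted by FDR, then p, then term:
#'   `term_id`, `namespace`, `name`, `study_count`, `study_size`,
#'   `population_count`, `population_size`, `direction`, `p_raw`, `fdr`.
#' @export
enrich <- function(study_genes, annotations, namespace = "GO", dag = NULL,
                   background = NULL, propagate = TRUE) {
  if (length(study_genes) == 0L) coex_abort("Empty study gene set.")
  namespace <- arg_match(namespace, c("GO", "KEGG", "KOG", "Pfam"))
  annotations <- annotation_table(annotations)
  if (namespace == "GO" && propagate && !is.null(dag)) {
    annotations <- propagate_annotations(annotations, dag)
  }
  ann <- annotations[annotations$namespace == namespace, , drop = FALSE]
  if (is.null(background)) background <- unique(ann$gene_id)
  background <- unique(background)
  study_genes <- unique(study_genes)
  outside <- setdiff(study_genes, background)
  if (length(outside) > 0L) {
    coex_abort(sprintf("Study gene(s) absent from the background: %s.",
                       toString(head(outside))),
               class = "coexnet_unknown_gene")
  }
  ann <- ann[ann$gene_id %in% background, , drop = FALSE]
  N <- length(background)
  n <- length(study_genes)
  per_term <- ann %>%
    distinct(.data$gene_id, .data$term_id, .keep_all = TRUE) %>%
    group_by(.data$term_id) %>%
    summarise(name = .data$description[1L],
              population_count = dplyr::n_distinct(.data$gene_id),
              study_count = sum(.data$gene_id %in% study_genes),
              .groups = "drop")
  if (nrow(per_term) == 0L) {
    res <- tibble(term_id = character(), namespace = character(),
                  name = character(), study_count = integer(),
                  study_size = integer(), population_count = integer(),
                  population_size = integer(), direction = character(),
                  p_raw = numeric(), fdr = numeric())
    class(res) <- c("enrichment_result", class(tibble()))
    return(res)
  }
  res <- per_term %>%
    mutate(namespace = namespace, study_size = n, population_size = N,
           direction = ifelse(.data$study_count / n >= .data$population_count / N,
                              "over", "under"),
           p_raw = purrr::map2_dbl(.data$study_count, .data$population_count,
                                   ~ fisher_two_sided(.x, .y, n, N))) %>%
    mutate(fdr = bh_adjust(.data$p_raw)) %>%
    select("term_id", "namespace", "name", "study_count", "study_size",
           "population_count", "population_size", "direction", "p_raw", "fdr") %>%
    arrange(.data$fdr, .data$p_raw, .data$term_id)
  class(res) <- c("enrichment_result", class(tibble()))
  res
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values in the original order, capped at 1.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric())
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    coex_abort("All p-values must lie in [0, 1].", class = "coexnet_value_error")
  }
  p.adjust(pvalues, method = "BH")
}

# shipped stop-word list: versioned so word frequencies are reproducible
coexnet_stopwords <- c(
  "a", "an", "and", "as", "at", "by", "for", "from", "in", "into", "involved",
  "of", "on", "or", "other", "the", "to", "via", "with"
)

#' Word frequencies among significantly enriched terms
#'
#' The table behind a word-cloud view: term names with FDR below the cutoff
#' are lowercased, tokenized on non-alphanumeric boundaries, stripped of a
#' fixed stop-word list, and counted.
#'
#' @param results `enrichment_result` from [enrich()].
#' @param fdr_cutoff Significance threshold (strict); default 0.05.
#' @return A tibble (`word`, `count`) sorted by descending count, ties
#'   alphabetical.
#' @export
term_word_frequencies <- function(results, fdr_cutoff = 0.05) {
  sig <- results$name[!is.na(results$fdr) & results$fdr < fdr_cutoff]
  if (length(sig) == 0L) return(tibble(word = character(), count = integer()))
  words <- unlist(strsplit(stringr::str_to_lower(sig), "[^a-z0-9]+"))
  words <- words[nzchar(words) & !words %in% coexnet_stopwords]
  if (length(words) == 0L) return(tibble(word = character(), count = integer()))
  tab <- table(words)
  out <- tibble(word = names(tab), count = as.integer(tab)) %>%
    arrange(desc(.data$count), .data$word)
  out
}
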