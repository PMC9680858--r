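#' Build an MR-thresholded co-expression graph
#'
#' Genes become nodes; an undirected edge joins A and B exactly when
#' `mr[A, B] < edge_cutoff` (strict, matching the usual "MR < 30" notation).
#' Isolated genes are retained as nodes. Annotations, when supplied, are
#' attached to nodes: the curated gene name, the KOG description (the
#' "functional category" used for node shapes in network displays), and a
#' concatenated annotation text used for keyword filtering.
#'
#' @param scores `coex_scores` from [coexpression_scores()].
#' @param edge_cutoff Positive MR threshold; default 30, a stringent edge
#'   definition for drawn networks. Table-style exploration typically uses
#'   looser cutoffs (1000-2000).
#' @param annotations Optional annotation table.
#' @param correlation Optional matching `coex_correlation`; adds a `pcc`
#'   edge attribute.
#' @return A `coex_graph`: an [igraph::graph] with `mr` (and optionally
#'   `pcc`) edge attributes and the cutoff stored as a graph attribute.
#' @export
build_graph <- function(scores, edge_cutoff = 30, annotations = NULL,
                        correlation = NULL) {
  assert_scalar_number(edge_cutoff, "edge_cutoff", lower = 1e-12)
  genes <- scores$gene_ids
  mr <- scores$mr
  sel <- which(upper.tri(mr) & mr < edge_cutoff & mr > 0, arr.ind = TRUE)
  edges <- tibble(from = genes[sel[, 1L]], to = genes[sel[, 2L]], mr = mr[sel])
  if (!is.null(correlation)) edges$pcc <- correlation$pcc[sel]
  vertices <- tibble(name = genes)
  if (!is.null(annotations)) {
    annotations <- annotation_table(annotations)
    vertices <- vertices %>%
      left_join(collapse_annotation(annotations, "NAME") %>%
                  rename(gene_name = "NAME"), by = c(name = "gene_id")) %>%
      left_join(collapse_annotation(annotations, "KOG") %>%
                  rename(kog_category = "KOG"), by = c(name = "gene_id"))
    txt <- annotations %>%
      group_by(.data$gene_id) %>%
      summarise(annotation_text = paste(.data$description, collapse = " "),
                .groups = "drop")
    vertices <- left_join(vertices, txt, by = c(name = "gene_id"))
    vertices <- dplyr::mutate(vertices, dplyr::across(dplyr::everything(),
                                                      ~ dplyr::coalesce(.x, "")))
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vertices)
  g <- igraph::set_graph_attr(g, "edge_cutoff", edge_cutoff)
  class(g) <- c("coex_graph", class(g))
  g
}

#' Distance-limited neighborhood of query genes
#'
#' Breadth-first traversal of the thresholded co-expression graph: every gene
#' reachable from the query set within `max_distance` edges is retained,
#' labeled with its shortest-path distance from the nearest query (queries
#' are at distance 0). The induced subgraph keeps all edges among retained
#' nodes.
#'
#' @param graph `coex_graph`.
#' @param query_genes Character vector of query gene IDs, all present in the
#'   graph.
#' @param max_distance Non-negative integer hop limit; default 3, the usual
#'   radius for single-gene network views.
#' @return A `coex_neighborhood`: list with `graph` (induced subgraph whose
#'   vertices carry a `distance` attribute), `distances` (tibble `gene_id`,
#'   `distance`), `query_genes`, `max_distance`.
#' @export
neighborhood <- function(graph, query_genes, max_distance = 3L) {
  if (!is.numeric(max_distance) || length(max_distance) != 1L ||
      max_distance < 0 || max_distance != round(max_distance)) {
    coex_abort("`max_distance` must be a non-negative integer.")
  }
  all_genes <- igraph::V(graph)$name
  unknown <- setdiff(query_genes, all_genes)
  if (length(unknown) > 0L) {
    coex_abort(sprintf("Query gene(s) not in graph: %s.", toString(head(unknown))),
               class = "coexnet_unknown_gene")
  }
  d <- igraph::distances(graph, v = query_genes, weights = NA)
  dmin <- apply(d, 2L, min)
  keep <- names(dmin)[dmin <= max_distance]
  sub <- igraph::induced_subgraph(graph, keep)
  dist_kept <- dmin[igraph::V(sub)$name]
  sub <- igraph::set_vertex_attr(sub, "distance", value = as.integer(dist_kept))
  structure(list(
    graph = sub,
    distances = tibble(gene_id = igraph::V(sub)$name,
                       distance = as.integer(dist_kept)),
    query_genes = query_genes,
    max_distance = as.integer(max_distance)
  ), class = "coex_neighborhood")
}

#' @export
print.coex_neighborhood <- function(x, ...) {
  cat(sprintf("<coex_neighborhood> %d genes within distance %d of {%s}; %d edges\n",
              nrow(x$distances), x$max_distance, toString(head(x$query_genes)),
              igraph::ecount(x$graph)))
  invisible(x)
}

#' Bait-centered functional network with keyword filtering
#'
#' Takes the union of the distance-limited neighborhoods of several bait
#' genes (default radius 10, wider than the single-gene view), then
#' optionally drops non-bait genes whose annotation text does not contain any
#' of the given keywords. Matching is a case-insensitive literal substring
#' over the concatenated name and KOG/KEGG/Pfam/GO descriptions attached by
#' [build_graph()]; multiple keywords combine as OR. Baits are always
#' retained, distances are measured from the nearest bait before filtering
#' and are not re-routed afterwards.
#'
#' @param graph `coex_graph` built with annotations when keyword filtering is
#'   wanted.
#' @param bait_genes One or more bait gene IDs.
#' @param max_distance Hop limit; default 10.
#' @param keyword Optional character vector of keywords.
#' @return A `coex_neighborhood` restricted to baits plus matching genes.
#' @export
functional_network <- function(graph, bait_genes, max_distance = 10L,
                               keyword = NULL) {
  if (length(bait_genes) < 1L) coex_abort("At least one bait gene is required.")
  nb <- neighborhood(graph, bait_genes, max_distance = max_distance)
  if (is.null(keyword) || length(keyword) == 0L) return(nb)
  txt <- igraph::vertex_attr(nb$graph, "annotation_text")
  if (is.null(txt)) {
    coex_abort("Graph has no annotation text; build it with `annotations` to filter by keyword.")
  }
  names(txt) <- igraph::V(nb$graph)$name
  hit <- Reduce(`|`, lapply(keyword, function(k) {
    stringr::str_detect(stringr::str_to_lower(txt),
                        stringr::fixed(stringr::str_to_lower(k)))
  }))
  keep <- igraph::V(nb$graph)$name[hit | igraph::V(nb$graph)$name %in% bait_genes]
  sub <- igraph::induced_subgraph(nb$graph, keep)
  structure(list(
    graph = sub,
    distances = nb$distances[nb$distances$gene_id %in% keep, , drop = FALSE],
    query_genes = bait_genes,
    max_distance = nb$max_distance
  ), class = "coex_neighborhood")
}

#' Export a neighborhood to GraphML, TSV edge list, or JSON
#'
#' GraphML and JSON are lossless for nodes (with name/KOG/annotation payload
#' and distances) and edges (MR and PCC weights); the TSV edge list keeps
#' edges only and is meant for spreadsheet use.
#'
#' @param nb `coex_neighborhood`.
#' @param path Output file path.
#' @param format `"graphml"`, `"edge_tsv"`, or `"json"`.
#' @return `path`, invisibly.
#' @seealso [import_graph()]
#' @export
export_graph <- function(nb, path, format = c("graphml", "edge_tsv", "json")) {
  format <- arg_match(format)
  g <- nb$graph
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else if (format == "edge_tsv") {
    readr::write_tsv(edge_tibble(g), path, progress = FALSE)
  } else {
    nodes <- tibble(gene_id = igraph::V(g)$name,
                    distance = igraph::vertex_attr(g, "distance") %||%
                      rep(NA_integer_, igraph::vcount(g)))
    for (a in c("gene_name", "kog_category", "annotation_text")) {
      v <- igraph::vertex_attr(g, a)
      if (!is.null(v)) nodes[[a]] <- v
    }
    jsonlite::write_json(list(nodes = nodes, edges = edge_tibble(g)),
                         path, auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

edge_tibble <- function(g) {
  if (igraph::ecount(g) == 0L) {
    return(tibble(gene_a = character(), gene_b = character(),
                  mr = numeric(), pcc = numeric()))
  }
  el <- igraph::as_edgelist(g)
  out <- tibble(gene_a = el[, 1L], gene_b = el[, 2L],
                mr = igraph::E(g)$mr)
  out$pcc <- igraph::edge_attr(g, "pcc") %||% rep(NA_real_, nrow(out))
  out
}

#' Import a graph written by [export_graph()]
#'
#' @param path File path.
#' @param format `"graphml"` or `"json"` (the TSV edge list is not
#'   re-importable as a full graph).
#' @return An [igraph::graph] with the exported attributes.
#' @export
import_graph <- function(path, format = c("graphml", "json")) {
  format <- arg_match(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    # igraph round-trips vertex names through the "name" attribute
    return(g)
  }
  dat <- jsonlite::read_json(path, simplifyVector = TRUE)
  nodes <- as_tibble(dat$nodes)
  edges <- as_tibble(dat$edges)
  names(nodes)[names(nodes) == "gene_id"] <- "name"
  if (nrow(edges) > 0L) names(edges)[1:2] <- c("from", "to")
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
}
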