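# small builders used across test files

toy_expr <- function(values, scale = "log2") {
  expression_matrix(values, scale = scale)
}

random_log2_matrix <- function(n_genes, n_samples, seed) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n_genes * n_samples, 5, 2), n_genes, n_samples,
                dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                sprintf("s%03d", seq_len(n_samples))))
    expression_matrix(m, scale = "log2")
  })
}

# a coex_scores stub with a hand-chosen MR matrix (for graph construction)
scores_from_mr <- function(mr) {
  structure(list(gene_ids = rownames(mr), rank = NULL,
                 hrr = mr, mr = mr), class = "coex_scores")
}

# MR matrix realizing a given edge list: listed pairs get small MR, all
# others a large one
mr_from_edges <- function(nodes, edges, low = 5, high = 1e6) {
  mr <- matrix(high, length(nodes), length(nodes),
               dimnames = list(nodes, nodes))
  diag(mr) <- 0
  for (i in seq_len(nrow(edges))) {
    mr[edges$from[i], edges$to[i]] <- low
    mr[edges$to[i], edges$from[i]] <- low
  }
  mr
}

random_edge_graph <- function(n_nodes, p_edge, seed) {
  withr::with_seed(seed, {
    nodes <- sprintf("n%03d", seq_len(n_nodes))
    pairs <- which(upper.tri(matrix(0, n_nodes, n_nodes)), arr.ind = TRUE)
    keep <- runif(nrow(pairs)) < p_edge
    edges <- tibble::tibble(from = nodes[pairs[keep, 1]],
                            to = nodes[pairs[keep, 2]])
    list(nodes = nodes, edges = edges)
  })
}

chain_obo_lines <- function() {
  c("format-version: 1.2", "",
    "[Term]", "id: GO:0000001", "name: root process",
    "namespace: biological_process", "",
    "[Term]", "id: GO:0000002", "name: mid process",
    "namespace: biological_process", "is_a: GO:0000001 ! root process", "",
    "[Term]", "id: GO:0000003", "name: leaf process",
    "namespace: biological_process", "is_a: GO:0000002 ! mid process", "",
    "[Term]", "id: GO:0000009", "name: gone process",
    "namespace: biological_process", "is_obsolete: true", "")
}
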