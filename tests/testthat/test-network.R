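path_graph <- function(nodes) {
  edges <- tibble::tibble(from = nodes[-length(nodes)], to = nodes[-1])
  build_graph(scores_from_mr(mr_from_edges(nodes, edges)), edge_cutoff = 30)
}

test_that("edges exist exactly where MR falls below the cutoff", {
  mr <- matrix(c(0, 5, 40, 5, 0, 100, 40, 100, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  g <- build_graph(scores_from_mr(mr), edge_cutoff = 30)
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::vcount(g), 3)  # isolated node retained
  expect_equal(igraph::E(g)$mr, 5)

  g0 <- build_graph(scores_from_mr(mr), edge_cutoff = 1)
  expect_equal(igraph::ecount(g0), 0)

  # strictness: an MR exactly at the cutoff is not an edge
  g5 <- build_graph(scores_from_mr(mr), edge_cutoff = 5)
  expect_equal(igraph::ecount(g5), 0)
})

test_that("the edge set of a random score matrix equals a pair scan", {
  cr <- correlation_matrix(random_log2_matrix(100, 15, seed = 301))
  sc <- coexpression_scores(cr)
  cutoff <- 30
  g <- build_graph(sc, edge_cutoff = cutoff)
  want <- character()
  for (i in 1:99) for (j in (i + 1):100) {
    if (sc$mr[i, j] < cutoff) {
      want <- c(want, paste(sc$gene_ids[i], sc$gene_ids[j], sep = "|"))
    }
  }
  el <- igraph::as_edgelist(g)
  got <- apply(el, 1, function(e) paste(sort(e), collapse = "|"))
  expect_setequal(got, want)
})

test_that("neighborhood distances follow BFS from the query set", {
  g <- path_graph(c("a", "b", "c", "d", "e"))
  nb <- neighborhood(g, "a", max_distance = 3)
  expect_setequal(nb$distances$gene_id, c("a", "b", "c", "d"))
  expect_equal(nb$distances$distance[match(c("a", "b", "c", "d"),
                                           nb$distances$gene_id)], 0:3)
  nb0 <- neighborhood(g, "a", max_distance = 0)
  expect_identical(nb0$distances$gene_id, "a")
  expect_error(neighborhood(g, "zzz"), class = "coexnet_unknown_gene")

  # random graphs vs the frontier-expansion oracle
  for (seed in c(1, 2, 3)) {
    rg <- random_edge_graph(100, 0.03, seed)
    g2 <- build_graph(scores_from_mr(mr_from_edges(rg$nodes, rg$edges)),
                      edge_cutoff = 30)
    queries <- rg$nodes[c(1, 50)]
    want <- oracle_bfs(rg$edges, rg$nodes, queries)
    nb2 <- neighborhood(g2, queries, max_distance = 4)
    expect_setequal(nb2$distances$gene_id, names(want)[want <= 4])
    expect_equal(nb2$distances$distance,
                 unname(want[nb2$distances$gene_id]))
  }
})

test_that("neighborhoods grow monotonically with distance and cutoff", {
  cr <- correlation_matrix(random_log2_matrix(60, 12, seed = 311))
  sc <- coexpression_scores(cr)
  g_tight <- build_graph(sc, edge_cutoff = 10)
  g_loose <- build_graph(sc, edge_cutoff = 30)
  expect_true(igraph::ecount(g_loose) >= igraph::ecount(g_tight))
  q <- sc$gene_ids[1]
  prev <- 0L
  for (d in 0:4) {
    nd <- nrow(neighborhood(g_loose, q, max_distance = d)$distances)
    expect_true(nd >= prev)
    prev <- nd
  }
  # every tight-graph edge persists in the loose graph
  el_t <- apply(igraph::as_edgelist(g_tight), 1, function(e)
    paste(sort(e), collapse = "|"))
  el_l <- apply(igraph::as_edgelist(g_loose), 1, function(e)
    paste(sort(e), collapse = "|"))
  expect_true(all(el_t %in% el_l))
})

test_that("keyword filtering keeps matching neighbors and all baits", {
  nodes <- c("bait", "hit", "miss")
  edges <- tibble::tibble(from = c("bait", "bait"), to = c("hit", "miss"))
  ann <- tibble::tibble(
    gene_id = c("hit", "miss", "bait"),
    namespace = c("Pfam", "Pfam", "KOG"),
    term_id = c("PF1", "PF2", "KOG1"),
    description = c("Terpenoid biosynthesis", "protein kinase", "transcription"))
  g <- build_graph(scores_from_mr(mr_from_edges(nodes, edges)),
                   edge_cutoff = 30, annotations = ann)
  fn <- functional_network(g, "bait", keyword = "terpenoid")
  expect_setequal(fn$distances$gene_id, c("bait", "hit"))
  fn2 <- functional_network(g, "bait", keyword = "kinase")
  expect_setequal(fn2$distances$gene_id, c("bait", "miss"))
  # bait retained even when it matches nothing
  expect_true("bait" %in% fn2$distances$gene_id)
  # multiple keywords combine as OR
  fn3 <- functional_network(g, "bait", keyword = c("terpenoid", "kinase"))
  expect_setequal(fn3$distances$gene_id, c("bait", "hit", "miss"))
})

test_that("disjoint baits contribute the union of their neighborhoods", {
  nodes <- c("a1", "a2", "b1", "b2", "far")
  edges <- tibble::tibble(from = c("a1", "b1"), to = c("a2", "b2"))
  g <- build_graph(scores_from_mr(mr_from_edges(nodes, edges)), edge_cutoff = 30)
  fn <- functional_network(g, c("a1", "b1"), max_distance = 10)
  expect_setequal(fn$distances$gene_id, c("a1", "a2", "b1", "b2"))
  expect_error(functional_network(g, character()), "bait")
})

test_that("keyword filtering is idempotent on the retained node set", {
  sim <- simulate_expression(n_genes = 120, n_samples = 20,
                             modules = c(mod = 12), noise_sd = 0.4, seed = 8)
  members <- sim$truth$modules$mod
  ann <- tibble::tibble(gene_id = members[5:12], namespace = "Pfam",
                        term_id = "PF9", description = "terpenoid pathway")
  cr <- correlation_matrix(sim$matrix)
  sc <- coexpression_scores(cr)
  g <- build_graph(sc, edge_cutoff = 50, annotations = ann)
  f1 <- functional_network(g, members[1], keyword = "terpenoid")
  g_again <- f1$graph
  class(g_again) <- class(g)
  f2 <- functional_network(g_again, members[1], keyword = "terpenoid")
  expect_setequal(f2$distances$gene_id, f1$distances$gene_id)
})

test_that("graph exports round-trip through GraphML and JSON", {
  nodes <- c("x", "y", "z")
  edges <- tibble::tibble(from = c("x", "y"), to = c("y", "z"))
  ann <- tibble::tibble(gene_id = nodes, namespace = "KOG",
                        term_id = paste0("KOG", 1:3),
                        description = c("metabolism", "transport", "signaling"))
  g <- build_graph(scores_from_mr(mr_from_edges(nodes, edges)),
                   edge_cutoff = 30, annotations = ann)
  nb <- neighborhood(g, "x", max_distance = 2)

  gml <- withr::local_tempfile(fileext = ".graphml")
  export_graph(nb, gml, format = "graphml")
  back <- import_graph(gml, format = "graphml")
  expect_setequal(igraph::V(back)$name, nb$distances$gene_id)
  expect_equal(sort(igraph::E(back)$mr), sort(igraph::E(nb$graph)$mr))
  expect_equal(igraph::vertex_attr(back, "distance")[
    match(nb$distances$gene_id, igraph::V(back)$name)],
    as.numeric(nb$distances$distance))
  expect_equal(igraph::vertex_attr(back, "kog_category")[
    match(nodes, igraph::V(back)$name)], ann$description)

  js <- withr::local_tempfile(fileext = ".json")
  export_graph(nb, js, format = "json")
  back2 <- import_graph(js, format = "json")
  expect_setequal(igraph::V(back2)$name, nb$distances$gene_id)
  expect_equal(igraph::ecount(back2), igraph::ecount(nb$graph))

  # a three-node path serializes two edge records
  dat <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_identical(nrow(dat$edges), 2L)

  # empty neighborhood still writes valid files
  lonely <- neighborhood(g, "z", max_distance = 0)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_graph(lonely, tsv, format = "edge_tsv")
  expect_identical(nrow(readr::read_tsv(tsv, show_col_types = FALSE)), 0L)
})
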