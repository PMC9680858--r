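test_that("OBO parsing keeps the is_a chain and drops obsolete terms", {
  obo <- withr::local_tempfile(fileext = ".obo")
  writeLines(chain_obo_lines(), obo)
  dag <- parse_obo(obo)
  expect_setequal(dag$terms$term_id, c("GO:0000001", "GO:0000002", "GO:0000003"))
  expect_identical(dag$parents[["GO:0000003"]], "GO:0000002")
  expect_setequal(go_ancestors(dag, "GO:0000003"), c("GO:0000001", "GO:0000002"))
  expect_identical(go_ancestors(dag, "GO:0000001"), character())
})

test_that("dangling parents and cycles are fatal", {
  bad <- withr::local_tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: GO:1", "name: a", "is_a: GO:404 ! missing"), bad)
  expect_error(parse_obo(bad), "GO:404", class = "coexnet_obo_error")

  cyc <- withr::local_tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: GO:1", "name: a", "is_a: GO:2", "",
               "[Term]", "id: GO:2", "name: b", "is_a: GO:1"), cyc)
  expect_error(parse_obo(cyc), "[Cc]ycle", class = "coexnet_obo_error")
})

test_that("ancestor sets of a synthetic DAG equal the closure oracle", {
  sim <- simulate_annotations(sprintf("g%03d", 1:50), n_terms = 50,
                              dag_depth = 4, seed = 42)
  dag <- sim$dag
  for (id in sample(dag$terms$term_id, 15)) {
    expect_setequal(go_ancestors(dag, id), oracle_ancestors(dag$parents, id))
  }
  # and the DAG survives an OBO round trip
  obo <- withr::local_tempfile(fileext = ".obo")
  write_obo(dag, obo)
  back <- parse_obo(obo)
  expect_setequal(back$terms$term_id, dag$terms$term_id)
  expect_identical(back$parents[dag$terms$term_id],
                   dag$parents[dag$terms$term_id])
})

test_that("annotation propagation adds exactly the ancestor records", {
  obo <- withr::local_tempfile(fileext = ".obo")
  writeLines(chain_obo_lines(), obo)
  dag <- parse_obo(obo)
  ann <- tibble::tibble(gene_id = "g1", namespace = "GO",
                        term_id = "GO:0000003", description = "leaf process")
  prop <- propagate_annotations(ann, dag)
  expect_setequal(prop$term_id[prop$gene_id == "g1"],
                  c("GO:0000001", "GO:0000002", "GO:0000003"))
  # idempotent
  expect_identical(nrow(propagate_annotations(prop, dag)), nrow(prop))
  # unknown terms warn and drop
  ann_bad <- tibble::tibble(gene_id = "g1", namespace = "GO",
                            term_id = "GO:9999999", description = "x")
  expect_warning(out <- propagate_annotations(ann_bad, dag), "absent")
  expect_identical(nrow(out), 0L)

  # random DAG: per-gene closure oracle
  sim <- simulate_annotations(sprintf("g%03d", 1:40), n_terms = 30,
                              dag_depth = 3, seed = 9)
  prop2 <- propagate_annotations(sim$annotations, sim$dag)
  for (g in unique(sim$annotations$gene_id)[1:10]) {
    direct <- sim$annotations$term_id[sim$annotations$gene_id == g]
    want <- unique(c(direct, unlist(lapply(direct, oracle_ancestors,
                                           parents = sim$dag$parents))))
    expect_setequal(prop2$term_id[prop2$gene_id == g], want)
  }
  # propagation never removes annotations; term counts grow monotonically
  k_before <- table(sim$annotations$term_id)
  k_after <- table(prop2$term_id)
  expect_true(all(k_after[names(k_before)] >= k_before))
})

test_that("Fisher enrichment matches exhaustive enumeration", {
  # N = 100 genes, a term covering K = 10; study of 10 hits k = 5
  genes <- sprintf("g%03d", 1:100)
  ann <- dplyr::bind_rows(
    tibble::tibble(gene_id = genes[1:10], namespace = "Pfam",
                   term_id = "PF1", description = "hit domain"),
    tibble::tibble(gene_id = genes, namespace = "Pfam",
                   term_id = "PF0", description = "universal domain"))
  study <- c(genes[1:5], genes[11:15])
  res <- enrich(study, ann, namespace = "Pfam")
  row <- res[res$term_id == "PF1", ]
  expect_identical(row$study_count, 5L)
  expect_identical(row$population_count, 10L)
  expect_equal(row$p_raw, oracle_fisher(5, 10, 10, 100), tolerance = 1e-12)
  expect_equal(row$p_raw, stats::fisher.test(
    matrix(c(5, 5, 5, 85), 2))$p.value, tolerance = 1e-7)
  expect_identical(row$direction, "over")

  # a term covering the whole background is uninformative: p = 1, "over"
  all_row <- res[res$term_id == "PF0", ]
  expect_equal(all_row$p_raw, 1)
  expect_identical(all_row$direction, "over")

  # the full background as the study gives p = 1 everywhere
  res_all <- enrich(genes, ann, namespace = "Pfam")
  expect_true(all(res_all$p_raw == 1))

  expect_error(enrich(character(), ann, namespace = "Pfam"), "[Ee]mpty")
  expect_error(enrich("not_a_gene", ann, namespace = "Pfam"),
               class = "coexnet_unknown_gene")
})

test_that("two-sided Fisher p equals enumeration across random tables", {
  withr::with_seed(77, {
    for (i in 1:200) {
      N <- sample(5:200, 1)
      K <- sample(1:N, 1)
      n <- sample(1:N, 1)
      k <- sample(max(0, n - (N - K)):min(n, K), 1)
      expect_equal(coexnet:::fisher_two_sided(k, K, n, N),
                   oracle_fisher(k, K, n, N), tolerance = 1e-10)
    }
  })
})

test_that("BH adjustment equals the step-up formula", {
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), class = "coexnet_value_error")

  withr::with_seed(5, {
    p <- runif(1000)
  })
  adj <- bh_adjust(p)
  expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
  expect_true(all(adj >= p - 1e-15))
  # invariance under permutation
  perm <- withr::with_seed(6, sample(1000))
  expect_equal(bh_adjust(p[perm]), adj[perm])
})

test_that("GO propagation feeds enrichment and respects the background choice", {
  sim <- simulate_annotations(sprintf("g%03d", 1:200), n_terms = 40,
                              dag_depth = 3,
                              enriched = list(genes = sprintf("g%03d", 1:20),
                                              prob = 1),
                              background_prob = 0.05, seed = 33)
  study <- sprintf("g%03d", 1:20)
  res <- enrich(study, sim$annotations, namespace = "GO", dag = sim$dag,
                background = sprintf("g%03d", 1:200))
  expect_identical(res$term_id[1], sim$truth$enriched_term)
  expect_identical(res$direction[1], "over")
  expect_true(res$fdr[1] < 1e-6)
  # a larger background cannot shrink K for the planted term
  res_small <- enrich(study, sim$annotations, namespace = "GO", dag = sim$dag)
  k_big <- res$population_count[res$term_id == sim$truth$enriched_term]
  k_small <- res_small$population_count[res_small$term_id == sim$truth$enriched_term]
  expect_identical(k_big, k_small)
})

test_that("word frequencies tokenize significant term names", {
  res <- tibble::tibble(
    term_id = c("t1", "t2", "t3"), namespace = "GO",
    name = c("terpenoid biosynthesis", "terpenoid transport", "kinase cascade"),
    study_count = 1L, study_size = 1L, population_count = 1L,
    population_size = 2L, direction = "over",
    p_raw = c(0.001, 0.001, 0.9), fdr = c(0.01, 0.01, 0.9))
  class(res) <- c("enrichment_result", class(tibble::tibble()))
  freq <- term_word_frequencies(res)
  expect_identical(freq$count[freq$word == "terpenoid"], 2L)
  expect_false("kinase" %in% freq$word)
  expect_identical(nrow(term_word_frequencies(res, fdr_cutoff = 1e-6)), 0L)

  # loop oracle over tokens of the significant names
  sig_names <- res$name[res$fdr < 0.05]
  toks <- unlist(strsplit(tolower(sig_names), "[^a-z0-9]+"))
  toks <- toks[nzchar(toks) & !toks %in% coexnet:::coexnet_stopwords]
  want <- sort(table(toks), decreasing = TRUE)
  expect_identical(sum(freq$count), length(toks))
  for (w in names(want)) {
    expect_identical(freq$count[freq$word == w], as.integer(want[[w]]))
  }
})
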