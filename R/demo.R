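#' Oil-body-style demo data set
#'
#' A self-contained synthetic study shaped like a marker-gene case study: a
#' co-expression module of 29 genes (4 "bait" marker genes plus 25 genes
#' annotated with a shared pathway keyword) planted in a 560-gene expression
#' compendium, two mutant-vs-wild-type count experiments in which the module
#' is upregulated, a toy GO DAG with one term planted exactly on the module's
#' annotated genes, and KOG/Pfam/NAME annotations. It exercises the full
#' workflow: differential expression on each experiment, set relations of the
#' up-gene lists, a bait-centered functional network with keyword filtering,
#' and term enrichment of the recovered genes.
#'
#' @param seed Integer seed; every component derives from it.
#' @param dir Optional directory: when given, all inputs are written there as
#'   TSV/OBO files (`expression.tsv`, `counts_mutA.tsv`, `counts_mutB.tsv`,
#'   `samples_mutA.tsv`, `samples_mutB.tsv`, `annotations.tsv`, `ontology.obo`).
#' @return List with `expression`, `counts_mutA`, `counts_mutB` (each a
#'   [simulate_counts()] result), `annotations`, `dag`, `bait_genes`,
#'   `module_genes` (the 25 annotated members), `keyword`, `enriched_term`.
#' @export
oil_body_demo <- function(seed = 1, dir = NULL) {
  n_genes <- 560
  expr <- simulate_expression(n_genes = n_genes, n_samples = 24,
                              modules = c(oil_body = 29), noise_sd = 0.5,
                              seed = seed)
  members <- expr$truth$modules$oil_body
  baits <- members[1:4]
  module_genes <- members[5:29]
  genes <- rownames(expr$matrix)

  sim_ann <- simulate_annotations(
    genes, n_terms = 40, dag_depth = 3,
    enriched = list(genes = module_genes, prob = 1),
    background_prob = 0.03, seed = seed + 1,
    words = c("lipid", "oxidoreductase", "transport", "kinase", "binding",
              "transferase", "signaling", "response", "membrane", "catabolism")
  )
  kog_cats <- c("Secondary metabolite metabolism", "Signal transduction",
                "Transcription", "General function")
  extra <- withr::with_seed(seed + 2, bind_rows(
    tibble(gene_id = module_genes, namespace = "Pfam", term_id = "PF00494",
           description = "terpenoid biosynthesis enzyme"),
    tibble(gene_id = baits, namespace = "NAME",
           term_id = paste0("NAME:", baits),
           description = paste0("oil body marker ", seq_along(baits))),
    tibble(gene_id = genes, namespace = "KOG",
           term_id = paste0("KOG", sample(seq_along(kog_cats), n_genes,
                                          replace = TRUE)),
           description = sample(kog_cats, n_genes, replace = TRUE))
  ))
  annotations <- annotation_table(bind_rows(sim_ann$annotations, extra))

  de_lfc <- function(extra_down_at) {
    lfc <- rep(0, n_genes)
    lfc[match(members, genes)] <- 2
    lfc[extra_down_at] <- -2
    lfc
  }
  counts_a <- simulate_counts(n_genes = n_genes, n_per_group = 5,
                              log2fc = de_lfc(101:120), alpha = 0.1,
                              baseline_mean = 100, seed = seed + 3)
  counts_b <- simulate_counts(n_genes = n_genes, n_per_group = 5,
                              log2fc = de_lfc(151:170), alpha = 0.1,
                              baseline_mean = 100, seed = seed + 4)
  # count genes share the expression matrix's ID space
  rn <- function(x) { dimnames(x$counts)[[1]] <- genes; x$counts <- count_matrix(unclass(x$counts)); x }
  counts_a <- rn(counts_a)
  counts_b <- rn(counts_b)

  out <- list(expression = expr$matrix, counts_mutA = counts_a,
              counts_mutB = counts_b, annotations = annotations,
              dag = sim_ann$dag, bait_genes = baits,
              module_genes = module_genes, keyword = "terpenoid",
              enriched_term = sim_ann$truth$enriched_term)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_expression_matrix(out$expression, file.path(dir, "expression.tsv"))
    write_expression_matrix(counts_a$counts, file.path(dir, "counts_mutA.tsv"))
    write_expression_matrix(counts_b$counts, file.path(dir, "counts_mutB.tsv"))
    readr::write_tsv(counts_a$samples, file.path(dir, "samples_mutA.tsv"), progress = FALSE)
    readr::write_tsv(counts_b$samples, file.path(dir, "samples_mutB.tsv"), progress = FALSE)
    readr::write_tsv(annotations, file.path(dir, "annotations.tsv"), progress = FALSE)
    write_obo(sim_ann$dag, file.path(dir, "ontology.obo"))
  }
  out
}
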