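#' Simulate a log2-scale expression matrix with planted co-expression modules
#'
#' Each module is driven by a latent profile — a smooth random walk across
#' samples with unit step size — and every member gene observes that profile
#' plus independent Gaussian noise, so within-module correlation is high
#' regardless of sample count. Background genes fluctuate independently
#' around gene-specific baselines. All randomness derives from `seed`, and
#' the caller's RNG state is left untouched.
#'
#' @param n_genes Total genes.
#' @param n_samples Samples (conditions).
#' @param modules Integer vector of module sizes (named or not); sizes must
#'   sum to at most `n_genes`.
#' @param noise_sd Per-cell Gaussian noise SD on the log2 scale; default 0.5,
#'   a realistic replicate-level spread for log-transformed TPM.
#' @param baseline_mean,baseline_sd Distribution of background-gene baselines
#'   (log2 scale).
#' @param seed Integer seed.
#' @return List: `matrix` (log2-scale `expr_matrix`), `truth` (list with
#'   `modules` — named list of member gene IDs — `noise_sd`, `seed`).
#' @export
simulate_expression <- function(n_genes = 500, n_samples = 24,
                                modules = c(module1 = 20), noise_sd = 0.5,
                                baseline_mean = 5, baseline_sd = 2, seed = 1) {
  if (noise_sd < 0) coex_abort("`noise_sd` must be non-negative.")
  if (sum(modules) > n_genes) {
    coex_abort("Module sizes exceed the number of genes.", class = "coexnet_value_error")
  }
  if (is.null(names(modules))) names(modules) <- paste0("module", seq_along(modules))
  withr::with_seed(seed, {
    genes <- sprintf("g%04d", seq_len(n_genes))
    samples <- sprintf("s%03d", seq_len(n_samples))
    vals <- matrix(rnorm(n_genes * n_samples,
                         mean = rnorm(n_genes, baseline_mean, baseline_sd),
                         sd = noise_sd),
                   n_genes, n_samples, dimnames = list(genes, samples))
    truth_modules <- list()
    at <- 1L
    for (m in names(modules)) {
      size <- modules[[m]]
      members <- genes[at:(at + size - 1L)]
      latent <- cumsum(rnorm(n_samples))        # smooth shared trajectory
      vals[members, ] <- matrix(rep(latent, each = size), size, n_samples) +
        rnorm(size, baseline_mean, baseline_sd) +
        matrix(rnorm(size * n_samples, 0, noise_sd), size, n_samples)
      truth_modules[[m]] <- members
      at <- at + size
    }
    list(matrix = expression_matrix(vals, scale = "log2"),
         truth = list(modules = truth_modules, noise_sd = noise_sd, seed = seed))
  })
}

#' Simulate an NB count matrix with planted fold changes
#'
#' Counts follow a negative binomial with variance `mu + alpha * mu^2`:
#' group-1 mean = per-gene baseline, group-2 mean = baseline times
#' `2^log2fc`, both scaled by a per-sample depth multiplier. Setting
#' `poisson = TRUE` draws Poisson counts (the `alpha -> 0` limit).
#'
#' @param n_genes Genes.
#' @param n_per_group Replicates per group (scalar or length-2); at least 3,
#'   the usual minimum for dispersion estimation.
#' @param log2fc True log2 fold changes: a scalar or length-`n_genes` vector
#'   (0 = null gene).
#' @param alpha NB dispersion (> 0 unless `poisson`).
#' @param baseline_mean Mean of the baseline distribution.
#' @param baseline_sdlog Log-normal spread of baselines; 0 makes every
#'   baseline exactly `baseline_mean`.
#' @param depth_multipliers Optional per-sample depth factors (length = total
#'   samples); default all 1.
#' @param poisson Draw Poisson counts instead of NB.
#' @param seed Integer seed.
#' @return List: `counts` (`count_matrix`), `samples` ([sample_table()] with
#'   groups `"group1"`/`"group2"`), `truth` (tibble `gene_id`, `baseline`,
#'   `log2fc`, plus `alpha` and `seed` attributes).
#' @export
simulate_counts <- function(n_genes = 2000, n_per_group = 3, log2fc = 0,
                            alpha = 0.1, baseline_mean = 100,
                            baseline_sdlog = 1, depth_multipliers = NULL,
                            poisson = FALSE, seed = 1) {
  if (!poisson && alpha <= 0) coex_abort("`alpha` must be > 0 (or use `poisson = TRUE`).")
  if (length(n_per_group) == 1L) n_per_group <- rep(n_per_group, 2L)
  if (any(n_per_group < 3L)) {
    coex_abort("Each group needs >= 3 replicates.", class = "coexnet_replicate_error")
  }
  lfc <- rep_len(log2fc, n_genes)
  n_total <- sum(n_per_group)
  depth <- depth_multipliers %||% rep(1, n_total)
  if (length(depth) != n_total) coex_abort("`depth_multipliers` must cover every sample.")
  withr::with_seed(seed, {
    genes <- sprintf("g%04d", seq_len(n_genes))
    samp <- c(sprintf("c%02d", seq_len(n_per_group[1L])),
              sprintf("t%02d", seq_len(n_per_group[2L])))
    grp <- rep(c("group1", "group2"), n_per_group)
    baseline <- if (baseline_sdlog > 0) {
      rlnorm(n_genes, log(baseline_mean), baseline_sdlog)
    } else rep(baseline_mean, n_genes)
    mu <- outer(baseline, rep(1, n_total)) *
      2^outer(lfc, as.numeric(grp == "group2")) *
      matrix(depth, n_genes, n_total, byrow = TRUE)
    draws <- if (poisson) rpois(length(mu), mu) else
      rnbinom(length(mu), size = 1 / alpha, mu = mu)
    cts <- matrix(draws, n_genes, n_total, dimnames = list(genes, samp))
    truth <- tibble(gene_id = genes, baseline = baseline, log2fc = lfc)
    attr(truth, "alpha") <- if (poisson) 0 else alpha
    attr(truth, "seed") <- seed
    list(counts = count_matrix(cts),
         samples = sample_table(sample_id = samp, group = grp),
         truth = truth)
  })
}

#' Simulate an annotation table with a toy GO DAG
#'
#' Builds a layered random DAG (each non-root term gets one or two parents
#' from the previous layer), annotates genes to leaf-layer terms at a uniform
#' background probability, and optionally plants one term whose annotation
#' probability is elevated within a chosen gene subset — the ground truth for
#' enrichment testing. The DAG round-trips through [write_obo()] /
#' [parse_obo()].
#'
#' @param genes Character vector of gene IDs.
#' @param n_terms Total number of terms (>= 3).
#' @param dag_depth Number of layers below the root (>= 1).
#' @param enriched Optional list `(genes = <subset>, prob = <probability>)`;
#'   the planted term (ID returned in `truth`) is annotated to each subset
#'   gene with this probability and to no others.
#' @param background_prob Per (gene, leaf-term) annotation probability.
#' @param words Vocabulary that term names are drawn from (pairs of words);
#'   override to control which keywords can appear in background terms.
#' @param seed Integer seed.
#' @return List: `annotations` (GO-namespace annotation table), `dag`
#'   (`go_dag`), `truth` (list with `enriched_term`, `enriched_genes`).
#' @export
simulate_annotations <- function(genes, n_terms = 50, dag_depth = 3,
                                 enriched = NULL, background_prob = 0.05,
                                 words = c("terpenoid", "lipid",
                                           "phenylpropanoid", "oxidoreductase",
                                           "transport", "biosynthesis",
                                           "metabolism", "kinase", "binding",
                                           "transferase", "signaling",
                                           "response", "membrane", "catabolism"),
                                 seed = 1) {
  if (dag_depth < 1) coex_abort("`dag_depth` must be >= 1.", class = "coexnet_value_error")
  if (n_terms < dag_depth + 2L) coex_abort("`n_terms` too small for the requested depth.")
  withr::with_seed(seed, {
    ids <- sprintf("GO:%07d", seq_len(n_terms))
    layer <- c(0L, sort(sample(rep(seq_len(dag_depth), length.out = n_terms - 1L))))
    parents <- setNames(rep(list(character()), n_terms), ids)
    for (i in seq_len(n_terms)[-1L]) {
      pool <- ids[layer == layer[i] - 1L]
      parents[[i]] <- sample(pool, min(length(pool), sample(1:2, 1L)))
    }
    term_names <- paste(sample(words, n_terms, replace = TRUE),
                        sample(words, n_terms, replace = TRUE))
    dag <- structure(list(
      terms = tibble(term_id = ids, name = term_names,
                     namespace = "biological_process"),
      parents = parents
    ), class = "go_dag")
    leaves <- ids[layer == dag_depth]
    planted <- if (is.null(enriched)) character() else sample(leaves, 1L)
    bg_leaves <- setdiff(leaves, planted)   # planted term gets no background hits
    hit <- which(matrix(runif(length(genes) * length(bg_leaves)),
                        length(genes)) < background_prob, arr.ind = TRUE)
    ann <- tibble(gene_id = genes[hit[, 1L]], namespace = "GO",
                  term_id = bg_leaves[hit[, 2L]])
    truth <- list(enriched_term = NA_character_, enriched_genes = character())
    if (!is.null(enriched)) {
      prob <- enriched$prob %||% 1
      got <- enriched$genes[runif(length(enriched$genes)) < prob]
      ann <- bind_rows(ann, tibble(gene_id = got, namespace = "GO",
                                   term_id = planted))
      truth <- list(enriched_term = planted, enriched_genes = got)
    }
    name_of <- setNames(dag$terms$name, dag$terms$term_id)
    ann$description <- unname(name_of[ann$term_id])
    list(annotations = annotation_table(distinct(ann)), dag = dag, truth = truth)
  })
}
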