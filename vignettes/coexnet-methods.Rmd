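---
title: "Methods behind coexnet: co-expression scoring, networks, enrichment and differential expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind coexnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexnet)
```

`coexnet` implements the analysis core of a co-expression study on a bulk
RNA-seq compendium: many heterogeneous samples quantified as TPM, a raw
count matrix for pairwise differential expression, and gene annotations in
the GO/KEGG/KOG/Pfam namespaces. This vignette is the package's account of
the models and of every numerical choice a user may want to audit.

## Expression scale

All correlation and exploratory analyses operate on `log2(TPM + 0.25)`. The
pseudocount keeps the transform defined at zero abundance (a TPM of 0 maps
to −2) while compressing the mean-variance relationship of abundance data;
it is strictly monotone and exactly invertible, which
`inverse_log_transform()` exploits. The scale is carried as an explicit flag
on the matrix, and every consumer checks it — there is no silent
double-transformation, and orientation (genes in rows, samples in columns)
is fixed rather than auto-detected.

Per-sample QC values (e.g. mapping rates) are supplied metadata, never
computed here. `filter_samples()` drops samples strictly below the
threshold, defaulting to 0.5 — the conventional "at least half the reads
map" bar for including a public run. Samples without a QC value are kept:
absence of evidence is not failure.

## Co-expression scores

For genes A and B the Pearson correlation r is computed over the selected
samples, with a two-sided p-value from the exact transform
t = r·sqrt((n−2)/(1−r²)) on n−2 degrees of freedom. Within gene A's partner
list, ranked by descending correlation, gene B occupies rank\_A(B) (a gene's
rank against itself is 0). The two symmetric scores are

- HRR(A,B) = max(rank_A(B), rank_B(A)) — the highest reciprocal rank;
- MR(A,B) = sqrt(rank_A(B) · rank_B(A)) — the mutual rank.

Since a geometric mean never exceeds a maximum, MR ≤ HRR everywhere; both
are symmetric by construction and invariant under gene relabeling. Ranks
are useful precisely because they are scale-free: a gene with globally high
correlations is not automatically a hub.

Three choices here were genuinely open:

- **Ties.** Tied correlations receive fractional (average) ranks. This
  makes scores deterministic and stable under permutation of the input, at
  the price of non-integer HRR/MR values — which the formulas permit.
- **Degenerate genes.** A gene with zero variance over the selected samples
  has no defined correlation; it is flagged, excluded as a partner from
  nobody's ranking denominator, and sorted below every finite correlation.
- **p-value multiplicity.** Pairwise correlation p-values are emitted raw;
  with ~10^7 pairs any correction is a global modeling decision we leave to
  the caller.

Dense gene×gene matrices are the contract; they are practical to roughly
2×10^4 genes (3–4 GB per matrix), which covers a full plant gene complement.
Larger universes are out of scope for this implementation.

## Networks

`build_graph()` draws an undirected edge wherever MR < cutoff (strict, to
match the conventional "MR < 30" notation); isolated genes remain nodes.
The default cutoff of 30 is a stringent choice suitable for drawn networks;
tabular exploration typically uses looser cutoffs (1000–2000), and every
cutoff is an argument. `neighborhood()` performs breadth-first traversal
from a query set (default radius 3); `functional_network()` widens the
radius to 10 around multiple baits and then filters non-bait genes by a
case-insensitive literal substring match against the concatenated
name/KOG/KEGG/Pfam/GO description text. Order matters and is fixed:
traverse first, then filter, and do not re-route distances through removed
genes — the keyword restricts what is *shown*, not what is *reachable*.
Multiple keywords combine as OR; there is no stemming.

## Enrichment

`enrich()` tests each annotation term with at least one background gene by
the two-sided Fisher's exact test on the table (k, n−k; K−k, N−K−n+k),
computed by summing hypergeometric point masses no larger than the observed
one (the customary 1+1e-7 relative tolerance). Direction is labeled "over"
when k/n ≥ K/N (equality is uninformative and conventionally "over") and
"under" otherwise, so a single FDR family covers both directions.
Benjamini–Hochberg adjustment is applied per namespace per run.

GO annotations are propagated to ancestors (via `is_a` and `part_of`)
before testing, the standard GOEA semantics; propagation is idempotent,
never removes records, and can be disabled. KEGG/KOG/Pfam are flat. The
default background is every gene with ≥ 1 annotation in the tested
namespace; passing the full gene universe instead changes N and K and
therefore every p-value, which is why the choice is an explicit argument.
The OBO 1.2 parser keeps non-obsolete `[Term]` stanzas and validates the
DAG (no dangling parents, no cycles). The stop-word list used by
`term_word_frequencies()` ships with the package so word counts are
reproducible.

## Differential expression

The two-group stage models counts as NB(μ, α) with variance μ + αμ²:

1. **Size factors** by median-of-ratios over genes with positive counts in
   every sample (a pseudo-reference flag handles sparse matrices), computed
   on the two selected groups only.
2. **Dispersion** per gene by moments on normalized counts with
   within-group pooling: α̂ = max((pooled var − pooled mean)/pooled mean²,
   1e-8). Closed-form and deterministic; genes at or below Poisson variance
   land on the floor.
3. **GLM fit**: log-link NB regression (intercept + group indicator, log
   size factors as offsets) by iteratively reweighted least squares,
   vectorized across genes; at most 50 iterations, relative coefficient
   tolerance 1e-8. Non-converged genes are reported with missing p-values
   and excluded from the BH family; all-zero genes are skipped up front.
4. **Test**: Wald statistic β/SE from the expected information. The p-value
   uses a t reference with n−2 residual degrees of freedom rather than a
   normal one: with 3–5 replicates the moment dispersion is itself noisy,
   and treating it as known makes a normal reference anticonservative. The
   null false-positive rate under the t reference is measured directly by
   the test suite and the acceptance script on 2000 simulated null genes.

This is deliberately a simple, fully-specified stage, not a DESeq2 clone:
no dispersion trend or MAP shrinkage, no outlier replacement, no
independent filtering, no LFC shrinkage. On planted-effect simulations it
recovers log2 fold changes with correlation ≥ 0.95 and power ≥ 0.8 at
|lfc| = 2 (5 vs 5, mean 100, α = 0.1), which is the accuracy the
surrounding tools need. Both groups must have ≥ 3 biological replicates;
the requirement is enforced, not advisory.

Classification for volcano views is `up` when padj < α and log2fc exceeds
the (default 0) threshold, `down` symmetrically, otherwise `ns`.

## Set relations

`exclusive_intersections()` partitions the union of k ≥ 2 gene sets into
the at most 2^k − 1 non-empty exclusive regions (each gene belongs to the
region of exactly the sets containing it), checked on every run: regions
are disjoint and reconstruct the union. Duplicate IDs within a set are
dropped with a message; no gene-universe validation is applied because the
inputs are bare ID lists. Region tables are ordered by size, ties broken by
label. A region's gene list feeds `enrich()` unchanged.

## Exploratory analysis

Sample clustering uses Ward linkage (`ward.D2`, i.e. Ward on Euclidean
distances, matching the common scientific-Python default) on full gene
vectors with no variance pre-filtering — with heterogeneous compendia the
signal of interest is exactly the global profile. PCA centers each gene and
does not scale to unit variance; component signs are fixed by forcing each
axis's largest-magnitude loading positive, so coordinates are reproducible
across platforms.

## Synthetic data: what it emulates, and what it does not

The generators exist so every stage is testable without downloads, and
their defaults are the package's reference study conditions.

- `simulate_expression()` (500 genes × 24 samples, one 20-gene module,
  noise SD 0.5): each module follows a latent smooth random walk across
  samples; members observe it plus independent Gaussian noise. A latent
  factor guarantees high within-module correlation regardless of sample
  count, which a multivariate-normal covariance specification does not.
  Noise SD 0.5 on the log2 scale is a realistic replicate-level spread.
- `simulate_counts()` (2000 genes, ≥ 3 replicates per group, dispersion
  0.1, lognormal baselines around 100): NB draws with per-sample depth
  multipliers and planted log2 fold changes; a Poisson flag gives the
  α → 0 limit.
- `simulate_annotations()`: a layered random DAG (each non-root term takes
  1–2 parents from the previous layer), uniform background annotation of
  leaf terms, and optionally one planted term annotated only within a
  chosen gene subset — exact ground truth for enrichment.

What passing tests on these data do **not** show: real compendia have
batch structure, correlated noise between modules, library-composition
bias, annotation incompleteness that varies with gene family, and
mapping-rate artifacts. The generators model none of these, so results
here certify algorithmic correctness and calibration under the stated
model, not robustness to every failure mode of public data.

The end-to-end demo (`oil_body_demo()`) wires the pieces into the shape of
a marker-gene case study: a 29-gene module (4 baits + 25 genes sharing a
pathway keyword) inside a 560-gene compendium, two mutant experiments in
which the module is upregulated, and a planted GO term covering the
annotated module genes. Differential expression on both experiments, set
relations of the up-lists, a keyword-filtered functional network around
the baits, and enrichment of the shared genes recover the planted
structure.

## Problem sizes and determinism

The shipped tests and the acceptance script use desk-scale problems —
hundreds of genes for co-expression, 1000–2000 genes for the count stage,
100-node graphs for traversal checks — sizes at which every oracle
comparison is exact and the whole suite runs in minutes. All generators
take integer seeds, derive every stream from them, and restore the
caller's RNG state, so identical seeds give identical studies across
platforms.

## Known limitations

- Pearson correlation only; rank-based alternatives are out of scope.
- Single dispersion per gene shared across the two groups; no shrinkage.
- Dense score matrices bound the gene universe (~2×10^4).
- Keyword filtering is literal substring matching, with the usual false
  hits (e.g. "kinase" matches "kinase inhibitor").
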