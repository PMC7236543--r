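---
title: "Coexpression networks, overlapping modules and annotation refinement with coexkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coexpression networks, overlapping modules and annotation refinement with coexkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexkit)
```

## The problem

Genome projects for non-model plants typically leave half or more of the
predicted genes without a useful functional annotation. When multiple
transcriptome samples are available, guilt-by-association can close part of
that gap: genes whose expression profiles rise and fall together across
samples tend to act in the same processes, so an unannotated gene inside a
tightly co-expressed group inherits a testable functional hypothesis from its
neighbors. `coexkit` implements this strategy as a complete, tested pipeline:
low-expression filtering, correlation/mutual-rank network construction,
overlapping module detection by clique percolation, over-representation-based
module annotation, per-gene annotation refinement, promoter cis-element
enrichment, and reciprocal-best-hit orthology. A seeded synthetic-data
generator with a recorded ground truth makes every stage verifiable without
any external download.

## The model, stage by stage

### Low-expression filtering

FPKM values near zero carry almost no correlation signal, and genes that are
near zero everywhere only add noise to an all-pairs correlation analysis. The
filter computes, for each sample, the 5th percentile of that sample's FPKM
distribution (linear interpolation between order statistics, zeros included),
then sets

```
threshold = mean(p5 across samples) + 3 * sd(p5 across samples)
```

with the unbiased (n−1) standard deviation. A gene is removed only when it is
strictly below the threshold in *every* sample; one expressed sample rescues
it. Percentile and multiplier are arguments (`percentile`, `sigma`), and a
`groups` option computes per-group thresholds for designs where experimental
groups differ in depth. Both interpolation scheme and the population over
which the percentile is taken (all genes, including zeros) are deliberate
choices: the statistic is meant to track the floor of each sample's
distribution, not the floor of its expressed fraction.

### Correlation and mutual ranks

All gene pairs are scored with the Pearson product-moment correlation of
their FPKM profiles. Weakly correlated pairs (|r| below `min_abs_pcc`,
default 0.6) are discarded before ranking; this pre-filter cutoff is the one
tuning knob with no published value, so it is exposed prominently and
documented as deviation-sensitive. Constant-expression genes have no defined
correlation; they are dropped with a reported count, never silently.

Raw correlation cutoffs treat a hub's 500th-best partner and a peripheral
gene's best partner identically. The mutual rank corrects for this: for each
gene, its retained partners are ranked 1, 2, … and the pair score is the
geometric mean `MR(AB) = sqrt(rank(A→B) · rank(B→A))`. Ranking happens
within sign class — positive partners by descending r, negative partners by
ascending r — so negative co-expression can survive rank-based selection; a
joint `|r|` ranking is available via `rank_mode = "abs"`. Ties break by
partner id, which makes ranking deterministic and permutation-auditable.

Edges are selected by `min(rank_ab, rank_ba) <= 3` **or** `MR <= 30`
(inclusive cutoffs; the `union` rule). Both cutoffs, the strictness of the
inequality and an `intersection` variant are arguments. A note on scale: at
genome scale (tens of thousands of genes) the MR cutoff is the binding
constraint, because partner lists are long; at the few-hundred-gene scale of
the synthetic benchmark the same cutoffs are close to "keep every pair that
passed the pre-filter". The recovery results below should be read with that
in mind.

`evaluate_cutoffs_roc()` sweeps the MR cutoff against a labelled pair set and
reports TPR/FPR and the trapezoidal AUC. No published labelling exists for
this analysis, so the intended gold standard on synthetic data — same-block
pairs positive, cross-block pairs negative — is the package's own choice.

### Overlapping modules by clique percolation

Functional modules are k-clique-percolation communities: two k-cliques are
adjacent when they share exactly k−1 nodes, and a module is the union of a
connected component of this adjacency. Unlike partitioning methods, genes may
belong to several modules, which matches the biology of multifunctional
genes. The implementation enumerates maximal cliques (via igraph) and links
maximal cliques sharing at least k−1 nodes — the standard acceleration, whose
equivalence to the direct definition is exercised in tests against an
exhaustive all-subsets oracle. Edge sign is ignored during clique detection
by default (`positive_only = TRUE` restricts to positive edges). `scan_k()`
tabulates module count and gene coverage over a k range and recommends the k
maximizing coverage, breaking ties by module count — a lexicographic reading
of the "maximize coverage and module number" goal; because coverage is
monotone non-increasing in k, this recommendation is a floor, and users
wanting fewer, denser modules should inspect the scan table. The default
single-run k is 5 (a module therefore has at least five genes).

### Module annotation and per-gene refinement

Module annotation is over-representation analysis: the exact hypergeometric
upper tail `P(X >= overlap)` (Fisher's one-sided test) for every
(module, term) pair, followed by Benjamini–Hochberg adjustment within each
term namespace (GO, KEGG, PO, GFam, …), with `fdr < 0.05` as the default
significance flag. The multiple-testing procedure is BH because the target
quantity is an FDR; Bonferroni is available. The background defaults to the
genes of the filtered expression matrix — enrichment should be judged
against the genes that could have appeared in a module, not the whole
genome — with a genome-wide background selectable.

Refinement is two-step. First, every gene of a module inherits the module's
significant terms (provenance `module`). Second, each network gene's direct
neighbor set is itself tested for over-representation, FDR-adjusted per gene,
and significant terms are appended (provenance `neighbor`). Neighbor-derived
terms never displace inherited ones. The `z` flag re-scores enrichment
results against overlaps of random same-size gene sets — the same
randomization null used for promoter motifs, reused here because no separate
construction is published for term Z scores; it is an interpretation aid,
not a second test.

### Promoter cis-element enrichment

`scan_promoter()` counts exact IUPAC-consensus matches on both strands
(motif scanned over the sequence and over its reverse complement), overlaps
allowed, with `N` in a promoter matching nothing. PWM scoring is out of
scope. `motif_zscore()` sums counts over a gene list and compares against
`n_draws` random same-size gene sets:

```
Z = (observed − null_mean) / null_sd
empirical_p = (1 + #draws ≥ observed) / (1 + n_draws)
```

The underlying formula is sometimes written with `σ/√n`; with `n` equal to
the number of draws that denominator is the standard error of the null mean
and inflates Z roughly 32-fold at 1000 draws, so plain standardization is
the default and the literal convention sits behind `mode = "literal"`. The
empirical p-value (with the +1 pseudocount so it is never zero) is always
reported and is the robust selection criterion; `significant_motifs()`
filters at `p < 0.05`.

### Orthology from alignment tables

The module consumes 12-column tabular alignment hits (it never runs an
aligner). After collapsing to the best HSP per (query, subject) — lowest
E-value, ties by bit score — subjects are ranked per query and pairs that
appear in both directions' top-`top_n` lists become best-tier orthologs.
"Top three hits" admits two readings; reciprocal-top-3 is the default and
strict RBH is `top_n = 1`. The secondary tier takes the E-value at the modal
bin of the best pairs' log10 E-value histogram (Freedman–Diaconis widths,
ties to the more significant bin, zeros floored at 1e-180) as a threshold
and admits reciprocal pairs of any rank below it, comparing the smaller of
the two directional E-values by default (`compare = "max"` requires both).

## The synthetic-data generator

`generate_expression()` draws, for each planted block, one latent sample
profile; block genes mix that profile with independent Gaussian noise
(`z = sqrt(rho)·L + sqrt(1−rho)·noise_sd·ε`, so the latent within-block
correlation is exactly `rho` at `noise_sd = 1`) and are mapped through
`exp(baseline + log_scale·z)` to give non-negative, right-skewed, FPKM-like
marginals. A configurable fraction of off-block genes is "unexpressed"
(uniform below a small ceiling) so the 3σ filter has a real target; the
default fraction (4%) sits below the filter's 5th-percentile statistic so
that the planted unexpressed population falls wholly below the computed
threshold. Gene sets, promoters (with a Poisson-inserted consensus motif and
a full insertion ledger) and reciprocal alignment tables with strictly-worse
decoys complete the inputs; every generator records its ground truth, and
all randomness flows from one integer seed, so identical seeds give
identical bytes.

Two constructions deserve emphasis because they are what make the planted
truth *identifiable in the generated sample*, not just in expectation, at
realistic sample counts:

* **Orthogonal block profiles.** With a dozen samples, two independently
  drawn profiles can correlate above 0.6 by chance, silently merging two
  "distinct" blocks. Profiles are therefore centered and orthogonalized
  (exact zero pairwise sample correlation) whenever `n_blocks < n_samples`.
* **Flattened off-block noise.** The same small-sample effect would let
  off-block genes fake co-expression with a block. There is a dimensional
  constraint here: with 12 samples and 10 block profiles, only one centered
  dimension remains, so noise genes cannot simply be projected away from the
  block subspace — they would all collapse onto one direction and become
  mutually correlated. Instead, each off-block gene's correlation with every
  block profile is set to exactly the null scale `1/sqrt(n_samples − 1)`
  with an independent random sign, the remainder lying in the orthogonal
  complement. This reproduces the typical null association (the same
  standard deviation an i.i.d. draw would give) while removing the upper
  tail. The `log_scale` default (0.25) keeps the exponential map close
  enough to linear that these latent-scale guarantees survive on the FPKM
  scale; larger values let single extreme samples dominate product-moment
  correlations and re-introduce spurious associations.

What the generator consequently does **not** emulate: chance correlations of
truly independent genes at small n (flattened away), library-size or batch
effects, count noise at low expression, overlapping regulatory programs, and
genome-scale gene counts. Passing the recovery benchmarks therefore
demonstrates that the pipeline's machinery is correct and calibrated — not
that real small-n data are free of spurious edges. On real data the
pre-filter and MR cutoffs, not geometry, are the only defense.

## Numerical choices

* Percentiles: linear interpolation (R type 7); SD: unbiased n−1 form.
* Rank ties: ordinal, broken by partner gene id; ranking within sign class.
* Edge cutoffs inclusive (`<=`); `strict = TRUE` switches both.
* Rounding for report figures: half away from zero (one decimal for mean
  degree and module size, two for coverage) so printed summaries are
  reproducible across platforms.
* Empirical p-values use the +1 pseudocount; Z is undefined (flagged, not
  infinite) when the null SD is zero.
* E-value zeros floored at 1e-180 before log histograms.
* ROC ties: all tied pairs enter together; trapezoidal integration gives
  AUC 0.5 for indistinguishable scores.
* Problem sizes used by the test-suite benchmarks (500 genes × 12 samples,
  10 planted blocks of 20; 1000 promoters of 3 kb; 200 + 200 proteins with
  150 orthologs) are desk-scale study conditions chosen so the whole suite
  runs in minutes; the published networks are three orders of magnitude
  larger, and nothing in the implementation depends on these sizes.

## Known limitations

* Pearson correlation only; no Spearman/mutual-information option, no
  WGCNA-style soft thresholds, no partial correlations.
* CPM is unweighted and undirected; very dense graphs can produce giant
  communities (a known property of percolation, not a bug).
* GO term relationships are ignored (no ancestor propagation), and the
  rank-based flavor of gene-set enrichment is deliberately not implemented —
  the published procedure is the Fisher/FDR form.
* Motif scanning is exact-consensus; degenerate matrices (PWMs) are out of
  scope, and motif definitions are user input.
* The MR and rank cutoffs were published for genome-scale networks; at
  desk scale they are close to non-binding (see above).

## A worked desk-scale run

```{r example, eval = FALSE}
sim <- generate_expression(500, 12, n_blocks = 10, block_size = 20,
                           rho = 0.95, seed = 7)
filt <- filter_low_expression(sim$expression,
                              compute_fpkm_threshold(sim$expression))
net <- select_edges(compute_mutual_ranks(compute_pcc_pairs(filt, 0.6)),
                    genome_size = 500)
glance(net)
mods <- clique_percolation(net, k = 5)
sets <- generate_genesets(sim$truth, n_noise_terms = 10, seed = 7)
ann <- annotate_modules(mods, sets, background = filt$gene_id)
refined <- refine_gene_annotations(net, mods, ann, sets,
                                   background = filt$gene_id)
attr(refined, "annotated_fraction")
```

The same flow, file-based and atomic, is available as `run_pipeline()` with
a `pipeline_config()`; `scripts/acceptance.R` at the repository root re-runs
every benchmark quantity from scratch.
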