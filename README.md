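# coexkit

Gene coexpression-network analysis for bulk expression data, aimed at
refining functional annotation in poorly annotated (typically non-model
plant) genomes. Starting from an FPKM matrix of genes × samples, `coexkit`

1. removes unexpressed genes with a 3σ threshold on per-sample lower
   percentiles — `threshold = mean(p5) + 3·sd(p5)`, a gene going only when it
   is below the threshold in *every* sample;
2. scores all gene pairs by Pearson correlation and **mutual rank**,
   `MR(AB) = √(Rank(A→B) · Rank(B→A))`, keeping edges with a directional
   rank ≤ 3 or MR ≤ 30;
3. finds overlapping functional modules by **k-clique percolation** (two
   k-cliques adjacent when sharing k−1 nodes; modules are components of that
   adjacency; default k = 5);
4. annotates modules by Fisher exact over-representation against GO / KEGG /
   PO / gene-family sets with Benjamini–Hochberg control (FDR < 0.05), then
   refines per-gene annotations in two steps (module inheritance +
   enrichment of each gene's direct neighbor set);
5. tests promoter cis-elements in a gene list with a randomization Z score,
   `Z = (X − u)/σ` against 1,000 random same-size gene sets, plus an
   empirical p-value;
6. identifies orthologs from 12-column tabular alignment hits by reciprocal
   top-N pairing, with a secondary tier below the peak of the best-pair
   E-value distribution.

A seeded synthetic-data module (`generate_expression()`,
`generate_genesets()`, `generate_promoters()`,
`generate_alignment_hits()`) produces every pipeline input with a recorded
ground truth, so all stages are testable end to end with no downloads.

Everything is tidyverse-shaped: data frames in, tibbles out, `tidy()` /
`glance()` methods on fitted objects, `autoplot()` for networks, ROC curves
and motif nulls.

## Worked example

```r
library(coexkit)

sim  <- generate_expression(500, 12, n_blocks = 10, block_size = 20,
                            rho = 0.95, seed = 7)
filt <- filter_low_expression(sim$expression,
                              compute_fpkm_threshold(sim$expression))
net  <- select_edges(compute_mutual_ranks(compute_pcc_pairs(filt, 0.6)),
                     genome_size = 500)
glance(net)
#> # A tibble: 1 × 6
#>   edge_count node_count mean_edges_per_gene mean_edges_report coverage_pct coverage_report
#>        <int>      <int>               <dbl>             <dbl>        <dbl>           <dbl>
#> 1       4021        479                16.8              16.8         95.8            95.8

mods <- clique_percolation(net, k = 5)
sets <- generate_genesets(sim$truth, n_noise_terms = 10, seed = 7)
ann  <- annotate_modules(mods, sets, background = filt$gene_id)
ref  <- refine_gene_annotations(net, mods, ann, sets,
                                background = filt$gene_id)
round(attr(ref, "annotated_fraction"), 3)
#> [1] 0.422
```

479 of the 500 simulated genes survive filtering (all 20 planted
"unexpressed" genes fall below the 3.3-FPKM threshold, plus one borderline
low-expressed gene) and form a 4,021-edge network covering 95.8% of the
genome. Each of the 10 planted blocks of 20 co-regulated genes comes back as
its own k = 5 module among the 64 detected, and 42.2% of network genes end
up with at least one refined annotation — including every planted-block gene
with its own block's term; the rest of the network is background genes whose
modules are, correctly, left unannotated.

The same flow runs file-to-file with `run_pipeline(pipeline_config(...))`,
which writes edge lists, module tables, annotation tables and a JSON run
report atomically and reproducibly (identical config + seed ⇒ identical
bytes). A thin command-line wrapper lives at `inst/cli/coexkit.R`.

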