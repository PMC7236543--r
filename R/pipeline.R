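#' Build and validate a pipeline configuration
#'
#' Collects every stage parameter and input path into one validated list.
#' The configuration round-trips losslessly through YAML
#' ([read_pipeline_config()] / [write_pipeline_config()]); its hash appears
#' in the run report so reports are traceable to exact settings.
#'
#' @param expression Path to the FPKM expression TSV (required).
#' @param gmt Path to the gene-set GMT (required for enrichment).
#' @param promoters,motifs,motif_genes Optional paths: promoter FASTA, motif
#'   definitions (name TAB IUPAC consensus per line), and the gene list to
#'   test; all three enable the motif stage.
#' @param hits_ab,hits_ba Optional paths to alignment hit tables; both enable
#'   the orthology stage.
#' @param out_dir Output directory (created if missing).
#' @param percentile,sigma Low-expression threshold parameters.
#' @param min_abs_pcc,rank_cutoff,mr_cutoff,rule Network-construction
#'   parameters.
#' @param k Clique size for module detection.
#' @param fdr_cutoff,z_cutoff Enrichment significance and Z-flag cutoffs.
#' @param n_draws Random draws for motif/Z nulls.
#' @param top_n Reciprocal rank cutoff for orthology.
#' @param genome_size Genome gene count for coverage (defaults to the number
#'   of genes in the expression matrix).
#' @param seed Integer seed governing all randomized stages.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(expression, gmt = NULL, promoters = NULL,
                            motifs = NULL, motif_genes = NULL,
                            hits_ab = NULL, hits_ba = NULL,
                            out_dir = tempfile("coexkit_run_"),
                            percentile = 5, sigma = 3, min_abs_pcc = 0.6,
                            rank_cutoff = 3, mr_cutoff = 30, rule = "union",
                            k = 5, fdr_cutoff = 0.05, z_cutoff = 4,
                            n_draws = 1000, top_n = 3, genome_size = NULL,
                            seed = 1) {
  cfg <- list(
    expression = expression, gmt = gmt, promoters = promoters,
    motifs = motifs, motif_genes = motif_genes,
    hits_ab = hits_ab, hits_ba = hits_ba, out_dir = out_dir,
    percentile = percentile, sigma = sigma, min_abs_pcc = min_abs_pcc,
    rank_cutoff = rank_cutoff, mr_cutoff = mr_cutoff, rule = rule,
    k = k, fdr_cutoff = fdr_cutoff, z_cutoff = z_cutoff,
    n_draws = n_draws, top_n = top_n, genome_size = genome_size,
    seed = as.integer(seed)
  )
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  paths <- c("expression", "gmt", "promoters", "motifs", "motif_genes",
             "hits_ab", "hits_ba")
  for (p in paths) {
    if (!is.null(cfg[[p]])) {
      abort_if(!file.exists(cfg[[p]]),
               paste0("config path `", p, "` does not exist: ", cfg[[p]]))
    }
  }
  abort_if(is.null(cfg$expression), "config requires an expression path")
  abort_if(cfg$min_abs_pcc < 0 || cfg$min_abs_pcc > 1,
           "min_abs_pcc must lie in [0, 1]")
  abort_if(cfg$rank_cutoff <= 0 || cfg$mr_cutoff <= 0,
           "cutoffs must be positive")
  abort_if(!cfg$rule %in% c("union", "intersection"), "unknown rule")
  abort_if(cfg$k < 3, "k must be at least 3")
  abort_if(cfg$fdr_cutoff <= 0 || cfg$fdr_cutoff > 1,
           "fdr_cutoff must lie in (0, 1]")
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#' @param path YAML path.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' Write a pipeline configuration to YAML
#' @param cfg A `pipeline_config`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg)[!vapply(unclass(cfg), is.null, logical(1))],
                   path)
  invisible(path)
}

#' Run the coexpression pipeline end to end
#'
#' Executes filter, network, modules, enrichment and refinement, plus the
#' optional promoter-motif and orthology stages when their inputs are
#' configured. Stages communicate through files under `cfg$out_dir`; every
#' file is written atomically (temp file + rename), and a structured log line
#' reports each stage's input/output sizes. Identical configuration and seed
#' reproduce identical output bytes.
#'
#' @param cfg A `pipeline_config`.
#' @param quiet Suppress per-stage log messages.
#' @return The run report (list, also written as `report.json`): per-stage
#'   sizes and thresholds, network statistics, module summary, annotation
#'   fraction, package version and config hash.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  validate_pipeline_config(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  report <- list(
    package_version = as.character(utils::packageVersion("coexkit")),
    # out_dir does not affect results; hash only the scientific parameters
    config_hash = rlang::hash(unclass(cfg)[setdiff(names(cfg), "out_dir")]),
    seed = cfg$seed
  )

  # filter
  expr <- read_expression_matrix(cfg$expression)
  thr <- compute_fpkm_threshold(expr, percentile = cfg$percentile,
                                sigma = cfg$sigma)
  filtered <- filter_low_expression(expr, thr)
  write_expression_tsv(filtered, file.path(cfg$out_dir, "filtered.tsv"))
  write_tsv_atomic(attr(filtered, "removal_report"),
                   file.path(cfg$out_dir, "removal_report.tsv"))
  write_json_atomic(glance(thr), file.path(cfg$out_dir, "threshold.json"))
  report$filter <- list(genes_in = nrow(expr), genes_out = nrow(filtered),
                        threshold = thr$threshold)
  say("filter: %d -> %d genes (threshold %.4g)", nrow(expr), nrow(filtered),
      thr$threshold)

  # network
  genome_size <- cfg$genome_size %||% nrow(expr)
  pairs <- compute_pcc_pairs(filtered, min_abs_pcc = cfg$min_abs_pcc)
  ranked <- compute_mutual_ranks(pairs)
  network <- select_edges(ranked, rank_cutoff = cfg$rank_cutoff,
                          mr_cutoff = cfg$mr_cutoff, rule = cfg$rule,
                          genome_size = genome_size)
  write_edges_tsv(network, file.path(cfg$out_dir, "edges.tsv"))
  net_stats <- network_statistics(network)
  write_json_atomic(net_stats, file.path(cfg$out_dir, "network_stats.json"))
  report$network <- as.list(net_stats)
  say("network: %d nodes, %d edges", net_stats$node_count,
      net_stats$edge_count)

  # modules
  modules <- clique_percolation(network, k = cfg$k)
  write_modules_tsv(modules, file.path(cfg$out_dir, "modules.tsv"))
  report$modules <- as.list(glance(modules))
  say("modules: %d at k = %d", nrow(modules), cfg$k)

  # enrichment + refinement
  if (!is.null(cfg$gmt)) {
    genesets <- read_gmt(cfg$gmt, background = filtered$gene_id)
    ann <- annotate_modules(modules, genesets, fdr_cutoff = cfg$fdr_cutoff,
                            background = filtered$gene_id)
    write_tsv_atomic(ann, file.path(cfg$out_dir, "module_annotations.tsv"))
    refined <- refine_gene_annotations(network, modules, ann, genesets,
                                       fdr_cutoff = cfg$fdr_cutoff,
                                       background = filtered$gene_id)
    write_tsv_atomic(refined, file.path(cfg$out_dir, "gene_annotations.tsv"))
    report$enrichment <- list(
      n_tests = nrow(ann),
      n_significant = sum(ann$significant),
      annotated_modules = length(unique(ann$subject[ann$significant])),
      annotated_gene_fraction = attr(refined, "annotated_fraction")
    )
    say("enrichment: %d/%d modules annotated; %.1f%% of network genes",
        report$enrichment$annotated_modules, nrow(modules),
        100 * report$enrichment$annotated_gene_fraction)
  }

  # promoter motifs (optional)
  if (!is.null(cfg$promoters) && !is.null(cfg$motifs) &&
      !is.null(cfg$motif_genes)) {
    promoters <- read_promoters_fasta(cfg$promoters)
    motif_tab <- readr::read_tsv(cfg$motifs, col_names = c("name", "motif"),
                                 col_types = "cc", progress = FALSE)
    genes <- readLines(cfg$motif_genes)
    mres <- dplyr::bind_rows(lapply(seq_len(nrow(motif_tab)), function(i) {
      r <- motif_zscore(promoters, genes, motif_tab$motif[i],
                        n_draws = cfg$n_draws,
                        seed = child_seed(cfg$seed, i))
      dplyr::mutate(r, name = motif_tab$name[i], .before = 1)
    }))
    write_tsv_atomic(mres, file.path(cfg$out_dir, "motif_enrichment.tsv"))
    report$motifs <- list(n_motifs = nrow(mres),
                          n_significant = sum(mres$empirical_p < 0.05))
    say("motifs: %d tested, %d at p < 0.05", nrow(mres),
        report$motifs$n_significant)
  }

  # orthology (optional)
  if (!is.null(cfg$hits_ab) && !is.null(cfg$hits_ba)) {
    orth <- find_orthologs(read_hits_tsv(cfg$hits_ab),
                           read_hits_tsv(cfg$hits_ba), top_n = cfg$top_n)
    write_tsv_atomic(orth, file.path(cfg$out_dir, "orthologs.tsv"))
    report$orthology <- list(
      n_best = sum(orth$tier == "best"),
      n_secondary = sum(orth$tier == "secondary"),
      evalue_threshold = attr(orth, "evalue_threshold")
    )
    say("orthology: %d best + %d secondary pairs",
        report$orthology$n_best, report$orthology$n_secondary)
  }

  report$summary <- as.list(summarize_network(
    edge_count = net_stats$edge_count,
    node_count = net_stats$node_count,
    genome_size = genome_size,
    module_count = nrow(modules),
    module_sizes = modules$size
  ))
  write_json_atomic(report, file.path(cfg$out_dir, "report.json"))
  invisible(report)
}

#' Table-style network summary block
#'
#' The reporting conventions used for headline network tables: mean edges per
#' gene `2E / N` rounded half-up to one decimal, mean module size to one
#' decimal, genome coverage `100 N / genome_size` to two decimals.
#'
#' @param edge_count,node_count Network edge and node counts.
#' @param genome_size Optional genome gene count.
#' @param module_count Optional module count.
#' @param module_sizes Optional vector of module sizes.
#' @return One-row tibble: `edge_count`, `node_count`,
#'   `mean_edges_per_gene`, `coverage_pct`, `module_count`,
#'   `mean_module_nodes` (unavailable fields are `NA`).
#' @export
#' @examples
#' summarize_network(630081, 31847)$mean_edges_per_gene # 39.6
summarize_network <- function(edge_count, node_count, genome_size = NULL,
                              module_count = NULL, module_sizes = NULL) {
  mean_edges <- if (node_count > 0) 2 * edge_count / node_count else 0
  tibble::tibble(
    edge_count = edge_count,
    node_count = node_count,
    mean_edges_per_gene = round_half_up(mean_edges, 1),
    coverage_pct = if (!is.null(genome_size) && genome_size > 0) {
      round_half_up(100 * node_count / genome_size, 2)
    } else {
      NA_real_
    },
    module_count = module_count %||% NA_integer_,
    mean_module_nodes = if (!is.null(module_sizes) &&
                            length(module_sizes) > 0) {
      round_half_up(mean(module_sizes), 1)
    } else {
      NA_real_
    }
  )
}
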