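#' Pearson correlation between two expression profiles
#'
#' The standard product-moment correlation of two FPKM vectors across samples.
#' Errors on constant vectors (undefined correlation) rather than returning
#' `NA`, so callers must skip such genes explicitly.
#'
#' @param x,y Numeric vectors of equal length (at least 3 samples).
#' @return The correlation, in \[-1, 1\].
#' @export
#' @examples
#' pearson_correlation(c(1, 2, 3), c(2, 4, 6)) # 1
pearson_correlation <- function(x, y) {
  abort_if(length(x) != length(y), "vectors must have equal length")
  abort_if(length(x) < 3, "at least 3 samples required")
  abort_if(sd(x) == 0 || sd(y) == 0,
           "correlation undefined for a constant vector")
  cor(x, y)
}

#' All gene pairs with strong Pearson correlation
#'
#' Computes the correlation of every unordered gene pair across samples and
#' keeps pairs with `|pcc| >= min_abs_pcc` (the weak-pair pre-filter applied
#' before mutual ranking). Genes with constant expression have no defined
#' correlation; they are excluded and their count recorded in
#' `attr(, "n_constant_dropped")`.
#'
#' @param expr Expression tibble (`gene_id` + sample columns), normally
#'   already low-expression filtered.
#' @param min_abs_pcc Minimum absolute correlation retained, in \[0, 1\]
#'   (default 0.6).
#' @return Tibble `gene_a`, `gene_b` (pair sorted lexicographically), `pcc`.
#' @export
compute_pcc_pairs <- function(expr, min_abs_pcc = 0.6) {
  validate_expression(expr)
  abort_if(min_abs_pcc < 0 || min_abs_pcc > 1,
           "min_abs_pcc must lie in [0, 1]")
  m <- expr_as_matrix(expr)
  constant <- apply(m, 1, sd) == 0
  n_const <- sum(constant)
  if (n_const > 0) {
    message(n_const, " constant-expression gene(s) excluded from correlation")
    m <- m[!constant, , drop = FALSE]
  }
  cc <- cor(t(m))
  keep <- which(upper.tri(cc) & abs(cc) >= min_abs_pcc, arr.ind = TRUE)
  ids <- rownames(m)
  out <- tibble::tibble(
    gene_a = ids[keep[, 1]],
    gene_b = ids[keep[, 2]],
    pcc = cc[keep]
  )
  # canonical order inside the pair, then sort for reproducible diffs
  cp <- canonical_pairs(out$gene_a, out$gene_b)
  out$gene_a <- cp$gene_a
  out$gene_b <- cp$gene_b
  out <- dplyr::arrange(out, .data$gene_a, .data$gene_b)
  attr(out, "n_constant_dropped") <- n_const
  attr(out, "universe") <- ids
  out
}

#' Mutual ranks of correlated gene pairs
#'
#' For each gene, its retained partners are ranked 1, 2, ... separately within
#' the positive class (descending correlation) and the negative class
#' (ascending correlation, most negative first); ties are broken by partner
#' gene id, so ranking is deterministic. The mutual rank of a pair is the
#' geometric mean of its two directional ranks,
#' `MR(AB) = sqrt(rank(A->B) * rank(B->A))`; low MR means both genes place
#' each other near the top of their partner lists. An alternative mode ranks
#' all partners jointly by `|pcc|`.
#'
#' @param pairs Pair tibble from [compute_pcc_pairs()].
#' @param rank_mode `"signed"` (default: rank within sign class) or `"abs"`
#'   (single ranking by absolute correlation).
#' @return Tibble `gene_a`, `gene_b`, `pcc`, `rank_ab`, `rank_ba`, `mr`,
#'   `sign`, sorted by pair.
#' @export
compute_mutual_ranks <- function(pairs, rank_mode = c("signed", "abs")) {
  rank_mode <- match.arg(rank_mode)
  if (nrow(pairs) == 0) {
    return(tibble::tibble(gene_a = character(0), gene_b = character(0),
                          pcc = numeric(0), rank_ab = integer(0),
                          rank_ba = integer(0), mr = numeric(0),
                          sign = character(0)))
  }
  long <- dplyr::bind_rows(
    dplyr::transmute(pairs, from = .data$gene_a, to = .data$gene_b,
                     pcc = .data$pcc),
    dplyr::transmute(pairs, from = .data$gene_b, to = .data$gene_a,
                     pcc = .data$pcc)
  )
  if (rank_mode == "signed") {
    long <- long |>
      dplyr::mutate(cls = ifelse(.data$pcc < 0, "neg", "pos"),
                    key = ifelse(.data$pcc < 0, .data$pcc, -.data$pcc)) |>
      dplyr::group_by(.data$from, .data$cls)
  } else {
    long <- long |>
      dplyr::mutate(key = -abs(.data$pcc)) |>
      dplyr::group_by(.data$from)
  }
  long <- long |>
    dplyr::arrange(.data$key, .data$to, .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select("from", "to", "rank")

  out <- pairs |>
    dplyr::left_join(long, by = c(gene_a = "from", gene_b = "to")) |>
    dplyr::rename(rank_ab = "rank") |>
    dplyr::left_join(long, by = c(gene_b = "from", gene_a = "to")) |>
    dplyr::rename(rank_ba = "rank") |>
    dplyr::mutate(
      mr = sqrt(.data$rank_ab * .data$rank_ba),
      sign = ifelse(.data$pcc < 0, "negative", "positive")
    ) |>
    dplyr::arrange(.data$gene_a, .data$gene_b)
  attr(out, "universe") <- attr(pairs, "universe")
  out
}

#' Select coexpression-network edges by rank and mutual-rank cutoffs
#'
#' Under the default `union` rule a pair becomes an edge iff either
#' directional rank is within `rank_cutoff` or its mutual rank is within
#' `mr_cutoff`; `intersection` requires both. Cutoffs are inclusive by
#' default (`rank <= 3`, `MR <= 30`); `strict = TRUE` switches both to
#' strict inequality.
#'
#' @param ranked Ranked-pair tibble from [compute_mutual_ranks()].
#' @param rank_cutoff Unidirectional rank cutoff (default 3).
#' @param mr_cutoff Mutual-rank cutoff (default 30).
#' @param rule `"union"` (default) or `"intersection"`.
#' @param strict Use strict inequalities instead of `<=`.
#' @param genome_size Optional genome gene count for coverage statistics.
#' @return A `coex_network`: list with `edges` (the kept ranked pairs),
#'   `nodes` (sorted endpoint gene ids) and `genome_size`.
#' @export
select_edges <- function(ranked, rank_cutoff = 3, mr_cutoff = 30,
                         rule = c("union", "intersection"), strict = FALSE,
                         genome_size = NULL) {
  rule <- match.arg(rule)
  abort_if(rank_cutoff <= 0 || mr_cutoff <= 0, "cutoffs must be positive")
  cmp <- if (strict) `<` else `<=`
  rank_ok <- cmp(pmin(ranked$rank_ab, ranked$rank_ba), rank_cutoff)
  mr_ok <- cmp(ranked$mr, mr_cutoff)
  keep <- if (rule == "union") rank_ok | mr_ok else rank_ok & mr_ok
  edges <- dplyr::arrange(ranked[keep, , drop = FALSE],
                          .data$gene_a, .data$gene_b)
  out <- list(
    edges = edges,
    nodes = sort(unique(c(edges$gene_a, edges$gene_b))),
    genome_size = genome_size
  )
  class(out) <- "coex_network"
  out
}

#' @export
print.coex_network <- function(x, ...) {
  cat(sprintf("coexpression network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' @export
tidy.coex_network <- function(x, ...) x$edges

#' @export
glance.coex_network <- function(x, ...) {
  network_statistics(x, genome_size = x$genome_size)
}

# undirected simple igraph over the network's node set
network_as_igraph <- function(network, positive_only = FALSE) {
  edges <- network$edges
  if (positive_only) edges <- edges[edges$sign != "negative", , drop = FALSE]
  igraph::graph_from_data_frame(
    edges[, c("gene_a", "gene_b")],
    directed = FALSE,
    vertices = data.frame(name = network$nodes)
  )
}

#' Coexpression-network summary statistics
#'
#' Edge count, node count, mean edges per gene (`2E / N`) and genome coverage
#' (`100 * N / genome_size`). The `*_report` columns carry the reporting
#' convention: mean degree rounded half-up to one decimal, coverage to two.
#'
#' @param network A `coex_network`.
#' @param genome_size Genome gene count; defaults to the network's own.
#' @return One-row tibble of statistics.
#' @export
network_statistics <- function(network, genome_size = NULL) {
  genome_size <- genome_size %||% network$genome_size
  n_edges <- nrow(network$edges)
  n_nodes <- length(network$nodes)
  if (n_nodes == 0) {
    warning("empty network; statistics are zero")
    mean_deg <- 0
  } else {
    mean_deg <- 2 * n_edges / n_nodes
  }
  coverage <- if (!is.null(genome_size) && genome_size > 0) {
    abort_if(genome_size < n_nodes, "genome_size smaller than node count")
    100 * n_nodes / genome_size
  } else {
    NA_real_
  }
  tibble::tibble(
    edge_count = n_edges,
    node_count = n_nodes,
    mean_edges_per_gene = mean_deg,
    mean_edges_report = round_half_up(mean_deg, 1),
    coverage_pct = coverage,
    coverage_report = round_half_up(coverage, 2)
  )
}

#' Degree distribution of a coexpression network
#'
#' Histogram of node degrees, with a log-log least-squares slope as a
#' descriptive scale-free diagnostic (biological coexpression networks
#' typically show a small number of highly connected hubs).
#'
#' @param network A `coex_network`.
#' @return Tibble `degree`, `n_genes`; the fitted log-log slope (or `NA` with
#'   fewer than 3 distinct degrees) is in `attr(, "loglog_slope")`.
#' @export
degree_distribution <- function(network) {
  g <- network_as_igraph(network)
  deg <- igraph::degree(g)
  tab <- table(deg)
  out <- tibble::tibble(
    degree = as.integer(names(tab)),
    n_genes = as.integer(tab)
  )
  pos <- out$degree > 0
  slope <- if (sum(pos) >= 3) {
    unname(stats::coef(stats::lm(log10(n_genes) ~ log10(degree),
                                 data = out[pos, ]))[2])
  } else {
    NA_real_
  }
  attr(out, "loglog_slope") <- slope
  out
}

#' @describeIn degree_distribution Log-log degree distribution plot.
#' @param object A `coex_network`.
#' @param ... Ignored.
#' @export
autoplot.coex_network <- function(object, ...) {
  dd <- degree_distribution(object)
  ggplot2::ggplot(dd[dd$degree > 0, ],
                  ggplot2::aes(x = .data$degree, y = .data$n_genes)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "degree", y = "genes",
                  title = "Degree distribution") +
    ggplot2::theme_minimal()
}

#' ROC analysis of mutual-rank cutoffs against a labelled gold standard
#'
#' Sweeps the mutual-rank cutoff over all observed values and scores each
#' labelled pair as an edge iff its MR is at or below the cutoff; labelled
#' pairs absent from the ranked table never become edges (MR = infinity).
#' Reports one (FPR, TPR) point per cutoff and the trapezoidal AUC. The
#' intended gold standard on synthetic data labels same-block pairs positive
#' and cross-block pairs negative.
#'
#' @param ranked Ranked-pair tibble from [compute_mutual_ranks()].
#' @param positives,negatives Tibbles with `gene_a`, `gene_b` columns
#'   (unordered pairs); the two sets must be disjoint and non-empty.
#' @return A `coex_roc`: list with `points` (tibble `mr_cutoff`, `tpr`,
#'   `fpr`) and `auc`.
#' @export
evaluate_cutoffs_roc <- function(ranked, positives, negatives) {
  abort_if(nrow(positives) == 0 || nrow(negatives) == 0, "empty label set")
  key <- function(d) {
    cp <- canonical_pairs(d$gene_a, d$gene_b)
    paste(cp$gene_a, cp$gene_b)
  }
  kp <- unique(key(positives))
  kn <- unique(key(negatives))
  abort_if(length(intersect(kp, kn)) > 0, "label sets overlap")
  mr_of <- stats::setNames(ranked$mr, key(ranked))
  score_p <- unname(mr_of[kp]); score_p[is.na(score_p)] <- Inf
  score_n <- unname(mr_of[kn]); score_n[is.na(score_n)] <- Inf

  cuts <- sort(unique(c(score_p, score_n)))
  pts <- tibble::tibble(
    mr_cutoff = c(-Inf, cuts),
    tpr = vapply(c(-Inf, cuts), function(t) mean(score_p <= t), numeric(1)),
    fpr = vapply(c(-Inf, cuts), function(t) mean(score_n <= t), numeric(1))
  )
  o <- order(pts$fpr, pts$tpr)
  fpr <- pts$fpr[o]; tpr <- pts$tpr[o]
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  out <- list(points = pts, auc = auc)
  class(out) <- "coex_roc"
  out
}

#' @export
print.coex_roc <- function(x, ...) {
  cat(sprintf("mutual-rank ROC: AUC = %.4f over %d cutoffs\n",
              x$auc, nrow(x$points)))
  invisible(x)
}

#' @export
tidy.coex_roc <- function(x, ...) x$points

#' @export
glance.coex_roc <- function(x, ...) tibble::tibble(auc = x$auc)

#' @export
autoplot.coex_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_path() +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("MR cutoff ROC (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' Write a network edge list to TSV
#' @param network A `coex_network`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_edges_tsv <- function(network, path) {
  write_tsv_atomic(network$edges, path)
}

#' Read a network edge list from TSV
#' @param path Edge TSV written by [write_edges_tsv()].
#' @param genome_size Optional genome gene count.
#' @return A `coex_network`.
#' @export
read_edges_tsv <- function(path, genome_size = NULL) {
  edges <- readr::read_tsv(path, col_types = readr::cols(
    gene_a = readr::col_character(),
    gene_b = readr::col_character(),
    .default = readr::col_guess()
  ), progress = FALSE)
  out <- list(
    edges = edges,
    nodes = sort(unique(c(edges$gene_a, edges$gene_b))),
    genome_size = genome_size
  )
  class(out) <- "coex_network"
  out
}
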