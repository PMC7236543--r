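#' Enumerate all k-cliques of a coexpression network
#'
#' Complete enumeration of fully connected node sets of exactly `k` nodes.
#' Edge sign is ignored by default (the network is treated as a simple
#' undirected graph); `positive_only = TRUE` drops negative-correlation edges
#' first.
#'
#' @param network A `coex_network` (or an igraph graph).
#' @param k Clique size, at least 3.
#' @param positive_only Drop negative edges before enumeration.
#' @return List of character vectors, each a sorted k-node clique; the list is
#'   ordered lexicographically, so output is canonical.
#' @export
enumerate_k_cliques <- function(network, k, positive_only = FALSE) {
  abort_if(k < 3, "k must be at least 3")
  g <- if (inherits(network, "igraph")) network
       else network_as_igraph(network, positive_only = positive_only)
  cl <- igraph::cliques(g, min = k, max = k)
  out <- lapply(cl, function(v) sort(igraph::V(g)$name[v]))
  keys <- vapply(out, paste, character(1), collapse = "|")
  out[order(keys)]
}

#' Overlapping modules by k-clique percolation
#'
#' Classic clique percolation: two k-cliques are adjacent iff they share
#' exactly k-1 nodes, and a module is the union of the node sets of a
#' connected component of the clique-adjacency graph. The implementation
#' works at the level of maximal cliques, the standard acceleration: every
#' k-clique lies inside a maximal clique of size >= k, all k-cliques within
#' one maximal clique percolate into one community, and two maximal cliques
#' carry adjacent k-cliques iff they share at least k-1 nodes; modules are
#' therefore the node unions of components of the maximal-clique overlap
#' graph. The output contract is fixed by the direct definition (tests
#' compare against brute-force enumeration over all k-subsets). Modules may
#' overlap in genes, and every module has at least k members.
#'
#' @inheritParams enumerate_k_cliques
#' @return A `coex_modules` tibble: `module_id`, `k`, `size`, `clique_count`
#'   (maximal cliques of size >= k merged into the module), `genes` (list
#'   column of sorted gene ids). Module ids are assigned after sorting
#'   modules by size (descending) then member list, so they are
#'   deterministic under node relabelling.
#' @export
#' @examples
#' net <- list(edges = tibble::tibble(
#'   gene_a = c("a", "a", "b", "b", "c"),
#'   gene_b = c("b", "c", "c", "d", "d"), sign = "positive"),
#'   nodes = c("a", "b", "c", "d"), genome_size = NULL)
#' class(net) <- "coex_network"
#' clique_percolation(net, k = 3)
clique_percolation <- function(network, k, positive_only = FALSE) {
  abort_if(k < 3, "k must be at least 3")
  g <- if (inherits(network, "igraph")) network
       else network_as_igraph(network, positive_only = positive_only)
  maximal <- igraph::max_cliques(g, min = k)
  empty <- tibble::tibble(
    module_id = character(0), k = integer(0), size = integer(0),
    clique_count = integer(0), genes = list()
  )
  if (length(maximal) == 0) {
    class(empty) <- c("coex_modules", class(empty))
    attr(empty, "k") <- as.integer(k)
    return(empty)
  }
  maximal <- lapply(maximal, function(v) sort(igraph::V(g)$name[v]))

  # overlap >= k-1 between maximal cliques <=> their k-cliques percolate
  n_cl <- length(maximal)
  comp <- seq_len(n_cl)
  if (n_cl > 1) {
    pairs <- combn(n_cl, 2)
    ov <- vapply(seq_len(ncol(pairs)), function(j) {
      length(intersect(maximal[[pairs[1, j]]], maximal[[pairs[2, j]]]))
    }, integer(1))
    adj <- pairs[, ov >= k - 1, drop = FALSE]
    if (ncol(adj) > 0) {
      cg <- igraph::graph_from_edgelist(t(adj), directed = FALSE)
      cg <- igraph::add_vertices(cg, max(0, n_cl - igraph::vcount(cg)))
      comp <- igraph::components(cg)$membership[seq_len(n_cl)]
    }
  }

  members <- unname(split(seq_len(n_cl), comp))
  modules <- lapply(members, function(idx) {
    list(genes = sort(unique(unlist(maximal[idx]))),
         clique_count = length(idx))
  })
  sizes <- vapply(modules, function(m) length(m$genes), integer(1))
  keys <- vapply(modules, function(m) paste(m$genes, collapse = "|"),
                 character(1))
  modules <- modules[order(-sizes, keys)]

  out <- tibble::tibble(
    module_id = sprintf("M%04d", seq_along(modules)),
    k = as.integer(k),
    size = vapply(modules, function(m) length(m$genes), integer(1)),
    clique_count = vapply(modules, function(m) m$clique_count, integer(1)),
    genes = lapply(modules, function(m) m$genes)
  )
  class(out) <- c("coex_modules", class(out))
  attr(out, "k") <- as.integer(k)
  out
}

#' @export
glance.coex_modules <- function(x, ...) {
  tibble::tibble(
    n_modules = nrow(x),
    mean_size = if (nrow(x) > 0) mean(x$size) else 0,
    covered_genes = length(unique(unlist(x$genes)))
  )
}

#' @export
tidy.coex_modules <- function(x, ...) {
  tibble::tibble(
    module_id = rep(x$module_id, lengths(x$genes)),
    gene_id = unlist(x$genes)
  )
}

#' Scan clique sizes for module count and gene coverage
#'
#' Runs clique percolation for each k in `[k_min, k_max]` and tabulates the
#' module count and the fraction of network genes covered by at least one
#' module. Coverage never increases with k (a k-clique contains k smaller
#' cliques). The recommended k maximises coverage, with module count as the
#' tie-break — a lexicographic reading of "maximise gene coverage and module
#' number" — and is a recommendation only.
#'
#' @param network A `coex_network`.
#' @param k_min,k_max Clique-size range, `3 <= k_min <= k_max`.
#' @return Tibble `k`, `module_count`, `covered_genes`, `coverage_fraction`;
#'   the recommended k is in `attr(, "recommended_k")`.
#' @export
scan_k <- function(network, k_min = 3, k_max = 8) {
  abort_if(k_min < 3 || k_min > k_max, "need 3 <= k_min <= k_max")
  abort_if(length(network$nodes) == 0, "empty network")
  n_nodes <- length(network$nodes)
  rows <- lapply(seq(k_min, k_max), function(k) {
    mods <- clique_percolation(network, k)
    covered <- length(unique(unlist(mods$genes)))
    tibble::tibble(k = as.integer(k), module_count = nrow(mods),
                   covered_genes = covered,
                   coverage_fraction = covered / n_nodes)
  })
  out <- dplyr::bind_rows(rows)
  best <- order(-out$coverage_fraction, -out$module_count, out$k)[1]
  attr(out, "recommended_k") <- out$k[best]
  out
}

#' Write modules to TSV
#'
#' One row per module: `module_id`, `k`, `size`, `clique_count`, and the
#' comma-joined sorted member gene ids.
#' @param modules A `coex_modules` tibble.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_modules_tsv <- function(modules, path) {
  flat <- dplyr::mutate(
    tibble::as_tibble(modules[, c("module_id", "k", "size", "clique_count")]),
    genes = vapply(modules$genes, paste, character(1), collapse = ",")
  )
  write_tsv_atomic(flat, path)
}

#' Read modules from TSV
#' @param path Module TSV written by [write_modules_tsv()].
#' @return A `coex_modules` tibble.
#' @export
read_modules_tsv <- function(path) {
  flat <- readr::read_tsv(path, col_types = "ciiic", progress = FALSE)
  out <- dplyr::mutate(flat, genes = strsplit(.data$genes, ","))
  class(out) <- c("coex_modules", class(out))
  if (nrow(out) > 0) attr(out, "k") <- out$k[1]
  out
}
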