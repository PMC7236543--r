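# Independent brute-force oracles. These deliberately share no code with the
# package internals: plain double loops, exhaustive subset enumeration and
# closed-form combinatorics.

# all-pairs PCC + mutual ranks by explicit double loops over a numeric matrix
oracle_pcc_mr <- function(mat, min_abs_pcc) {
  ids <- rownames(mat)
  n <- nrow(mat)
  keep_a <- character(0); keep_b <- character(0); keep_p <- numeric(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      p <- suppressWarnings(cor(mat[i, ], mat[j, ]))
      if (!is.na(p) && abs(p) >= min_abs_pcc) {
        a <- ids[i]; b <- ids[j]
        if (a > b) { tmp <- a; a <- b; b <- tmp }
        keep_a <- c(keep_a, a); keep_b <- c(keep_b, b); keep_p <- c(keep_p, p)
      }
    }
  }
  pairs <- data.frame(gene_a = keep_a, gene_b = keep_b, pcc = keep_p,
                      stringsAsFactors = FALSE)
  if (nrow(pairs) == 0) return(pairs)
  rank_of <- function(from, to) {
    # partners of `from`, ranked within sign class: positive by descending
    # pcc, negative by ascending pcc, ties by partner id
    rows <- pairs[pairs$gene_a == from | pairs$gene_b == from, ]
    partner <- ifelse(rows$gene_a == from, rows$gene_b, rows$gene_a)
    p <- rows$pcc
    target_neg <- p[partner == to] < 0
    sel <- (p < 0) == target_neg
    partner <- partner[sel]; p <- p[sel]
    key <- if (target_neg) p else -p
    ord <- order(key, partner)
    match(to, partner[ord])
  }
  pairs$rank_ab <- mapply(rank_of, pairs$gene_a, pairs$gene_b)
  pairs$rank_ba <- mapply(rank_of, pairs$gene_b, pairs$gene_a)
  pairs$mr <- sqrt(pairs$rank_ab * pairs$rank_ba)
  pairs[order(pairs$gene_a, pairs$gene_b), ]
}

# exhaustive k-clique enumeration over all C(n, k) subsets
oracle_k_cliques <- function(adj, k) {
  ids <- rownames(adj)
  n <- nrow(adj)
  if (n < k) return(list())
  out <- list()
  subsets <- combn(n, k)
  for (ci in seq_len(ncol(subsets))) {
    s <- subsets[, ci]
    ok <- TRUE
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        if (!adj[s[i], s[j]]) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    if (ok) out[[length(out) + 1]] <- sort(ids[s])
  }
  out
}

# CPM communities from scratch: enumerate k-cliques, link cliques sharing
# exactly k-1 nodes, merge connected components by repeated sweeps
oracle_cpm <- function(adj, k) {
  cliques <- oracle_k_cliques(adj, k)
  nc <- length(cliques)
  if (nc == 0) return(list())
  comp <- seq_len(nc)
  repeat {
    changed <- FALSE
    for (i in seq_len(nc - 1)) {
      for (j in (i + 1):nc) {
        if (comp[i] != comp[j] &&
            length(intersect(cliques[[i]], cliques[[j]])) == k - 1) {
          comp[comp == comp[j]] <- comp[i]
          changed <- TRUE
        }
      }
    }
    if (!changed || nc == 1) break
  }
  mods <- lapply(split(seq_len(nc), comp), function(idx) {
    sort(unique(unlist(cliques[idx])))
  })
  unname(mods[order(vapply(mods, paste, character(1), collapse = "|"))])
}

# hypergeometric upper tail from binomial coefficients
oracle_hyper_tail <- function(q, term, bg, subject) {
  i <- q:min(term, subject)
  sum(choose(term, i) * choose(bg - term, subject - i)) / choose(bg, subject)
}

# IUPAC matcher by position-by-position character sets, both strands
oracle_scan <- function(sequence, motif) {
  codes <- list(A = "A", C = "C", G = "G", T = "T",
                R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                B = c("C", "G", "T"), D = c("A", "G", "T"),
                H = c("A", "C", "T"), V = c("A", "C", "G"),
                N = c("A", "C", "G", "T"))
  revcomp <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  count_one <- function(s) {
    sc <- strsplit(s, "")[[1]]
    mc <- strsplit(motif, "")[[1]]
    w <- length(mc)
    hits <- 0
    for (start in seq_len(length(sc) - w + 1)) {
      ok <- TRUE
      for (p in seq_len(w)) {
        if (!(sc[start + p - 1] %in% codes[[mc[p]]])) { ok <- FALSE; break }
      }
      if (ok) hits <- hits + 1
    }
    hits
  }
  count_one(sequence) + count_one(revcomp(sequence))
}

# random Erdos-Renyi coex_network with given node count and edge probability
random_network <- function(n, p, seed) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(n))
  adj <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      adj[i, j] <- adj[j, i] <- runif(1) < p
    }
  }
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  net <- list(
    edges = tibble::tibble(gene_a = ids[idx[, 1]], gene_b = ids[idx[, 2]],
                           sign = "positive"),
    nodes = ids,
    genome_size = NULL
  )
  class(net) <- "coex_network"
  list(network = net, adj = adj)
}

make_network <- function(gene_a, gene_b) {
  net <- list(
    edges = tibble::tibble(gene_a = gene_a, gene_b = gene_b,
                           sign = "positive"),
    nodes = sort(unique(c(gene_a, gene_b))),
    genome_size = NULL
  )
  class(net) <- "coex_network"
  net
}

# small planted-block simulation shared by several tests
small_sim <- function(seed = 9, n_genes = 300, n_blocks = 6, block_size = 15) {
  generate_expression(n_genes, 12, n_blocks = n_blocks,
                      block_size = block_size, rho = 0.95, seed = seed)
}

best_jaccard <- function(block, modules) {
  if (nrow(modules) == 0) return(0)
  max(vapply(modules$genes, function(g) {
    length(intersect(block, g)) / length(union(block, g))
  }, numeric(1)))
}
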