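test_that("pearson_correlation matches hand-evaluated cases and rejects degenerates", {
  expect_equal(pearson_correlation(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pearson_correlation(c(1, 2, 3), c(6, 4, 2)), -1)
  expect_equal(pearson_correlation(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_equal(pearson_correlation(c(1, 5, 2, 8), c(1, 5, 2, 8)), 1)
  expect_error(pearson_correlation(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson_correlation(c(1, 2), c(1, 2)), "3 samples")
  expect_error(pearson_correlation(1:3, 1:4), "equal length")
})

test_that("pair computation matches a double-loop oracle and handles edge cases", {
  sim <- generate_expression(50, 10, n_blocks = 3, block_size = 8, rho = 0.9,
                             frac_unexpressed = 0, seed = 21)
  m <- as.matrix(sim$expression[, -1]); rownames(m) <- sim$expression$gene_id

  pairs <- compute_pcc_pairs(sim$expression, min_abs_pcc = 0.6)
  ora <- oracle_pcc_mr(m, 0.6)
  expect_equal(paste(pairs$gene_a, pairs$gene_b),
               paste(ora$gene_a, ora$gene_b))
  expect_equal(pairs$pcc, ora$pcc)

  ranked <- compute_mutual_ranks(pairs)
  expect_equal(ranked$rank_ab, as.integer(ora$rank_ab))
  expect_equal(ranked$rank_ba, as.integer(ora$rank_ba))
  expect_equal(ranked$mr, ora$mr)
  expect_equal(ranked$mr, sqrt(ranked$rank_ab * ranked$rank_ba))
  expect_equal(ranked$sign == "negative", ranked$pcc < 0)

  # min_abs_pcc = 0 yields all n(n-1)/2 pairs of non-constant genes
  all_pairs <- compute_pcc_pairs(sim$expression, min_abs_pcc = 0)
  expect_equal(nrow(all_pairs), choose(50, 2))

  # a duplicated profile is the only pair at cutoff 1
  dup <- sim$expression[1:10, ]
  dup[10, -1] <- dup[1, -1]
  only <- compute_pcc_pairs(dup, min_abs_pcc = 1)
  expect_equal(nrow(only), 1)
  expect_setequal(c(only$gene_a, only$gene_b), dup$gene_id[c(1, 10)])

  # constant genes are dropped with a message, not an error
  const <- sim$expression[1:5, ]
  const[3, -1] <- as.list(rep(2, 10))
  expect_message(p <- compute_pcc_pairs(const, 0), "constant")
  expect_equal(attr(p, "n_constant_dropped"), 1L)
})

test_that("pair and rank computation are invariant under gene order permutation", {
  sim <- generate_expression(30, 8, n_blocks = 2, block_size = 8, rho = 0.9,
                             frac_unexpressed = 0, seed = 5)
  base <- compute_mutual_ranks(compute_pcc_pairs(sim$expression, 0.5))
  set.seed(1)
  perm <- sim$expression[sample(nrow(sim$expression)), ]
  shuf <- compute_mutual_ranks(compute_pcc_pairs(perm, 0.5))
  expect_equal(base[, c("gene_a", "gene_b", "rank_ab", "rank_ba", "mr")],
               shuf[, c("gene_a", "gene_b", "rank_ab", "rank_ba", "mr")],
               ignore_attr = TRUE)
})

test_that("edge selection implements the union/intersection rule semantics", {
  ranked <- tibble::tibble(
    gene_a = c("a", "c", "e"), gene_b = c("b", "d", "f"),
    pcc = c(0.9, 0.8, 0.7),
    rank_ab = c(2L, 10L, 50L), rank_ba = c(40L, 10L, 50L)
  )
  ranked$mr <- sqrt(ranked$rank_ab * ranked$rank_ba)
  ranked$sign <- "positive"

  uni <- select_edges(ranked, rank_cutoff = 3, mr_cutoff = 30, rule = "union")
  # rank 2 qualifies a-b; mr 10 qualifies c-d; e-f (mr 50) fails both
  expect_setequal(paste(uni$edges$gene_a, uni$edges$gene_b), c("a b", "c d"))

  int <- select_edges(ranked, rule = "intersection")
  expect_equal(paste(int$edges$gene_a, int$edges$gene_b), "a b")

  expect_error(select_edges(ranked, rank_cutoff = 0), "positive")

  # monotone: larger cutoffs never drop an edge
  sim <- small_sim(seed = 2, n_genes = 120, n_blocks = 3, block_size = 12)
  r <- compute_mutual_ranks(compute_pcc_pairs(sim$expression, 0.5))
  small <- select_edges(r, rank_cutoff = 2, mr_cutoff = 10)
  big <- select_edges(r, rank_cutoff = 5, mr_cutoff = 50)
  expect_true(all(paste(small$edges$gene_a, small$edges$gene_b) %in%
                    paste(big$edges$gene_a, big$edges$gene_b)))
})

test_that("network statistics follow the 2E/N and coverage conventions", {
  net <- make_network(gene_a = sprintf("g%d", 1:10),
                      gene_b = sprintf("g%d", c(2:10, 1)))
  st <- network_statistics(net)
  expect_equal(st$mean_edges_per_gene, 2) # 2 * 10 / 10
  st2 <- network_statistics(net, genome_size = 20)
  expect_equal(st2$coverage_pct, 50)
  expect_equal(st2$coverage_report, 50.00)

  empty <- make_network(character(0), character(0))
  expect_warning(st0 <- network_statistics(empty), "empty")
  expect_equal(st0$edge_count, 0)
})

test_that("degree distribution is an exact histogram with a log-log diagnostic", {
  tri <- make_network(c("a", "a", "b"), c("b", "c", "c"))
  dd <- degree_distribution(tri)
  expect_equal(dd, tibble::tibble(degree = 2L, n_genes = 3L),
               ignore_attr = TRUE)

  star <- make_network(rep("hub", 5), paste0("leaf", 1:5))
  ds <- degree_distribution(star)
  expect_equal(ds$n_genes[ds$degree == 5], 1L)
  expect_equal(ds$n_genes[ds$degree == 1], 5L)

  sim <- small_sim(seed = 31)
  net <- select_edges(compute_mutual_ranks(compute_pcc_pairs(sim$expression,
                                                             0.6)))
  dh <- degree_distribution(net)
  expect_equal(sum(dh$n_genes), length(net$nodes)) # conservation
})

test_that("ROC over mutual-rank cutoffs handles separation, ties and noise", {
  ranked <- tibble::tibble(
    gene_a = sprintf("p%d", 1:6), gene_b = sprintf("q%d", 1:6),
    pcc = 0.9, rank_ab = 1L, rank_ba = 1L,
    mr = c(1, 2, 3, 40, 50, 60), sign = "positive"
  )
  pos <- ranked[1:3, c("gene_a", "gene_b")]
  neg <- ranked[4:6, c("gene_a", "gene_b")]
  expect_equal(evaluate_cutoffs_roc(ranked, pos, neg)$auc, 1)

  tied <- dplyr::mutate(ranked, mr = 7)
  expect_equal(evaluate_cutoffs_roc(tied, pos, neg)$auc, 0.5)

  # pairs missing from the table are scored as non-edges, not errors
  far <- tibble::tibble(gene_a = "zz1", gene_b = "zz2")
  auc_abs <- evaluate_cutoffs_roc(ranked, pos, dplyr::bind_rows(neg, far))$auc
  expect_equal(auc_abs, 1)

  expect_error(evaluate_cutoffs_roc(ranked, pos[0, ], neg), "empty")
  expect_error(evaluate_cutoffs_roc(ranked, pos, pos), "overlap")

  # random labels hover near chance
  set.seed(8)
  big <- tibble::tibble(
    gene_a = sprintf("a%04d", 1:1000), gene_b = sprintf("b%04d", 1:1000),
    pcc = 0.9, rank_ab = 1L, rank_ba = 1L, mr = runif(1000, 1, 100),
    sign = "positive"
  )
  lab <- sample(c(TRUE, FALSE), 1000, replace = TRUE)
  auc <- evaluate_cutoffs_roc(big, big[lab, 1:2], big[!lab, 1:2])$auc
  expect_lt(abs(auc - 0.5), 0.05)
})

test_that("edge lists round-trip through TSV", {
  sim <- small_sim(seed = 3, n_genes = 80, n_blocks = 2, block_size = 10)
  net <- select_edges(compute_mutual_ranks(compute_pcc_pairs(sim$expression,
                                                             0.6)),
                      genome_size = 80)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edges_tsv(net, path)
  back <- read_edges_tsv(path, genome_size = 80)
  expect_equal(back$edges$gene_a, net$edges$gene_a)
  expect_equal(back$edges$mr, net$edges$mr)
  expect_equal(back$nodes, net$nodes)
})
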