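test_that("same seed reproduces every generated artifact exactly", {
  a <- generate_expression(80, 10, n_blocks = 3, block_size = 10, rho = 0.9,
                           seed = 11)
  b <- generate_expression(80, 10, n_blocks = 3, block_size = 10, rho = 0.9,
                           seed = 11)
  expect_identical(a, b)

  expect_identical(generate_genesets(a$truth, seed = 5),
                   generate_genesets(a$truth, seed = 5))

  ids <- sprintf("p%02d", 1:20)
  expect_identical(
    generate_promoters(ids, 200, "CACGTG", ids[1:5], 2, 0.2, seed = 3),
    generate_promoters(ids, 200, "CACGTG", ids[1:5], 2, 0.2, seed = 3)
  )
  expect_identical(generate_alignment_hits(30, 30, 20, 2, seed = 8),
                   generate_alignment_hits(30, 30, 20, 2, seed = 8))
})

test_that("expression values are finite, non-negative, and truth ids resolve", {
  sim <- generate_expression(100, 8, n_blocks = 4, block_size = 10,
                             rho = 0.8, seed = 2)
  m <- as.matrix(sim$expression[, -1])
  expect_true(all(is.finite(m)))
  expect_true(all(m >= 0))
  blocks <- sim$truth$planted_blocks
  expect_length(unique(unlist(blocks)), sum(lengths(blocks))) # disjoint
  expect_true(all(unlist(blocks) %in% sim$expression$gene_id))
  expect_true(all(sim$truth$unexpressed_genes %in% sim$expression$gene_id))
})

test_that("rho = 1 with zero noise gives perfectly correlated blocks", {
  sim <- generate_expression(40, 6, n_blocks = 2, block_size = 8, rho = 1,
                             noise_sd = 0, frac_unexpressed = 0, seed = 4)
  m <- as.matrix(sim$expression[, -1]); rownames(m) <- sim$expression$gene_id
  for (b in sim$truth$planted_blocks) {
    cc <- cor(t(m[b, ]))
    expect_equal(unname(cc), matrix(1, length(b), length(b)), tolerance = 1e-12)
  }
})

test_that("rho = 0 leaves within-block correlation at the off-block level", {
  sim <- generate_expression(200, 50, n_blocks = 4, block_size = 15, rho = 0,
                             frac_unexpressed = 0, seed = 6)
  m <- as.matrix(sim$expression[, -1]); rownames(m) <- sim$expression$gene_id
  cc <- cor(t(m))
  bid <- rep(0L, nrow(m))
  for (i in seq_along(sim$truth$planted_blocks)) {
    bid[match(sim$truth$planted_blocks[[i]], rownames(m))] <- i
  }
  ut <- upper.tri(cc)
  same <- outer(bid, bid, "==") & outer(bid, bid, "*") > 0 & ut
  diff <- (!outer(bid, bid, "==")) & ut
  expect_lt(abs(mean(abs(cc[same])) - mean(abs(cc[diff]))), 0.05)
})

test_that("planted blocks separate cleanly from the off-block background", {
  sim <- generate_expression(500, 12, n_blocks = 10, block_size = 20,
                             rho = 0.95, seed = 7)
  m <- as.matrix(sim$expression[, -1]); rownames(m) <- sim$expression$gene_id
  keep <- setdiff(rownames(m), sim$truth$unexpressed_genes)
  cc <- cor(t(m[keep, ]))
  bid <- rep(0L, length(keep))
  for (i in seq_along(sim$truth$planted_blocks)) {
    bid[match(sim$truth$planted_blocks[[i]], keep)] <- i
  }
  ut <- upper.tri(cc)
  within <- outer(bid, bid, "==") & outer(bid, bid, "*") > 0 & ut
  off <- (!outer(bid, bid, "==")) & ut
  expect_gt(mean(cc[within]), quantile(cc[off], 0.99))
})

test_that("aligned gene-set terms track planted blocks under jitter", {
  sim <- generate_expression(120, 10, n_blocks = 4, block_size = 20,
                             rho = 0.9, seed = 3)
  sets0 <- generate_genesets(sim$truth, n_noise_terms = 0, jitter = 0,
                             seed = 1)
  expect_equal(nrow(sets0), 4)
  for (i in 1:4) {
    expect_setequal(sets0$genes[[i]],
                    sim$truth$planted_blocks[[sub("term_", "", sets0$term[i])]])
  }
  sets <- generate_genesets(sim$truth, n_noise_terms = 3, jitter = 0.2,
                            seed = 1)
  expect_equal(nrow(sets), 7)
  for (i in 1:4) {
    block <- sim$truth$planted_blocks[[sub("term_", "", sets$term[i])]]
    expect_length(intersect(sets$genes[[i]], block), 16) # 20 - 0.2 * 20
  }
  expect_error(generate_genesets(sim$truth, jitter = 1), "jitter")
})

test_that("promoter insertions are recorded, non-overlapping and findable", {
  ids <- sprintf("p%03d", 1:40)
  pr <- generate_promoters(ids, 300, "CAACGG", target_genes = ids[1:10],
                           planted_rate = 3, background_rate = 0.2, seed = 5)
  expect_true(all(nchar(pr$sequences) == 300))
  expect_true(all(strsplit(paste(pr$sequences, collapse = ""), "")[[1]] %in%
                    c("A", "C", "G", "T")))
  led <- pr$truth$insertions
  # ledger positions never overlap within a promoter
  by_gene <- split(led$position, led$gene_id)
  for (pos in by_gene) expect_true(all(diff(sort(pos)) >= nchar("CAACGG")))
  # every recorded insertion is found by the scanner
  for (g in unique(led$gene_id)) {
    expect_gte(scan_promoter(pr$sequences[[g]], "CAACGG"),
               length(by_gene[[g]]))
  }
  expect_error(generate_promoters(ids, 4, "CAACGG", seed = 1), "longer")
})

test_that("alignment-hit tables follow the 12-column contract with true hits best", {
  h <- generate_alignment_hits(40, 40, 25, decoy_hits_per_query = 4, seed = 6)
  expect_named(h$hits_ab, c("qseqid", "sseqid", "pident", "length", "mismatch",
                            "gapopen", "qstart", "qend", "sstart", "send",
                            "evalue", "bitscore"))
  map <- h$truth$ortholog_map
  for (i in seq_len(nrow(map))) {
    mine <- h$hits_ab[h$hits_ab$qseqid == map$gene_a[i], ]
    expect_equal(mine$sseqid[which.min(mine$evalue)], map$gene_b[i])
  }
  # no-ortholog and no-decoy degenerate cases
  h0 <- generate_alignment_hits(10, 10, 0, 2, seed = 1)
  expect_equal(nrow(h0$truth$ortholog_map), 0)
  h1 <- generate_alignment_hits(10, 10, 5, 0, seed = 1)
  expect_equal(nrow(h1$hits_ab), 5)
  expect_error(generate_alignment_hits(5, 5, 9, 1, seed = 1), "exceeds")
})
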