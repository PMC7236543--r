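test_that("fisher_enrichment equals the closed-form hypergeometric tail", {
  bg <- paste0("g", 1:20)
  full <- fisher_enrichment(bg[1:5], bg[1:5], bg)
  expect_equal(full$p_value, 1 / choose(20, 5)) # only one way to draw all 5

  expect_equal(fisher_enrichment(bg[1:5], bg[6:10], bg)$p_value, 1) # overlap 0
  expect_equal(fisher_enrichment(bg, bg[1:4], bg)$p_value, 1) # subject = bg

  expect_error(fisher_enrichment(c("zz"), bg[1:2], bg), "outside background")

  # exhaustive sweep against the choose()-ratio oracle
  for (bg_n in c(5, 8, 11)) {
    u <- paste0("u", seq_len(bg_n))
    for (m in 1:(bg_n - 1)) {
      for (k in 1:(bg_n - 1)) {
        for (q in 0:min(m, k)) {
          if (q < max(0, m + k - bg_n)) next
          subject <- c(u[seq_len(q)],
                       u[setdiff(seq_len(bg_n), seq_len(m))][seq_len(k - q)])
          got <- fisher_enrichment(subject, u[seq_len(m)], u)
          expect_equal(got$overlap, q)
          expect_equal(got$p_value, oracle_hyper_tail(q, m, bg_n, k),
                       tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("BH adjustment reproduces the step-up arithmetic and preserves order", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))

  p <- c(0.04, 0.001, 0.3, 0.02)
  adj <- bh_fdr(p)
  perm <- c(3, 1, 4, 2)
  expect_equal(bh_fdr(p[perm]), adj[perm])
  expect_true(all(adj >= p))

  expect_equal(bh_fdr(c(0.01, 0.04), method = "bonferroni"), c(0.02, 0.08))
  expect_error(bh_fdr(c(0.5, 0)), "0, 1")
  expect_error(bh_fdr(1.5), "0, 1")
})

test_that("gene-set collections round-trip through GMT", {
  sim <- generate_expression(100, 8, n_blocks = 3, block_size = 10, rho = 0.9,
                             seed = 12)
  sets <- generate_genesets(sim$truth, n_noise_terms = 4, jitter = 0.1,
                            seed = 2)
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  back <- read_gmt(path, background = sim$truth$gene_ids)
  expect_equal(back$term, sets$term)
  expect_equal(back$namespace, sets$namespace)
  expect_equal(back$genes, sets$genes)
  expect_equal(attr(back, "background"), sim$truth$gene_ids)

  bad <- withr::local_tempfile(fileext = ".gmt")
  writeLines("lonely_term\tdesc", bad)
  expect_error(read_gmt(bad), "malformed")
})

test_that("module annotation flags aligned terms and controls the FDR flag", {
  sim <- generate_expression(200, 10, n_blocks = 4, block_size = 15,
                             rho = 0.95, seed = 23)
  sets <- generate_genesets(sim$truth, n_noise_terms = 6, jitter = 0, seed = 3)
  # modules identical to the planted blocks
  mods <- tibble::tibble(
    module_id = sprintf("M%02d", 1:4), k = 5L,
    size = lengths(sim$truth$planted_blocks),
    clique_count = 1L,
    genes = unname(sim$truth$planted_blocks)
  )
  class(mods) <- c("coex_modules", class(mods))
  ann <- annotate_modules(mods, sets, background = sim$truth$gene_ids)
  expect_true(all(ann$fdr >= ann$p_value))
  expect_true(all(ann$overlap <= pmin(ann$subject_size, ann$term_size)))
  top <- ann |> dplyr::group_by(subject) |> dplyr::slice_min(fdr, n = 1)
  expect_setequal(top$term, paste0("term_block0", 1:4))
  expect_true(all(top$significant))

  # a module with genes in no term yields nothing significant
  outside <- setdiff(sim$truth$gene_ids,
                     unique(unlist(c(sets$genes,
                                     sim$truth$planted_blocks))))[1:8]
  lonely <- mods[1, ]
  lonely$genes <- list(outside)
  ann2 <- annotate_modules(lonely, sets, background = sim$truth$gene_ids)
  expect_false(any(ann2$significant))
})

test_that("refinement inherits module terms and appends neighbor-derived ones", {
  sim <- small_sim(seed = 29)
  filt <- filter_low_expression(sim$expression,
                                compute_fpkm_threshold(sim$expression))
  net <- select_edges(compute_mutual_ranks(compute_pcc_pairs(filt, 0.6)))
  mods <- clique_percolation(net, 5)
  sets <- generate_genesets(sim$truth, n_noise_terms = 5, jitter = 0, seed = 7)
  ann <- annotate_modules(mods, sets, background = filt$gene_id)
  ref <- refine_gene_annotations(net, mods, ann, sets,
                                 background = filt$gene_id)
  expect_setequal(unique(ref$provenance), c("module", "neighbor"))

  # step 1: every gene of an annotated module carries the module's terms
  sig <- ann[ann$significant, ]
  m1 <- sig$subject[1]
  t1 <- sig$term[sig$subject == m1]
  for (g in mods$genes[[match(m1, mods$module_id)]]) {
    expect_true(all(t1 %in% ref$term[ref$gene_id == g]))
  }

  # block genes overwhelmingly receive their own block's term
  hit <- vapply(seq_along(sim$truth$planted_blocks), function(i) {
    b <- sim$truth$planted_blocks[[i]]
    term <- paste0("term_", names(sim$truth$planted_blocks)[i])
    mean(b %in% ref$gene_id[ref$term == term])
  }, numeric(1))
  expect_gte(mean(hit), 0.9)

  # genes outside the network receive nothing
  expect_length(setdiff(unique(ref$gene_id), net$nodes), 0)
})

test_that("enrichment is calibrated under a random null", {
  set.seed(77)
  universe <- paste0("g", 1:400)
  rand_mods <- tibble::tibble(
    module_id = sprintf("R%02d", 1:20), k = 5L, size = 20L, clique_count = 1L,
    genes = replicate(20, sample(universe, 20), simplify = FALSE)
  )
  class(rand_mods) <- c("coex_modules", class(rand_mods))
  rand_sets <- tibble::tibble(
    term = sprintf("T%02d", 1:20), namespace = "GO",
    genes = replicate(20, sample(universe, 20), simplify = FALSE)
  )
  attr(rand_sets, "background") <- universe
  ann <- annotate_modules(rand_mods, rand_sets, background = universe)
  expect_lte(mean(ann$significant), 0.05 + 0.03)
})

test_that("randomization Z flags the aligned term and respects the cutoff", {
  sim <- generate_expression(150, 10, n_blocks = 2, block_size = 20,
                             rho = 0.95, seed = 41)
  sets <- generate_genesets(sim$truth, n_noise_terms = 2, jitter = 0, seed = 4)
  mods <- tibble::tibble(
    module_id = c("M1", "M2"), k = 5L, size = 20L, clique_count = 1L,
    genes = unname(sim$truth$planted_blocks)
  )
  class(mods) <- c("coex_modules", class(mods))
  ann <- annotate_modules(mods, sets, background = sim$truth$gene_ids)
  flagged <- term_zscore_flag(ann, mods, sets, z_cutoff = 4, n_draws = 300,
                              background = sim$truth$gene_ids, seed = 6)
  aligned <- flagged$term == paste0("term_block0", 1:2 )[match(flagged$subject, c("M1", "M2"))]
  expect_true(all(flagged$z_flag[aligned & flagged$subject == "M1" &
                                   flagged$term == "term_block01"]))
  none <- term_zscore_flag(ann, mods, sets, z_cutoff = Inf, n_draws = 100,
                           background = sim$truth$gene_ids, seed = 6)
  expect_false(any(none$z_flag))
  # determinism under a fixed seed
  again <- term_zscore_flag(ann, mods, sets, z_cutoff = 4, n_draws = 300,
                            background = sim$truth$gene_ids, seed = 6)
  expect_identical(flagged$z, again$z)
})
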