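#' Generate a synthetic FPKM expression matrix with planted co-regulated blocks
#'
#' Builds a genes-by-samples FPKM-like table from a latent-factor block model:
#' every gene in a planted block mixes a shared latent sample profile with
#' independent Gaussian noise, and the latent values are mapped through an
#' exponential so marginals are non-negative and heavy-tailed, as real FPKM
#' distributions are. Genes outside blocks are mutually independent, and a
#' configurable fraction of the off-block genes is "unexpressed": uniformly
#' near zero in every sample, so low-expression filtering has a real target.
#'
#' With `noise_sd = 1` the latent correlation of two same-block genes is
#' exactly `rho`; the exponential map is monotone, so realized sample Pearson
#' correlations increase monotonically with `rho` (and equal 1 when
#' `rho = 1, noise_sd = 0`).
#'
#' @param n_genes Total number of genes.
#' @param n_samples Number of samples (at least 3, so correlations are defined).
#' @param n_blocks Number of planted co-regulated blocks.
#' @param block_size Genes per block (`n_blocks * block_size <= n_genes`).
#' @param rho Latent within-block correlation, in \[0, 1\].
#' @param noise_sd Standard deviation of the per-gene latent noise.
#' @param log_scale Multiplier on the latent value before exponentiation;
#'   sets the lognormal spread (dynamic range) of the FPKM marginals. The
#'   default 0.25 keeps the monotone map from `rho` to realized Pearson
#'   correlation close to the identity; large values make extreme samples
#'   dominate product-moment correlations and blur planted structure.
#' @param frac_unexpressed Fraction of genes planted as unexpressed
#'   (drawn from the off-block genes; capped at their count).
#' @param noise_structure How off-block latent vectors relate to the block
#'   profiles. `"flattened"` (default) is the identifiability guarantee: each
#'   off-block gene's sample correlation with every block profile is set to
#'   exactly the null scale `1/sqrt(n_samples - 1)` with an independent random
#'   sign, and the remainder of the vector lies in the orthogonal complement.
#'   This preserves the natural spread of null correlations (the flattened
#'   coordinates have the same standard deviation an i.i.d. draw would) while
#'   removing the upper tail, so the recorded ground truth ("off-block genes
#'   do not co-express with any block") holds in the generated sample itself
#'   and not only in expectation -- at a dozen samples, i.i.d. noise vectors
#'   routinely show chance correlations above typical edge cutoffs. `"iid"`
#'   draws plain independent Gaussian noise; it is also the fallback whenever
#'   `n_blocks >= n_samples - 1` leaves no orthogonal complement to use.
#' @param unexpressed_ceiling Upper bound of the uniform near-zero FPKM given
#'   to unexpressed genes.
#' @param seed Integer seed; the same seed reproduces the output byte-for-byte.
#'
#' @return A list of class `synth_expression` with elements
#'   `expression` (tibble: `gene_id` + one numeric column per sample) and
#'   `truth` (list: `planted_blocks`, `unexpressed_genes`, `gene_ids`, `seed`).
#' @export
#' @examples
#' sim <- generate_expression(60, 12, n_blocks = 2, block_size = 10,
#'                            rho = 0.9, seed = 1)
#' dim(sim$expression)
generate_expression <- function(n_genes, n_samples, n_blocks, block_size,
                                rho, noise_sd = 1, log_scale = 0.25,
                                frac_unexpressed = 0.04,
                                noise_structure = c("flattened", "iid"),
                                unexpressed_ceiling = 0.05, seed = 1) {
  noise_structure <- match.arg(noise_structure)
  abort_if(n_genes < 1 || n_samples < 3 || n_blocks < 0 || block_size < 1,
           "non-positive dimensions (and n_samples must be >= 3)")
  abort_if(rho < 0 || rho > 1, "rho must lie in [0, 1]")
  abort_if(noise_sd < 0, "noise_sd must be non-negative")
  abort_if(n_blocks * block_size > n_genes,
           "n_blocks * block_size exceeds n_genes")

  gene_ids <- sprintf("g%05d", seq_len(n_genes))
  sample_ids <- sprintf("s%02d", seq_len(n_samples))

  with_seed(seed, {
    n_block_genes <- n_blocks * block_size
    block_of <- rep(NA_integer_, n_genes)
    if (n_blocks > 0) {
      block_of[seq_len(n_block_genes)] <- rep(seq_len(n_blocks),
                                              each = block_size)
    }

    off_block <- which(is.na(block_of))
    n_unexpr <- min(length(off_block), round(frac_unexpressed * n_genes))
    unexpr <- if (n_unexpr > 0) sample(off_block, n_unexpr) else integer(0)

    # Block profiles are decorrelated by construction (centered, then
    # orthogonalized) so distinct blocks cannot collide through chance
    # correlation at small sample counts; with n_blocks >= n_samples
    # orthogonalization is impossible and i.i.d. profiles are used.
    latent_profiles <- matrix(rnorm(n_blocks * n_samples),
                              nrow = n_blocks, ncol = n_samples)
    if (n_blocks > 1 && n_blocks < n_samples) {
      m <- scale(t(latent_profiles), center = TRUE, scale = FALSE)
      q <- qr.Q(qr(m))[, seq_len(n_blocks), drop = FALSE]
      latent_profiles <- t(q) * sqrt(n_samples - 1)
    }
    baseline <- rnorm(n_genes, mean = log(10), sd = 0.5)

    vals <- matrix(0, nrow = n_genes, ncol = n_samples,
                   dimnames = list(gene_ids, sample_ids))
    for (g in seq_len(n_genes)) {
      if (g %in% unexpr) {
        vals[g, ] <- runif(n_samples, 0, unexpressed_ceiling)
      } else if (!is.na(block_of[g])) {
        z <- sqrt(rho) * latent_profiles[block_of[g], ] +
          sqrt(1 - rho) * noise_sd * rnorm(n_samples)
        vals[g, ] <- exp(baseline[g] + log_scale * z)
      } else {
        e <- if (noise_structure == "flattened" && n_blocks > 0 &&
                 n_blocks < n_samples - 1) {
          flattened_noise(latent_profiles, n_samples)
        } else {
          rnorm(n_samples)
        }
        vals[g, ] <- exp(baseline[g] + log_scale * noise_sd * e)
      }
    }

    blocks <- if (n_blocks > 0) {
      stats::setNames(
        lapply(seq_len(n_blocks), function(b) gene_ids[which(block_of == b)]),
        sprintf("block%02d", seq_len(n_blocks))
      )
    } else {
      list()
    }

    out <- list(
      expression = expr_from_matrix(vals),
      truth = list(
        planted_blocks = blocks,
        unexpressed_genes = gene_ids[sort(unexpr)],
        gene_ids = gene_ids,
        seed = as.integer(seed)
      )
    )
    class(out) <- "synth_expression"
    out
  })
}

#' Generate gene-set terms aligned to planted blocks
#'
#' Emits one term per planted block, with a `jitter` fraction of its members
#' swapped for random genes outside the block, plus `n_noise_terms` terms of
#' random genes. The result is GMT-serializable via [write_gmt()].
#'
#' @param truth Truth component of a [generate_expression()] result.
#' @param n_noise_terms Number of random (unaligned) terms to add.
#' @param jitter Fraction of each aligned term's members to swap out, in \[0, 1).
#' @param noise_term_size Size of each noise term.
#' @param seed Integer seed.
#'
#' @return A gene-set collection tibble (class `gene_sets`): columns `term`,
#'   `namespace`, `genes` (list column), with the gene universe in
#'   `attr(, "background")`.
#' @export
generate_genesets <- function(truth, n_noise_terms = 10, jitter = 0,
                              noise_term_size = 15, seed = 1) {
  abort_if(jitter < 0 || jitter >= 1, "jitter must lie in [0, 1)")
  universe <- truth$gene_ids
  blocks <- truth$planted_blocks

  with_seed(seed, {
    aligned <- purrr::imap(blocks, function(genes, nm) {
      n_swap <- round(jitter * length(genes))
      if (n_swap > 0) {
        drop <- sample(genes, n_swap)
        pool <- setdiff(universe, genes)
        genes <- c(setdiff(genes, drop), sample(pool, n_swap))
      }
      sort(genes)
    })
    names(aligned) <- paste0("term_", names(blocks))

    noise <- list()
    if (n_noise_terms > 0) {
      noise <- lapply(seq_len(n_noise_terms), function(i) {
        sort(sample(universe, min(noise_term_size, length(universe))))
      })
      names(noise) <- sprintf("noise%03d", seq_len(n_noise_terms))
    }

    sets <- c(aligned, noise)
    out <- tibble::tibble(
      term = names(sets),
      namespace = "GO",
      genes = unname(sets)
    )
    attr(out, "background") <- universe
    class(out) <- c("gene_sets", class(out))
    out
  })
}

# Draw one off-block latent vector with "flattened" block correlations:
# correlation with each (centered, orthonormalized) block profile is exactly
# +/- 1/sqrt(n_samples - 1) with a random sign, and the remaining direction
# is uniform in the orthogonal complement of the profiles and the intercept.
# 1/sqrt(n - 1) is the standard deviation of a null sample correlation, so
# the flattened coordinates reproduce the typical null association while
# removing the tail that would fake co-expression at small sample counts.
flattened_noise <- function(profiles, n_samples) {
  n_blocks <- nrow(profiles)
  ph <- scale(t(profiles), center = TRUE, scale = FALSE)
  u <- qr.Q(qr(ph))[, seq_len(n_blocks), drop = FALSE]
  tau <- 1 / sqrt(n_samples - 1)
  c_blocks <- sample(c(-tau, tau), n_blocks, replace = TRUE)
  # residual direction: centered, orthogonal to every profile
  r <- rnorm(n_samples)
  r <- r - mean(r)
  r <- r - u %*% crossprod(u, r)
  r <- r / sqrt(sum(r^2))
  c_res <- sqrt(max(1 - sum(c_blocks^2), 0))
  drop(sqrt(n_samples - 1) * (u %*% c_blocks + c_res * r))
}

# Instantiate an IUPAC consensus into one concrete ACGT word.
instantiate_motif <- function(motif) {
  codes <- iupac_code_list()
  chars <- strsplit(toupper(motif), "")[[1]]
  abort_if(!all(chars %in% names(codes)),
           paste0("invalid IUPAC character in motif: ", motif))
  paste0(vapply(chars, function(ch) sample(codes[[ch]], 1), character(1)),
         collapse = "")
}

#' Generate promoter sequences with a motif planted in a target gene list
#'
#' Produces uniform-random ACGT promoters of a fixed length, then inserts
#' concrete instantiations of an IUPAC consensus motif: `Poisson(planted_rate)`
#' copies per target-gene promoter and `Poisson(background_rate)` copies per
#' other promoter. Insertions never overlap one another and never cross
#' sequence ends; every insertion position is recorded in the truth ledger.
#'
#' @param gene_ids Character vector of promoter gene ids.
#' @param length Promoter length in bp (default 3000, i.e. a 3-kb region).
#' @param motif IUPAC consensus string to plant.
#' @param target_genes Genes receiving the elevated insertion rate.
#' @param planted_rate,background_rate Mean insertions per promoter.
#' @param seed Integer seed.
#'
#' @return A list of class `promoter_set`: `sequences` (named character),
#'   `nominal_length`, and `truth` (motif, target genes, insertion ledger
#'   tibble, seed).
#' @export
generate_promoters <- function(gene_ids, length = 3000, motif,
                               target_genes = character(0),
                               planted_rate = 3, background_rate = 0.3,
                               seed = 1) {
  abort_if(length < nchar(motif), "motif longer than promoter")
  abort_if(planted_rate < 0 || background_rate < 0, "rates must be >= 0")
  abort_if(!all(target_genes %in% gene_ids),
           "target_genes must be a subset of gene_ids")
  w <- nchar(motif)

  with_seed(seed, {
    seqs <- vapply(gene_ids, function(g) {
      paste0(sample(c("A", "C", "G", "T"), length, replace = TRUE),
             collapse = "")
    }, character(1))

    ledger <- list()
    for (g in gene_ids) {
      rate <- if (g %in% target_genes) planted_rate else background_rate
      n_ins <- rpois(1, rate)
      if (n_ins == 0) next
      taken <- integer(0) # occupied start positions
      s <- seqs[[g]]
      placed <- integer(0)
      for (i in seq_len(n_ins)) {
        # rejection-sample a non-overlapping start; cap attempts for safety
        for (try in 1:200) {
          pos <- sample.int(length - w + 1, 1)
          if (!any(abs(pos - taken) < w)) break
          pos <- NA_integer_
        }
        if (is.na(pos)) next
        inst <- instantiate_motif(motif)
        substr(s, pos, pos + w - 1) <- inst
        taken <- c(taken, pos)
        placed <- c(placed, pos)
      }
      seqs[[g]] <- s
      if (length(placed) > 0) {
        ledger[[g]] <- tibble::tibble(gene_id = g, position = sort(placed))
      }
    }

    insertions <- if (length(ledger) > 0) {
      dplyr::bind_rows(ledger)
    } else {
      tibble::tibble(gene_id = character(0), position = integer(0))
    }

    out <- list(
      sequences = seqs,
      nominal_length = length,
      truth = list(
        motif = motif,
        motif_target_genes = target_genes,
        insertions = insertions,
        seed = as.integer(seed)
      )
    )
    class(out) <- "promoter_set"
    out
  })
}

#' Generate reciprocal alignment-hit tables with a known ortholog map
#'
#' Simulates two proteomes and their pairwise alignment results in 12-column
#' tabular format. Each true ortholog pair receives reciprocal hits whose
#' E-values are the best (lowest) for both queries; decoy hits occupy a
#' strictly worse E-value band. Decoy subjects are drawn from ortholog-paired
#' genes only, so no spurious pair can be mutually best.
#'
#' @param n_a,n_b Number of genes in species A and B.
#' @param n_orthologs Number of true ortholog pairs
#'   (`<= min(n_a, n_b)`).
#' @param decoy_hits_per_query Decoy hits added per query gene.
#' @param seed Integer seed.
#'
#' @return A list of class `synth_hits`: `hits_ab`, `hits_ba` (12-column
#'   tibbles) and `truth` (tibble `ortholog_map` with `gene_a`, `gene_b`;
#'   `seed`).
#' @export
generate_alignment_hits <- function(n_a, n_b, n_orthologs,
                                    decoy_hits_per_query = 5, seed = 1) {
  abort_if(n_a < 0 || n_b < 0 || n_orthologs < 0 || decoy_hits_per_query < 0,
           "negative counts")
  abort_if(n_orthologs > min(n_a, n_b),
           "n_orthologs exceeds min(n_a, n_b)")

  ids_a <- sprintf("spA_g%04d", seq_len(n_a))
  ids_b <- sprintf("spB_g%04d", seq_len(n_b))

  with_seed(seed, {
    paired_a <- if (n_orthologs > 0) sample(ids_a, n_orthologs) else character(0)
    paired_b <- if (n_orthologs > 0) sample(ids_b, n_orthologs) else character(0)
    ortho <- tibble::tibble(gene_a = paired_a, gene_b = paired_b)

    hit_row <- function(q, s, evalue) {
      len <- sample(150:500, length(q), replace = TRUE)
      tibble::tibble(
        qseqid = q, sseqid = s,
        pident = round(runif(length(q), 40, 99), 1),
        length = len,
        mismatch = sample(0:80, length(q), replace = TRUE),
        gapopen = sample(0:5, length(q), replace = TRUE),
        qstart = 1L, qend = len, sstart = 1L, send = len,
        evalue = evalue,
        bitscore = round(-log10(pmax(evalue, 1e-180)) * 2 +
                           runif(length(q), 0, 5), 1)
      )
    }

    # strictly separated E-value bands: true hits are always better
    true_e <- function(n) 10^-runif(n, 50, 150)
    decoy_e <- function(n) 10^-runif(n, 5, 20)

    true_ab <- hit_row(ortho$gene_a, ortho$gene_b, true_e(n_orthologs))
    true_ba <- hit_row(ortho$gene_b, ortho$gene_a, true_e(n_orthologs))

    decoys_for <- function(queries, subject_pool, partner_of) {
      if (decoy_hits_per_query == 0 || length(queries) == 0 ||
          length(subject_pool) == 0) {
        return(NULL)
      }
      rows <- lapply(queries, function(q) {
        pool <- setdiff(subject_pool, partner_of[[q]] %||% character(0))
        if (length(pool) == 0) return(NULL)
        subj <- sample(pool, min(decoy_hits_per_query, length(pool)))
        hit_row(rep(q, length(subj)), subj, decoy_e(length(subj)))
      })
      dplyr::bind_rows(rows)
    }

    partner_ab <- stats::setNames(as.list(ortho$gene_b), ortho$gene_a)
    partner_ba <- stats::setNames(as.list(ortho$gene_a), ortho$gene_b)

    hits_ab <- dplyr::bind_rows(true_ab,
                                decoys_for(ids_a, paired_b, partner_ab)) |>
      dplyr::arrange(.data$qseqid, .data$evalue)
    hits_ba <- dplyr::bind_rows(true_ba,
                                decoys_for(ids_b, paired_a, partner_ba)) |>
      dplyr::arrange(.data$qseqid, .data$evalue)

    out <- list(
      hits_ab = hits_ab,
      hits_ba = hits_ba,
      truth = list(ortholog_map = dplyr::arrange(ortho, .data$gene_a),
                   ids_a = ids_a, ids_b = ids_b, seed = as.integer(seed))
    )
    class(out) <- "synth_hits"
    out
  })
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Write an expression table to TSV
#'
#' First column `gene_id`, remaining columns sample ids, plain decimal values.
#' @param expr Expression tibble (`gene_id` + sample columns).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_expression_tsv <- function(expr, path) {
  validate_expression(expr)
  write_tsv_atomic(expr, path)
}

#' Write promoter sequences as FASTA
#' @param promoters A `promoter_set` or named character vector of sequences.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_promoters_fasta <- function(promoters, path) {
  seqs <- if (inherits(promoters, "promoter_set")) promoters$sequences
          else promoters
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read promoter sequences from FASTA
#' @param path FASTA file path.
#' @return A `promoter_set` (without a truth ledger).
#' @export
read_promoters_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- list(
    sequences = stats::setNames(as.character(x), names(x)),
    nominal_length = if (length(x) > 0) max(Biostrings::width(x)) else 0L,
    truth = NULL
  )
  class(out) <- "promoter_set"
  out
}

#' Write alignment hits in 12-column tabular format
#' @param hits Tibble with the standard 12 columns
#'   (qseqid..bitscore).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  tmp <- paste0(path, ".tmp")
  readr::write_tsv(hits, tmp, col_names = FALSE, progress = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

#' Write a synthetic truth ledger as JSON
#' @param truth A truth list from any generator.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  write_json_atomic(truth, path)
}
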