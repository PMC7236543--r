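#' Read a gene-set collection from GMT
#'
#' One set per line: term, description, then tab-separated gene ids. The
#' description field is used as the term's namespace (GO/KEGG/PO/GFam/other).
#'
#' @param path GMT file path.
#' @param background Optional gene universe; defaults to the union of all
#'   term members.
#' @return A `gene_sets` tibble: `term`, `namespace`, `genes` (list column),
#'   with the universe in `attr(, "background")`.
#' @export
read_gmt <- function(path, background = NULL) {
  abort_if(!file.exists(path), paste0("no such file: ", path))
  sets <- fgsea::gmtPathways(path)
  fields <- strsplit(readLines(path), "\t", fixed = TRUE)
  abort_if(any(lengths(fields) < 3),
           "malformed GMT: every line needs term, description, >= 1 gene")
  ns <- vapply(fields, `[[`, character(1), 2)
  out <- tibble::tibble(
    term = names(sets),
    namespace = ns,
    genes = unname(sets)
  )
  abort_if(any(lengths(out$genes) == 0), "empty term in GMT")
  attr(out, "background") <- background %||% sort(unique(unlist(sets)))
  class(out) <- c("gene_sets", class(out))
  out
}

#' Write a gene-set collection to GMT
#' @param genesets A `gene_sets` tibble.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gmt <- function(genesets, path) {
  lines <- purrr::pmap_chr(
    list(genesets$term, genesets$namespace, genesets$genes),
    function(term, ns, genes) paste(c(term, ns, genes), collapse = "\t")
  )
  tmp <- paste0(path, ".tmp")
  writeLines(lines, tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Fisher exact over-representation test
#'
#' One-sided over-representation p-value for the overlap of a subject gene
#' set with a term: the exact hypergeometric upper tail
#' `P(X >= overlap)` when drawing `|subject|` genes from the background
#' without replacement, `|term|` of which are term members. No normal
#' approximation is used.
#'
#' @param subject_genes,term_genes Character vectors of gene ids, both
#'   subsets of `background`.
#' @param background Character vector: the gene universe.
#' @return One-row tibble: `overlap`, `subject_size`, `term_size`,
#'   `background_size`, `p_value`.
#' @export
#' @examples
#' fisher_enrichment(letters[1:5], letters[1:5], letters[1:20])$p_value
fisher_enrichment <- function(subject_genes, term_genes, background) {
  subject_genes <- unique(subject_genes)
  term_genes <- unique(term_genes)
  background <- unique(background)
  abort_if(length(background) < 2, "background must have at least 2 genes")
  bad <- setdiff(c(subject_genes, term_genes), background)
  abort_if(length(bad) > 0,
           paste0("genes outside background: ",
                  paste(head(bad, 5), collapse = ", ")))
  q <- length(intersect(subject_genes, term_genes))
  m <- length(term_genes)
  n <- length(background) - m
  k <- length(subject_genes)
  tibble::tibble(
    overlap = q,
    subject_size = k,
    term_size = m,
    background_size = length(background),
    p_value = phyper(q - 1, m, n, k, lower.tail = FALSE)
  )
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; input order is preserved. A Bonferroni option is
#' available for family-wise control.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @param method `"BH"` (default) or `"bonferroni"`.
#' @return Adjusted values, capped at 1, in the input order.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
bh_fdr <- function(p_values, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  abort_if(any(p_values <= 0 | p_values > 1 | !is.finite(p_values)),
           "p-values must lie in (0, 1]")
  p.adjust(p_values, method = method)
}

#' Annotate modules by gene-set over-representation
#'
#' Fisher exact test of every (module, term) combination, with FDR control
#' applied across all tests within each namespace. Results with
#' `fdr < fdr_cutoff` are flagged significant; modules with no significant
#' term are left unannotated (and can be filtered downstream as suspect).
#' Module genes absent from the background are dropped with a warning.
#'
#' @param modules A `coex_modules` tibble.
#' @param genesets A `gene_sets` tibble.
#' @param fdr_cutoff Significance cutoff on the adjusted p-value
#'   (default 0.05).
#' @param background Gene universe; defaults to the collection's. Typically
#'   the genes of the filtered expression matrix.
#' @param method Adjustment method, see [bh_fdr()].
#' @return Tibble: `subject` (module id), `term`, `namespace`, `overlap`,
#'   `subject_size`, `term_size`, `background_size`, `p_value`, `fdr`,
#'   `significant`.
#' @export
annotate_modules <- function(modules, genesets, fdr_cutoff = 0.05,
                             background = NULL, method = "BH") {
  abort_if(nrow(genesets) == 0, "empty gene-set collection")
  background <- unique(background %||% attr(genesets, "background"))
  mod_genes <- lapply(modules$genes, function(g) {
    out <- intersect(g, background)
    if (length(out) < length(g)) {
      warning("module genes outside background dropped", call. = FALSE)
    }
    out
  })
  term_genes <- lapply(genesets$genes, intersect, background)

  grid <- tidyr::expand_grid(
    mi = seq_len(nrow(modules)),
    ti = seq_len(nrow(genesets))
  )
  q <- purrr::map2_int(grid$mi, grid$ti, function(i, j) {
    length(intersect(mod_genes[[i]], term_genes[[j]]))
  })
  m <- lengths(term_genes)[grid$ti]
  k <- lengths(mod_genes)[grid$mi]
  res <- tibble::tibble(
    subject = modules$module_id[grid$mi],
    term = genesets$term[grid$ti],
    namespace = genesets$namespace[grid$ti],
    overlap = q,
    subject_size = k,
    term_size = m,
    background_size = length(background),
    p_value = phyper(q - 1, m, length(background) - m, k, lower.tail = FALSE)
  )
  res <- res |>
    dplyr::group_by(.data$namespace) |>
    dplyr::mutate(fdr = bh_fdr(.data$p_value, method = method)) |>
    dplyr::ungroup() |>
    dplyr::mutate(significant = .data$fdr < fdr_cutoff) |>
    dplyr::arrange(.data$subject, .data$fdr, .data$term)
  res
}

#' Refine per-gene annotations from modules and coexpression neighborhoods
#'
#' Two-step refinement. Step 1: every gene of a module inherits the module's
#' significant terms (provenance `module`). Step 2: for every network gene
#' with at least one neighbor, its direct coexpression-neighbor set is tested
#' for over-representation against every term, FDR-adjusted per gene, and
#' terms with `fdr < fdr_cutoff` are appended (provenance `neighbor`).
#' Neighbor-derived terms never displace module-inherited ones.
#'
#' @param network A `coex_network`.
#' @param modules A `coex_modules` tibble.
#' @param module_annotations Result of [annotate_modules()].
#' @param genesets A `gene_sets` tibble.
#' @param fdr_cutoff Cutoff on the per-gene adjusted p-value.
#' @param background Gene universe; defaults to the collection's.
#' @param method Adjustment method, see [bh_fdr()].
#' @return Tibble `gene_id`, `term`, `namespace`, `provenance`, `p_value`,
#'   `fdr` (p and fdr are `NA` for module-inherited records); the fraction of
#'   network genes with at least one annotation is in
#'   `attr(, "annotated_fraction")`.
#' @export
refine_gene_annotations <- function(network, modules, module_annotations,
                                    genesets, fdr_cutoff = 0.05,
                                    background = NULL, method = "BH") {
  background <- unique(background %||% attr(genesets, "background"))

  sig <- module_annotations[module_annotations$significant, , drop = FALSE]
  membership <- tidy(modules)
  inherited <- membership |>
    dplyr::inner_join(sig[, c("subject", "term", "namespace")],
                      by = c(module_id = "subject"),
                      relationship = "many-to-many") |>
    dplyr::distinct(.data$gene_id, .data$term, .data$namespace) |>
    dplyr::mutate(provenance = "module", p_value = NA_real_, fdr = NA_real_)

  # step 2: per-gene enrichment of the direct-neighbor set
  edges <- network$edges
  nbr <- split(
    c(edges$gene_b, edges$gene_a),
    c(edges$gene_a, edges$gene_b)
  )
  term_genes <- lapply(genesets$genes, intersect, background)
  n_bg <- length(background)
  m_sizes <- lengths(term_genes)

  derived <- purrr::imap(nbr, function(neighbors, gene) {
    neighbors <- intersect(unique(neighbors), background)
    if (length(neighbors) == 0) return(NULL)
    q <- vapply(term_genes, function(tg) {
      length(intersect(neighbors, tg))
    }, integer(1))
    p <- phyper(q - 1, m_sizes, n_bg - m_sizes, length(neighbors),
                lower.tail = FALSE)
    fdr <- bh_fdr(p, method = method)
    keep <- fdr < fdr_cutoff
    if (!any(keep)) return(NULL)
    tibble::tibble(
      gene_id = gene,
      term = genesets$term[keep],
      namespace = genesets$namespace[keep],
      provenance = "neighbor",
      p_value = p[keep],
      fdr = fdr[keep]
    )
  })
  out <- dplyr::bind_rows(inherited, dplyr::bind_rows(derived)) |>
    dplyr::arrange(.data$gene_id, .data$term, .data$provenance) |>
    dplyr::distinct(.data$gene_id, .data$term, .keep_all = TRUE)
  attr(out, "annotated_fraction") <-
    length(unique(out$gene_id)) / max(length(network$nodes), 1)
  out
}

#' Flag strong enrichment results by a randomization Z score
#'
#' For each enrichment result, compares the observed overlap with the
#' overlaps of `n_draws` random gene sets of the same size drawn from the
#' background (the same null machinery as promoter-motif testing):
#' `Z = (observed - mean_null) / sd_null`. Results with `Z > z_cutoff` are
#' flagged. A degenerate null (zero SD) leaves the flag undefined and is
#' reported as such.
#'
#' @param results Result tibble from [annotate_modules()].
#' @param modules The `coex_modules` the results refer to.
#' @param genesets A `gene_sets` tibble.
#' @param z_cutoff Flagging cutoff (default 4).
#' @param n_draws Random draws per result (default 1000).
#' @param background Gene universe; defaults to the collection's.
#' @param seed Integer seed.
#' @return `results` with columns `z`, `z_degenerate`, `z_flag` appended.
#' @export
term_zscore_flag <- function(results, modules, genesets, z_cutoff = 4,
                             n_draws = 1000, background = NULL, seed = 1) {
  background <- unique(background %||% attr(genesets, "background"))
  genes_of_module <- stats::setNames(modules$genes, modules$module_id)
  genes_of_term <- stats::setNames(genesets$genes, genesets$term)

  with_seed(seed, {
    stats_list <- purrr::pmap(
      list(results$subject, results$term, results$overlap),
      function(subject, term, observed) {
        size <- length(intersect(genes_of_module[[subject]], background))
        tg <- intersect(genes_of_term[[term]], background)
        null_overlap <- vapply(seq_len(n_draws), function(i) {
          length(intersect(sample(background, size), tg))
        }, integer(1))
        mu <- mean(null_overlap)
        s <- sd(null_overlap)
        list(z = if (s == 0) NA_real_ else (observed - mu) / s,
             degenerate = s == 0)
      }
    )
    out <- dplyr::mutate(
      results,
      z = vapply(stats_list, `[[`, numeric(1), "z"),
      z_degenerate = vapply(stats_list, `[[`, logical(1), "degenerate"),
      z_flag = !is.na(.data$z) & .data$z > z_cutoff
    )
    if (any(out$z_degenerate)) {
      warning(sum(out$z_degenerate),
              " result(s) had a degenerate (zero-SD) null", call. = FALSE)
    }
    out
  })
}
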