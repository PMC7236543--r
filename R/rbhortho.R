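hit_columns <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore")

#' Read 12-column tabular alignment hits
#'
#' Standard tabular alignment output: qseqid, sseqid, pident, length,
#' mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore.
#'
#' @param path TSV path (no header).
#' @return Tibble with the 12 standard columns.
#' @export
read_hits_tsv <- function(path) {
  abort_if(!file.exists(path), paste0("no such file: ", path))
  hits <- readr::read_tsv(path, col_names = hit_columns,
                          col_types = "ccdiiiiiiidd", progress = FALSE)
  probs <- readr::problems(hits)
  abort_if(nrow(probs) > 0,
           paste0("parse error in ", path, " at line ", probs$row[1]))
  abort_if(any(hits$evalue < 0), "negative E-value")
  hits
}

#' Collapse alignment hits to the best HSP per query-subject pair
#'
#' Keeps, for each (query, subject) pair, the row with the lowest E-value;
#' ties go to the highest bit score, then to the first occurrence.
#'
#' @param hits Hit tibble (12 standard columns).
#' @return The collapsed tibble, one row per pair.
#' @export
collapse_best_hsp <- function(hits) {
  hits |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::group_by(.data$qseqid, .data$sseqid) |>
    dplyr::arrange(.data$evalue, dplyr::desc(.data$bitscore), .data$.row,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$.row) |>
    dplyr::select(-".row")
}

# per-query subject ranks: ascending evalue, ties by descending bitscore,
# then subject id
rank_hits <- function(hits) {
  hits |>
    dplyr::group_by(.data$qseqid) |>
    dplyr::arrange(.data$evalue, dplyr::desc(.data$bitscore), .data$sseqid,
                   .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup()
}

#' Reciprocal top-N orthologous pairs
#'
#' Ranks every query's subjects by ascending E-value (ties: descending bit
#' score, then subject id) in both alignment directions and returns the pairs
#' (a, b) where b is within a's top `top_n` hits and a is within b's top
#' `top_n`. `top_n = 1` is the strict reciprocal-best-hit criterion; the
#' default 3 is the looser reciprocal-top-3 reading.
#'
#' @param hits_ab Collapsed hits with species-A queries.
#' @param hits_ba Collapsed hits with species-B queries.
#' @param top_n Reciprocal rank cutoff (default 3).
#' @return Tibble of pairs: `gene_a`, `gene_b`, `tier` (`"best"`), `rank_a`
#'   (b's rank in a's list), `rank_b`, `min_e_value`.
#' @export
reciprocal_top_hits <- function(hits_ab, hits_ba, top_n = 3) {
  if (nrow(hits_ab) == 0 || nrow(hits_ba) == 0) {
    warning("empty hit table; no reciprocal pairs")
    return(tibble::tibble(gene_a = character(0), gene_b = character(0),
                          tier = character(0), rank_a = integer(0),
                          rank_b = integer(0), min_e_value = numeric(0)))
  }
  ra <- rank_hits(hits_ab)
  rb <- rank_hits(hits_ba)
  ra |>
    dplyr::filter(.data$rank <= top_n) |>
    dplyr::select(gene_a = "qseqid", gene_b = "sseqid",
                  rank_a = "rank", e_ab = "evalue") |>
    dplyr::inner_join(
      rb |>
        dplyr::filter(.data$rank <= top_n) |>
        dplyr::select(gene_b = "qseqid", gene_a = "sseqid",
                      rank_b = "rank", e_ba = "evalue"),
      by = c("gene_a", "gene_b")
    ) |>
    dplyr::transmute(
      .data$gene_a, .data$gene_b, tier = "best",
      .data$rank_a, .data$rank_b,
      min_e_value = pmin(.data$e_ab, .data$e_ba)
    ) |>
    dplyr::distinct(.data$gene_a, .data$gene_b, .keep_all = TRUE) |>
    dplyr::arrange(.data$gene_a, .data$gene_b)
}

#' E-value threshold at the peak of the best-pair distribution
#'
#' Histograms `log10` of the best pairs' minimum E-values (zeros floored at
#' 1e-180) with Freedman-Diaconis bin widths and returns the E-value at the
#' center of the modal bin; ties go to the more significant (smaller) bin.
#' Intended as the cutoff below which additional reciprocal pairs qualify as
#' secondary orthologs.
#'
#' @param best_pairs Tibble from [reciprocal_top_hits()].
#' @param e_floor Floor applied to zero E-values before the log transform.
#' @return A single E-value threshold.
#' @export
evalue_peak_threshold <- function(best_pairs, e_floor = 1e-180) {
  abort_if(nrow(best_pairs) == 0, "no best pairs")
  x <- log10(pmax(best_pairs$min_e_value, e_floor))
  if (length(unique(x)) == 1) {
    warning("degenerate E-value histogram: all values identical")
    return(10^x[1])
  }
  bw <- 2 * IQR(x) / length(x)^(1 / 3)
  if (bw == 0) {
    warning("degenerate E-value histogram: zero bin width; using median")
    return(10^stats::median(x))
  }
  breaks <- seq(min(x) - bw / 2, max(x) + bw, by = bw)
  h <- hist(x, breaks = breaks, plot = FALSE)
  mode_bin <- which(h$counts == max(h$counts))[1] # smallest center on ties
  10^h$mids[mode_bin]
}

#' Secondary orthologous pairs below an E-value threshold
#'
#' Reciprocal pairs of any rank whose directional E-values fall below the
#' threshold, excluding pairs already in the best tier. By default the
#' smaller of the two directional E-values is compared against the threshold
#' (the generous reading); `compare = "max"` requires both directions below
#' it.
#'
#' @param hits_ab,hits_ba Collapsed hit tables.
#' @param threshold E-value threshold, normally from
#'   [evalue_peak_threshold()].
#' @param best_pairs Best-tier pairs to exclude.
#' @param compare `"min"` (default) or `"max"`.
#' @return Tibble of pairs with `tier = "secondary"`.
#' @export
secondary_pairs <- function(hits_ab, hits_ba, threshold, best_pairs,
                            compare = c("min", "max")) {
  compare <- match.arg(compare)
  ra <- rank_hits(hits_ab)
  rb <- rank_hits(hits_ba)
  all_recip <- ra |>
    dplyr::select(gene_a = "qseqid", gene_b = "sseqid",
                  rank_a = "rank", e_ab = "evalue") |>
    dplyr::inner_join(
      rb |>
        dplyr::select(gene_b = "qseqid", gene_a = "sseqid",
                      rank_b = "rank", e_ba = "evalue"),
      by = c("gene_a", "gene_b")
    )
  crit <- if (compare == "min") pmin(all_recip$e_ab, all_recip$e_ba)
          else pmax(all_recip$e_ab, all_recip$e_ba)
  out <- all_recip[crit < threshold, , drop = FALSE]
  best_key <- paste(best_pairs$gene_a, best_pairs$gene_b)
  out <- out[!(paste(out$gene_a, out$gene_b) %in% best_key), , drop = FALSE]
  out |>
    dplyr::transmute(
      .data$gene_a, .data$gene_b, tier = "secondary",
      .data$rank_a, .data$rank_b,
      min_e_value = pmin(.data$e_ab, .data$e_ba)
    ) |>
    dplyr::arrange(.data$gene_a, .data$gene_b)
}

#' Best and secondary orthologs from a pair of alignment tables
#'
#' Convenience wrapper: collapses HSPs, takes reciprocal top-`top_n` pairs,
#' derives the E-value peak threshold from them, and appends secondary pairs
#' below it.
#'
#' @param hits_ab,hits_ba Raw hit tables (12 standard columns).
#' @param top_n Reciprocal rank cutoff for the best tier.
#' @param compare Directional E-value comparison for the secondary tier.
#' @return Tibble of `OrthologPair` rows (both tiers), with the threshold in
#'   `attr(, "evalue_threshold")`.
#' @export
find_orthologs <- function(hits_ab, hits_ba, top_n = 3, compare = "min") {
  ab <- collapse_best_hsp(hits_ab)
  ba <- collapse_best_hsp(hits_ba)
  best <- reciprocal_top_hits(ab, ba, top_n = top_n)
  if (nrow(best) == 0) {
    attr(best, "evalue_threshold") <- NA_real_
    return(best)
  }
  thr <- evalue_peak_threshold(best)
  sec <- secondary_pairs(ab, ba, thr, best, compare = compare)
  out <- dplyr::bind_rows(best, sec)
  attr(out, "evalue_threshold") <- thr
  out
}
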