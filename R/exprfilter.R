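#' Read and validate an FPKM expression matrix from TSV
#'
#' Strict reader: the first column must be `gene_id`, every other column is a
#' sample of plain decimal FPKM values. Ragged rows, duplicate gene or sample
#' ids, non-numeric cells and negative values are rejected with an error.
#'
#' @param path TSV file path.
#' @return A validated expression tibble (`gene_id` + numeric sample columns).
#' @export
read_expression_matrix <- function(path) {
  abort_if(!file.exists(path), paste0("no such file: ", path))
  expr <- withCallingHandlers(
    readr::read_tsv(path, col_types = readr::cols(
      gene_id = readr::col_character(),
      .default = readr::col_double()
    ), progress = FALSE),
    warning = function(w) stop("parse error in ", path, ": ",
                               conditionMessage(w), call. = FALSE)
  )
  probs <- readr::problems(expr)
  abort_if(nrow(probs) > 0,
           paste0("parse error in ", path, " at line ",
                  probs$row[1] + 1L, ": ", probs$expected[1]))
  validate_expression(expr)
  expr
}

#' Compute the 3-sigma low-expression FPKM threshold
#'
#' For each sample, takes the `percentile`-th percentile of its FPKM values
#' (linear interpolation between order statistics, zeros included); the
#' threshold is the mean of these per-sample percentiles plus `sigma` times
#' their standard deviation (unbiased, n-1 denominator):
#' `threshold = mean(p) + sigma * sd(p)`.
#'
#' @param expr Expression tibble.
#' @param percentile Lower percentile per sample, in percent (default 5).
#' @param sigma Multiplier on the across-sample SD (default 3).
#' @param groups Optional named list mapping group name to sample ids; when
#'   given, one threshold is computed per group and the result is a list of
#'   `fpkm_threshold` objects.
#' @return An object of class `fpkm_threshold`: fields `per_sample_p`,
#'   `mean_p`, `sd_p`, `threshold`, `percentile`, `sigma`.
#' @export
#' @examples
#' expr <- tibble::tibble(gene_id = c("a", "b", "c"),
#'                        s1 = c(0, 1, 10), s2 = c(0.2, 2, 9))
#' compute_fpkm_threshold(expr)$threshold
compute_fpkm_threshold <- function(expr, percentile = 5, sigma = 3,
                                   groups = NULL) {
  validate_expression(expr)
  if (!is.null(groups)) {
    return(lapply(groups, function(s) {
      compute_fpkm_threshold(expr[, c("gene_id", s)], percentile, sigma)
    }))
  }
  m <- expr_as_matrix(expr)
  abort_if(ncol(m) < 2 && sigma != 0,
           "at least 2 samples required (SD undefined) unless sigma = 0")
  p <- apply(m, 2, quantile, probs = percentile / 100, names = FALSE)
  sd_p <- if (length(p) > 1) sd(p) else 0
  out <- list(
    per_sample_p = p,
    mean_p = mean(p),
    sd_p = sd_p,
    threshold = mean(p) + sigma * sd_p,
    percentile = percentile,
    sigma = sigma
  )
  class(out) <- "fpkm_threshold"
  out
}

#' @export
print.fpkm_threshold <- function(x, ...) {
  cat(sprintf(
    "FPKM threshold: %.4g (mean p%g = %.4g, sd = %.4g, sigma = %g, %d samples)\n",
    x$threshold, x$percentile, x$mean_p, x$sd_p, x$sigma,
    length(x$per_sample_p)))
  invisible(x)
}

#' @export
tidy.fpkm_threshold <- function(x, ...) {
  tibble::tibble(sample_id = names(x$per_sample_p) %||%
                   paste0("s", seq_along(x$per_sample_p)),
                 p_low = unname(x$per_sample_p))
}

#' @export
glance.fpkm_threshold <- function(x, ...) {
  tibble::tibble(threshold = x$threshold, mean_p = x$mean_p, sd_p = x$sd_p,
                 percentile = x$percentile, sigma = x$sigma,
                 n_samples = length(x$per_sample_p))
}

#' Remove genes below the FPKM threshold in every sample
#'
#' A gene is removed iff its FPKM is strictly below the threshold in every
#' sample; a single sample at or above the threshold retains it. Sample
#' columns are never altered. Filtering is idempotent.
#'
#' @param expr Expression tibble.
#' @param threshold An `fpkm_threshold` object or a bare number.
#' @return The filtered expression tibble, with the removal report
#'   (tibble: `gene_id`, `max_fpkm`, `removed`) in `attr(, "removal_report")`
#'   and the retained fraction in `attr(, "retained_fraction")`.
#' @export
filter_low_expression <- function(expr, threshold) {
  validate_expression(expr)
  thr <- if (inherits(threshold, "fpkm_threshold")) threshold$threshold
         else as.numeric(threshold)
  m <- expr_as_matrix(expr)
  max_fpkm <- apply(m, 1, max)
  removed <- max_fpkm < thr
  report <- tibble::tibble(
    gene_id = rownames(m),
    max_fpkm = unname(max_fpkm),
    removed = unname(removed)
  )
  out <- expr[!removed, , drop = FALSE]
  attr(out, "removal_report") <- report
  attr(out, "retained_fraction") <- 1 - mean(removed)
  out
}
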