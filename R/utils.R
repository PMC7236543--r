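# Internal helpers shared across stages.

# Round half away from zero at `digits` decimals. base::round() rounds half to
# even, which does not reproduce report-style figures such as 39.6 from 39.55.
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# global RNG is untouched. All stochastic operations in the package funnel
# through this, so one integer seed determines every generated byte.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

# Derive a stream-specific child seed so that stages sharing one user seed do
# not consume the same random numbers.
child_seed <- function(seed, stream) {
  (as.integer(seed) * 1103L + as.integer(stream) * 12289L) %% 2147483629L
}

abort_if <- function(cond, msg) {
  if (cond) stop(msg, call. = FALSE)
}

# Expression tables are tibbles: `gene_id` + one numeric column per sample.
expr_gene_ids <- function(expr) expr[["gene_id"]]

expr_sample_ids <- function(expr) setdiff(names(expr), "gene_id")

# genes x samples numeric matrix with gene ids as rownames
expr_as_matrix <- function(expr) {
  m <- as.matrix(expr[, expr_sample_ids(expr), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- expr_gene_ids(expr)
  m
}

expr_from_matrix <- function(m) {
  dplyr::bind_cols(
    tibble::tibble(gene_id = rownames(m)),
    tibble::as_tibble(m)
  )
}

validate_expression <- function(expr) {
  abort_if(!is.data.frame(expr), "expression table must be a data frame")
  abort_if(!"gene_id" %in% names(expr),
           "expression table must have a `gene_id` first column")
  samples <- expr_sample_ids(expr)
  abort_if(length(samples) == 0, "expression table has no sample columns")
  abort_if(anyDuplicated(expr$gene_id) > 0,
           "duplicate gene ids in expression table")
  abort_if(anyDuplicated(samples) > 0, "duplicate sample ids")
  m <- expr_as_matrix(expr)
  abort_if(any(!is.finite(m)), "expression values must be finite")
  abort_if(any(m < 0), "expression values must be non-negative (FPKM)")
  invisible(expr)
}

# Canonical unordered pair labels: gene_a < gene_b lexicographically.
canonical_pairs <- function(a, b) {
  swap <- a > b
  tibble::tibble(
    gene_a = ifelse(swap, b, a),
    gene_b = ifelse(swap, a, b)
  )
}

write_tsv_atomic <- function(x, path) {
  tmp <- paste0(path, ".tmp")
  readr::write_tsv(x, tmp, progress = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

write_json_atomic <- function(x, path) {
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  file.rename(tmp, path)
  invisible(path)
}
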