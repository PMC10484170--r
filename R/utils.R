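# shared internal helpers

stop_format <- function(msg) abort(msg, class = "specsel_format_error")

# deterministic child seed; stays inside 32-bit signed range
derive_seed <- function(seed, offset) {
  ((as.numeric(seed) %% 2147483647) * 48271 + offset) %% 2147483647
}

rank_avg <- function(x) rank(x, ties.method = "average", na.last = "keep")

# expression tibble (gene_id + one column per sample) -> numeric matrix
expr_to_matrix <- function(expr) {
  stopifnot(is.data.frame(expr), names(expr)[1] == "gene_id")
  m <- as.matrix(expr[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- expr$gene_id
  m
}

matrix_to_expr <- function(m) {
  bind_cols(tibble(gene_id = rownames(m)), as_tibble(m))
}

log_skip <- function(what, n) {
  if (n > 0) inform(sprintf("specsel: skipped %d %s", n, what))
}
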