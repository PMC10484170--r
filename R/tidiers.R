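# broom-style accessors for the package's fitted objects

#' Tidy a surrogate-variable fit
#'
#' @param x An `sva_fit` from [estimate_surrogates()].
#' @param what `"variance"` (per-component variance shares and permutation
#'   p-values), `"surrogates"` (per-sample surrogate values, long) or
#'   `"loadings"` (per-gene loadings, long).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.sva_fit <- function(x, what = c("variance", "surrogates", "loadings"),
                         ...) {
  what <- match.arg(what)
  if (what == "variance") {
    return(tibble(component = seq_along(x$variance_share),
                  variance_share = x$variance_share,
                  p_value = x$p_values,
                  selected = seq_along(x$variance_share) <= x$k))
  }
  if (what == "surrogates") {
    if (x$k == 0L) {
      return(tibble(sample_id = character(0), surrogate = integer(0),
                    value = numeric(0)))
    }
    return(tibble(sample_id = rep(x$sample_ids, x$k),
                  surrogate = rep(seq_len(x$k), each = length(x$sample_ids)),
                  value = as.vector(x$surrogates)))
  }
  if (x$k == 0L) {
    return(tibble(gene_id = character(0), surrogate = integer(0),
                  loading = numeric(0)))
  }
  tibble(gene_id = rep(x$gene_ids, x$k),
         surrogate = rep(seq_len(x$k), each = length(x$gene_ids)),
         loading = as.vector(x$loadings))
}

#' @rdname tidy.sva_fit
#' @export
glance.sva_fit <- function(x, ...) {
  tibble(k = x$k,
         n_genes = length(x$gene_ids),
         n_samples = length(x$sample_ids),
         variance_removed = sum(x$variance_share[seq_len(x$k)]),
         B = x$B, alpha = x$alpha)
}

#' Tidy the ZINB confounding experiment
#'
#' @param x A `zinb_experiment` from [zinb_specificity_experiment()].
#' @param ... Unused.
#' @return `tidy()`: the per-matrix correlation tibble. `glance()`: one row
#'   with the mean correlation including and excluding zeros and the
#'   proportion of matrices where excluding zeros moved the correlation
#'   closer to zero.
#' @export
tidy.zinb_experiment <- function(x, ...) x$correlations

#' @rdname tidy.zinb_experiment
#' @export
glance.zinb_experiment <- function(x, ...) {
  cc <- x$correlations
  tibble(
    n_matrices = nrow(cc),
    mean_cor_including = mean(cc$cor_including, na.rm = TRUE),
    mean_cor_excluding = mean(cc$cor_excluding, na.rm = TRUE),
    prop_excluding_closer_to_zero =
      mean(abs(cc$cor_excluding) < abs(cc$cor_including), na.rm = TRUE)
  )
}

#' @export
print.zinb_experiment <- function(x, ...) {
  g <- glance(x)
  cat("ZINB specificity experiment:", g$n_matrices, "matrices\n")
  cat(sprintf("  mean Spearman(tau, avg incl. zeros): %.3f\n",
              g$mean_cor_including))
  cat(sprintf("  mean Spearman(tau, avg excl. zeros): %.3f\n",
              g$mean_cor_excluding))
  cat(sprintf("  excluding zeros closer to 0 in %.1f%% of matrices\n",
              100 * g$prop_excluding_closer_to_zero))
  invisible(x)
}

#' @export
print.sva_fit <- function(x, ...) {
  cat(sprintf("surrogate-variable fit: K = %d (%d genes x %d samples)\n",
              x$k, length(x$gene_ids), length(x$sample_ids)))
  invisible(x)
}
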