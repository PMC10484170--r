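# Zero-inflated negative-binomial expression simulation: the confounding
# experiment showing why thresholded averaging decouples average expression
# from the tau specificity index.

#' Draw a zero-inflated negative-binomial expression matrix
#'
#' Each entry is zero with probability `1 - prob_nonzero` and otherwise a
#' negative-binomial draw with the (size, success-probability)
#' parameterization, mean `nb_size * (1 - nb_prob) / nb_prob`. Columns are
#' organised into `n_groups` blocks of `reps_per_group` replicates
#' representing tissue/treatment groups.
#'
#' @param n_genes Number of rows (genes).
#' @param n_groups,reps_per_group Column-block structure (defaults 5 x 5).
#' @param nb_size,nb_prob Negative-binomial size and success probability
#'   (defaults 100 and 0.1).
#' @param prob_nonzero Probability that an entry is non-zero (default 0.4).
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments and the seed.
#' @return A numeric matrix with a `groups` attribute labelling the column
#'   blocks.
#' @export
simulate_zinb_matrix <- function(n_genes = 500, n_groups = 5,
                                 reps_per_group = 5, nb_size = 100,
                                 nb_prob = 0.1, prob_nonzero = 0.4,
                                 seed = 1L) {
  stopifnot(nb_prob > 0, nb_prob < 1, prob_nonzero >= 0, prob_nonzero <= 1)
  n_col <- n_groups * reps_per_group
  m <- with_seed(as.integer(seed), {
    nz <- rbinom(n_genes * n_col, 1L, prob_nonzero)
    matrix(nz * rnbinom(n_genes * n_col, size = nb_size, prob = nb_prob),
           nrow = n_genes, ncol = n_col)
  })
  rownames(m) <- paste0("gene", seq_len(n_genes))
  colnames(m) <- paste0("g", rep(seq_len(n_groups), each = reps_per_group),
                        "_r", rep(seq_len(reps_per_group), n_groups))
  attr(m, "groups") <- rep(paste0("g", seq_len(n_groups)),
                           each = reps_per_group)
  m
}

#' The ZINB specificity-vs-average-expression experiment
#'
#' For each of `n_matrices` simulated matrices: average columns within each
#' group, compute tau across the group means, and correlate tau with (a) the
#' average over all entries of the row and (b) the average over the non-zero
#' entries only (genes with all-zero rows are dropped pairwise). The
#' comparison of the two Spearman correlation distributions shows that
#' excluding unexpressed entries pulls the specificity/average-expression
#' correlation towards zero.
#'
#' @inheritParams simulate_zinb_matrix
#' @param n_matrices Number of replicate matrices (default 1,000).
#' @return An object of class `zinb_experiment`: a list with `correlations`
#'   (tibble: `matrix`, `cor_including`, `cor_excluding`) and `params`.
#' @export
zinb_specificity_experiment <- function(n_matrices = 1000, n_genes = 500,
                                        n_groups = 5, reps_per_group = 5,
                                        nb_size = 100, nb_prob = 0.1,
                                        prob_nonzero = 0.4, seed = 1L) {
  cor_inc <- cor_exc <- numeric(n_matrices)
  grp <- rep(seq_len(n_groups), each = reps_per_group)
  for (i in seq_len(n_matrices)) {
    m <- simulate_zinb_matrix(n_genes, n_groups, reps_per_group, nb_size,
                              nb_prob, prob_nonzero,
                              seed = derive_seed(seed, i))
    means <- t(rowsum(t(m), grp) / as.vector(table(grp)))
    tau <- .tau_rows(means)
    nz <- m > 0
    n_nz <- rowSums(nz)
    avg_inc <- rowMeans(m)
    avg_exc <- ifelse(n_nz > 0, rowSums(m) / n_nz, NA_real_)
    cor_inc[i] <- cor(avg_inc, tau, method = "spearman",
                      use = "pairwise.complete.obs")
    cor_exc[i] <- cor(avg_exc, tau, method = "spearman",
                      use = "pairwise.complete.obs")
  }
  structure(list(
    correlations = tibble(matrix = seq_len(n_matrices),
                          cor_including = cor_inc, cor_excluding = cor_exc),
    params = list(n_matrices = n_matrices, n_genes = n_genes,
                  n_groups = n_groups, reps_per_group = reps_per_group,
                  nb_size = nb_size, nb_prob = nb_prob,
                  prob_nonzero = prob_nonzero, seed = seed)
  ), class = "zinb_experiment")
}
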