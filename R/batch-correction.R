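# Surrogate-variable batch correction. Expression is modelled on the log2
# scale as x_ij = mu_i + f(y_j) + sum_k lambda_ki h_kj + e*_ij where f is the
# per-treatment mean deviation and the h_k are orthonormal sample-space
# vectors spanning the residual batch structure (the surrogate variables).
# The number of surrogates is picked by a Buja-Eyuboglu-style permutation
# test on the residual singular-value spectrum, a deliberate simplification
# of the iteratively-reweighted svaseq estimator: the model contract (design
# fit, surrogate span, removal) is the same, the estimator internals simpler.

#' Keep only treatments represented in at least `min_studies` studies
#'
#' Treatments observed in a single study confound treatment signal with
#' study-level batch variation; this helper applies the subsetting rule of
#' dropping them before surrogate estimation.
#'
#' @inheritParams validate_expression
#' @param min_studies Minimum number of distinct `study_id` values per
#'   treatment.
#' @return A list with the filtered `expr` and `samples`.
#' @export
filter_min_studies <- function(expr, samples, min_studies = 2) {
  meta <- samples[match(names(expr)[-1], samples$sample_id), ]
  keep_tr <- meta |>
    group_by(.data$treatment_label) |>
    summarise(n_studies = n_distinct(.data$study_id), .groups = "drop") |>
    filter(.data$n_studies >= min_studies) |>
    pull("treatment_label")
  keep <- meta$sample_id[meta$treatment_label %in% keep_tr]
  list(expr = expr[, c("gene_id", keep)],
       samples = samples[samples$sample_id %in% keep, ])
}

#' Fit the treatment design on the log2 scale
#'
#' Transforms TPM as `log2(tpm + 1)` and fits, per gene, the grand mean plus
#' per-treatment-category mean deviations; residuals are the within-category
#' centred values. Fitted plus residuals reconstructs the transformed matrix
#' exactly.
#'
#' @inheritParams group_means
#' @param transform Whether to apply the `log2(tpm + 1)` transform (disable
#'   for data already on a linear-model scale).
#' @return An object of class `treatment_fit`: transformed matrix `y`,
#'   `fitted`, `residuals`, the treatment factor and sample/gene identifiers.
#' @export
fit_treatment_design <- function(expr, samples, by = "treatment",
                                 transform = TRUE) {
  col <- .label_col(by)
  meta <- samples[match(names(expr)[-1], samples$sample_id), ]
  if (anyNA(meta$sample_id)) stop_format("samples absent from metadata")
  groups <- factor(meta[[col]])
  if (any(table(groups) < 2)) {
    stop_format("every category needs at least two experiments")
  }
  m <- expr_to_matrix(expr)
  y <- if (transform) log2(m + 1) else m
  gm <- t(rowsum(t(y), groups) / as.vector(table(groups)))
  fitted <- gm[, as.integer(groups), drop = FALSE]
  colnames(fitted) <- colnames(y)
  structure(list(y = y, fitted = fitted, residuals = y - fitted,
                 groups = groups, transform = transform,
                 sample_ids = colnames(y), gene_ids = rownames(y)),
            class = "treatment_fit")
}

# re-residualize a matrix on the treatment design (projection used by the
# permutation null)
.residualize <- function(m, groups) {
  gm <- t(rowsum(t(m), groups) / as.vector(table(groups)))
  m - gm[, as.integer(groups), drop = FALSE]
}

#' Estimate surrogate variables from design residuals
#'
#' The surrogates are the leading right singular vectors of the residual
#' matrix. With `k = "auto"` the number retained is chosen by comparing each
#' eigenvalue, normalized by the median eigenvalue of its own spectrum,
#' against its permutation null: every gene's residuals are permuted
#' independently, the permuted matrix is re-residualized on the design, and a
#' component is kept while its observed statistic exceeds the permuted one at
#' level `alpha` (add-one permutation p-values; `B` permutations). Median
#' normalization keeps the test calibrated when the residual spectrum is
#' deficient, e.g. on data from which surrogate directions have already been
#' removed. Surrogate loadings are estimated per gene by
#' least squares of the transformed expression on the design and surrogates
#' jointly, so removal does not absorb treatment signal.
#'
#' @param fit A `treatment_fit` from [fit_treatment_design()].
#' @param k `"auto"` or a fixed non-negative integer.
#' @param B,alpha Permutation count and test level for `k = "auto"`.
#' @param seed Seed for the permutation RNG (required for reproducibility).
#' @return An object of class `sva_fit`: `surrogates` (samples x K,
#'   orthonormal), `loadings` (genes x K), `k`, `variance_share`, `p_values`,
#'   plus the design bookkeeping needed by [remove_surrogates()].
#' @export
estimate_surrogates <- function(fit, k = "auto", B = 200, alpha = 0.05,
                                seed = 1L) {
  stopifnot(inherits(fit, "treatment_fit"))
  r <- fit$residuals
  n_samp <- ncol(r)
  max_k <- min(dim(r)) - nlevels(fit$groups)
  if (max_k < 0) max_k <- 0
  sv <- svd(r)
  share <- sv$d^2 / sum(sv$d^2)
  stat <- sv$d^2 / median(sv$d^2)
  p_values <- rep(NA_real_, length(share))
  if (identical(k, "auto")) {
    exceed <- integer(length(stat))
    with_seed(as.integer(seed), {
      for (b in seq_len(B)) {
        perm <- t(apply(r, 1, sample))
        perm <- .residualize(perm, fit$groups)
        d2 <- svd(perm, nu = 0, nv = 0)$d^2
        exceed <- exceed + (d2 / median(d2) >= stat)
      }
    })
    p_values <- (1 + exceed) / (B + 1)
    below <- which(p_values > alpha)
    k_sel <- if (length(below)) min(below) - 1L else length(share)
    k_sel <- min(k_sel, max_k)
  } else {
    k_sel <- as.integer(k)
    if (k_sel > max_k) {
      stop_format(sprintf("k = %d exceeds min(genes, samples) - rank(design) = %d",
                          k_sel, max_k))
    }
  }
  h <- sv$v[, seq_len(k_sel), drop = FALSE]
  rownames(h) <- fit$sample_ids
  loadings <- .fit_loadings(fit, h)
  structure(list(surrogates = h, loadings = loadings, k = k_sel,
                 variance_share = share, p_values = p_values,
                 groups = fit$groups, transform = fit$transform,
                 sample_ids = fit$sample_ids, gene_ids = fit$gene_ids,
                 B = B, alpha = alpha),
            class = "sva_fit")
}

# per-gene least squares of y on [treatment design, surrogates]; returns the
# genes x K surrogate coefficients
.fit_loadings <- function(fit, h) {
  k <- ncol(h)
  if (k == 0L) {
    return(matrix(numeric(0), nrow = nrow(fit$y), ncol = 0,
                  dimnames = list(fit$gene_ids, NULL)))
  }
  x <- cbind(model.matrix(~ fit$groups), h)
  beta <- t(qr.coef(qr(x), t(fit$y)))
  lam <- beta[, (ncol(x) - k + 1):ncol(x), drop = FALSE]
  dimnames(lam) <- list(fit$gene_ids, paste0("sv", seq_len(k)))
  lam
}

#' Remove fitted surrogate effects from an expression matrix
#'
#' Subtracts `sum_k lambda_ki h_kj` from the transformed expression and
#' back-transforms; back-transformed TPM is clipped at zero. With `k = 0` the
#' input is returned unchanged.
#'
#' @inheritParams validate_expression
#' @param model An `sva_fit` fitted on the same samples.
#' @return The corrected expression tibble (same genes and samples).
#' @export
remove_surrogates <- function(expr, model) {
  stopifnot(inherits(model, "sva_fit"))
  if (!identical(names(expr)[-1], model$sample_ids)) {
    stop_format("expression samples do not match the fitted model")
  }
  m <- expr_to_matrix(expr)
  y <- if (model$transform) log2(m + 1) else m
  if (model$k > 0) {
    y <- y - model$loadings %*% t(model$surrogates)
  }
  out <- if (model$transform) pmax(2^y - 1, 0) else y
  matrix_to_expr(out)
}

#' One-call surrogate-variable correction
#'
#' Convenience wrapper: fit the treatment design, estimate surrogates, remove
#' them.
#'
#' @inheritParams fit_treatment_design
#' @inheritParams estimate_surrogates
#' @param min_studies When `> 0`, first drop treatments seen in fewer than
#'   this many studies (see [filter_min_studies()]).
#' @return A list: `expr` (corrected), `samples`, `model` (the `sva_fit`).
#' @export
sva_correct <- function(expr, samples, by = "treatment", k = "auto",
                        min_studies = 0, B = 200, alpha = 0.05, seed = 1L) {
  if (min_studies > 0) {
    flt <- filter_min_studies(expr, samples, min_studies)
    expr <- flt$expr
    samples <- flt$samples
  }
  fit <- fit_treatment_design(expr, samples, by = by)
  model <- estimate_surrogates(fit, k = k, B = B, alpha = alpha, seed = seed)
  list(expr = remove_surrogates(expr, model), samples = samples, model = model)
}
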