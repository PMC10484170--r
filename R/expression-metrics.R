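# Expression summaries: technical-replicate collapsing, per-category means,
# the tau specificity index, and thresholded average expression.

#' Average technical replicates (runs sharing an experiment ID)
#'
#' Runs with matching `experiment_id` are technical replicates of the same
#' biological sample; their columns are replaced by their unweighted mean.
#' Tissue, treatment and study labels must agree within an experiment.
#'
#' @inheritParams validate_expression
#' @return A list with `expr` (one column per experiment, named by
#'   `experiment_id`) and `samples` (collapsed metadata, `sample_id` set to
#'   the experiment ID).
#' @export
collapse_technical_replicates <- function(expr, samples) {
  validate_expression(expr, samples)
  meta <- samples[match(names(expr)[-1], samples$sample_id), ]
  conflict <- meta |>
    group_by(.data$experiment_id) |>
    summarise(bad = n_distinct(.data$tissue_label) > 1 |
                n_distinct(.data$treatment_label) > 1 |
                n_distinct(.data$study_id) > 1, .groups = "drop")
  if (any(conflict$bad)) {
    stop_format(paste0("conflicting labels within experiment(s): ",
                       paste(conflict$experiment_id[conflict$bad], collapse = ", ")))
  }
  m <- expr_to_matrix(expr)
  f <- factor(meta$experiment_id, levels = unique(meta$experiment_id))
  collapsed <- t(rowsum(t(m), f) / as.vector(table(f)))
  new_meta <- meta |>
    distinct(.data$experiment_id, .data$study_id, .data$tissue_label,
             .data$treatment_label) |>
    mutate(sample_id = .data$experiment_id,
           run_id = .data$experiment_id,
           .before = 1) |>
    select("sample_id", "run_id", "experiment_id", "study_id",
           "tissue_label", "treatment_label")
  list(expr = matrix_to_expr(collapsed),
       samples = new_meta[match(colnames(collapsed), new_meta$sample_id), ])
}

.label_col <- function(by = c("treatment", "tissue")) {
  switch(match.arg(by), treatment = "treatment_label", tissue = "tissue_label")
}

#' Per-gene, per-category mean expression
#'
#' Unweighted mean TPM of every gene within each treatment (or tissue)
#' category; zeros are included at this stage. The input should already be
#' collapsed to one column per experiment.
#'
#' @inheritParams validate_expression
#' @param by Grouping label: `"treatment"` or `"tissue"`.
#' @return A long tibble: `gene_id`, `group`, `mean_tpm`, `n_experiments`.
#' @export
group_means <- function(expr, samples, by = c("treatment", "tissue")) {
  col <- .label_col(by)
  meta <- samples[match(names(expr)[-1], samples$sample_id), ]
  m <- expr_to_matrix(expr)
  f <- factor(meta[[col]])
  means <- t(rowsum(t(m), f) / as.vector(table(f)))
  tibble(
    gene_id = rep(rownames(means), times = ncol(means)),
    group = rep(colnames(means), each = nrow(means)),
    mean_tpm = as.vector(means),
    n_experiments = rep(as.vector(table(f)), each = nrow(means))
  )
}

#' The tau expression-specificity index for one vector of category means
#'
#' `tau = sum_i (1 - x_i / max(x)) / (N - 1)`, where `x` holds a gene's mean
#' expression in each of `N` categories. Dividing by `N - 1` bounds tau in
#' `[0, 1]`: 0 for perfectly uniform expression, 1 for expression confined to
#' a single category. `NA` when the gene is unexpressed everywhere or fewer
#' than two categories are available.
#'
#' @param x Non-negative numeric vector of per-category means.
#' @return A single numeric value in `[0, 1]`, or `NA`.
#' @export
tau_index <- function(x) {
  if (length(x) < 2L || anyNA(x)) return(NA_real_)
  if (any(x < 0)) stop_format("negative category means")
  mx <- max(x)
  if (mx == 0) return(NA_real_)
  sum(1 - x / mx) / (length(x) - 1)
}

# row-wise tau over a gene x category matrix of means
.tau_rows <- function(means) {
  if (ncol(means) < 2L) return(rep(NA_real_, nrow(means)))
  mx <- means[cbind(seq_len(nrow(means)), max.col(means, ties.method = "first"))]
  tau <- rowSums(1 - means / mx) / (ncol(means) - 1)
  tau[mx == 0] <- NA_real_
  tau
}

#' Per-gene treatment (or tissue) specificity
#'
#' Computes [group_means()] and applies [tau_index()] per gene.
#'
#' @inheritParams group_means
#' @return A tibble: `gene_id`, `tau`, `n_groups`.
#' @export
tau_specificity <- function(expr, samples, by = c("treatment", "tissue")) {
  gm <- group_means(expr, samples, by = by)
  wide <- pivot_wider(gm[, c("gene_id", "group", "mean_tpm")],
                      names_from = "group", values_from = "mean_tpm")
  means <- as.matrix(wide[, -1, drop = FALSE])
  tibble(gene_id = wide$gene_id, tau = .tau_rows(means),
         n_groups = ncol(means))
}

#' Tissue specificity from control samples
#'
#' Applies the tau formula across tissue-category means after restricting the
#' matrix to one treatment condition (the control condition by default).
#'
#' @inheritParams group_means
#' @param condition Treatment label retained before grouping by tissue.
#' @return A tibble: `gene_id`, `tau_tissue`, `n_groups`.
#' @export
tissue_specificity <- function(expr, samples, condition = "control") {
  keep <- samples$sample_id[samples$treatment_label == condition]
  keep <- intersect(names(expr)[-1], keep)
  if (length(keep) == 0L) stop_format("no samples in the requested condition")
  sub <- expr[, c("gene_id", keep)]
  res <- tau_specificity(sub, samples, by = "tissue")
  if (res$n_groups[1] < 2L) res$tau <- NA_real_
  names(res)[names(res) == "tau"] <- "tau_tissue"
  res
}

#' Thresholded average expression
#'
#' Per gene, the mean over experiments whose value is at least
#' `threshold_tpm` (values below the threshold are excluded so that average
#' expression decouples from expression specificity); `NA` when no value
#' passes. The default threshold of 5 TPM also guards against alignment-error
#' artifacts.
#'
#' @inheritParams validate_expression
#' @param threshold_tpm Inclusion threshold; values `>= threshold_tpm` are
#'   kept (a threshold of 0 gives the plain mean).
#' @return A tibble: `gene_id`, `avg_expr`, `n_used`.
#' @export
average_expression <- function(expr, threshold_tpm = 5) {
  m <- expr_to_matrix(expr)
  pass <- m >= threshold_tpm
  n_used <- rowSums(pass)
  avg <- ifelse(n_used > 0, rowSums(m * pass) / n_used, NA_real_)
  tibble(gene_id = rownames(m), avg_expr = unname(avg), n_used = unname(n_used))
}
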