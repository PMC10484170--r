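# Partial Spearman correlations via the precision matrix of rank-scale
# correlations, and the per-target analysis-table assembly with the covariate
# sets and gene filters used for each selection measure.

.TARGETS <- c(dN = "d_n", piN = "pi_n", tajimaD = "tajima_d", DoS = "dos")

# abort naming a collinear pair among the ranked variables
.collinear_error <- function(rmat) {
  off <- abs(rmat - diag(diag(rmat)))
  ij <- which(off == max(off), arr.ind = TRUE)[1, ]
  stop_format(sprintf(
    "rank-scale correlation matrix is singular; most collinear pair: %s ~ %s",
    rownames(rmat)[ij[1]], colnames(rmat)[ij[2]]))
}

#' Partial Spearman correlation
#'
#' Rank-transforms `x`, `y` and the covariates (average ranks for ties),
#' forms their Pearson correlation matrix, and reads the partial correlation
#' off the precision matrix: `rho = -O_xy / sqrt(O_xx O_yy)`. The p-value
#' uses the t statistic `rho * sqrt((n - 2 - k) / (1 - rho^2))` on
#' `n - 2 - k` degrees of freedom, `k` the number of covariates. With no
#' covariates this reduces to the ordinary Spearman correlation. Rows with
#' any missing value are dropped (complete-case).
#'
#' @param data A data frame holding the variables.
#' @param x,y Variables of interest (bare names or strings).
#' @param covariates Covariate columns, as a tidyselect specification (e.g.
#'   `c(avg_expr, length_bp)`); empty for the ordinary Spearman correlation.
#' @return A one-row tibble: `var_x`, `var_y`, `covariates` (comma-separated),
#'   `rho`, `statistic`, `p_value`, `n`.
#' @export
spearman_partial <- function(data, x, y, covariates = NULL) {
  x <- as_name(ensym(x))
  y <- as_name(ensym(y))
  cov_idx <- eval_select(enquo(covariates), data)
  cov_names <- setdiff(names(cov_idx), c(x, y))
  vars <- c(x, y, cov_names)
  d <- data[, vars, drop = FALSE]
  d <- d[complete.cases(d), , drop = FALSE]
  n <- nrow(d)
  k <- length(cov_names)
  if (n <= k + 2) stop_format("need n > k + 2 complete cases")
  ranks <- vapply(d, rank_avg, numeric(n))
  rmat <- cor(ranks)
  omega <- tryCatch(solve(rmat), error = function(e) NULL)
  if (is.null(omega) || !all(is.finite(omega))) {
    # x and y perfectly rank-correlated: the partial correlation is their
    # shared sign; any other singularity means collinear covariates
    if (1 - abs(rmat[1, 2]) < 1e-12) {
      rho <- sign(rmat[1, 2])
      omega <- NULL
    } else {
      .collinear_error(rmat)
    }
  } else {
    rho <- -omega[1, 2] / sqrt(omega[1, 1] * omega[2, 2])
  }
  rho <- max(min(rho, 1), -1)
  df <- n - 2 - k
  stat <- rho * sqrt(df / max(1 - rho^2, .Machine$double.eps))
  p <- 2 * pt(-abs(stat), df)
  tibble(var_x = x, var_y = y,
         covariates = paste(cov_names, collapse = ","),
         rho = rho, statistic = stat, p_value = p, n = n)
}

#' All-pairs partial Spearman correlation matrix
#'
#' For every unordered pair of the selected variables, the partial Spearman
#' correlation controlling either for all remaining selected variables
#' (`control = "remaining"`, the heatmap convention) or for a fixed covariate
#' set (`control = "fixed"`).
#'
#' @param data A data frame.
#' @param variables Tidyselect specification of at least three variables.
#' @param control `"remaining"` or `"fixed"`.
#' @param covariates Fixed covariate columns (only with `control = "fixed"`).
#' @return A long tibble of class `pcor_matrix` with `var_x`, `var_y`, `rho`,
#'   `p_value`, `n` for every ordered pair (symmetric, unit diagonal).
#' @export
correlation_heatmap <- function(data, variables,
                                control = c("remaining", "fixed"),
                                covariates = NULL) {
  control <- match.arg(control)
  idx <- eval_select(enquo(variables), data)
  vars <- names(idx)
  if (length(vars) < 3L) stop_format("need at least three variables")
  fixed <- if (control == "fixed") names(eval_select(enquo(covariates), data))
           else NULL
  rows <- list()
  for (i in seq_along(vars)) {
    for (j in seq_along(vars)) {
      if (j <= i) next
      ctrl <- if (control == "remaining") setdiff(vars, vars[c(i, j)]) else fixed
      res <- spearman_partial(data, !!rlang::sym(vars[i]), !!rlang::sym(vars[j]),
                              covariates = all_of(ctrl))
      rows[[length(rows) + 1L]] <- res
    }
  }
  long <- list_rbind(rows)
  sym <- long |>
    rename(var_x = "var_y", var_y = "var_x")
  diag_rows <- tibble(var_x = vars, var_y = vars, covariates = "",
                      rho = 1, statistic = Inf, p_value = 0,
                      n = long$n[1] %||% NA_integer_)
  out <- bind_rows(long, sym[, names(long)], diag_rows) |>
    mutate(var_x = factor(.data$var_x, levels = vars),
           var_y = factor(.data$var_y, levels = vars)) |>
    arrange(.data$var_x, .data$var_y)
  class(out) <- c("pcor_matrix", class(out))
  out
}

#' Assemble the complete-case gene table for one selection measure
#'
#' Joins selection statistics to gene covariates and applies the per-target
#' rules: the covariate set is always average expression, gene length, GC
#' content and tissue specificity; family size is added for the
#' polymorphism-based targets (`piN`, `tajimaD`); divergence-based targets
#' (`dN`, `DoS`) are restricted to 1:1 orthologs (a `one_to_one` flag if
#' present, otherwise `family_size == 1`); saturated genes (`dS > 1`) are
#' dropped for `dN`. Rows with any missing value among the analysis variables
#' are excluded.
#'
#' @param stats Per-gene selection statistics (needs `gene_id`,
#'   `tau_treatment` and the target column; `saturated` for `dN`).
#' @param covariates Per-gene covariates (`gene_id`, `avg_expr`, `length_bp`,
#'   `gc_fraction`, `family_size`, `tau_tissue`, optional `one_to_one`).
#' @param target One of `"dN"`, `"piN"`, `"tajimaD"`, `"DoS"`.
#' @return The filtered tibble, with attributes `target_col` and
#'   `covariate_set`; `nrow()` is the analysis n.
#' @export
build_analysis_table <- function(stats, covariates, target) {
  if (!target %in% names(.TARGETS)) {
    stop_format(sprintf("unknown target '%s' (use %s)", target,
                        paste(names(.TARGETS), collapse = ", ")))
  }
  target_col <- .TARGETS[[target]]
  tab <- left_join(stats, covariates, by = "gene_id")
  cov_set <- c("avg_expr", "length_bp", "gc_fraction", "tau_tissue")
  if (target %in% c("piN", "tajimaD")) cov_set <- c(cov_set, "family_size")
  if (target %in% c("dN", "DoS")) {
    tab <- if ("one_to_one" %in% names(tab)) {
      filter(tab, .data$one_to_one)
    } else {
      filter(tab, .data$family_size == 1)
    }
  }
  if (target == "dN" && "saturated" %in% names(tab)) {
    tab <- filter(tab, !is.na(.data$saturated) & !.data$saturated)
  }
  need <- c("tau_treatment", target_col, cov_set)
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop_format(paste0("missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  tab <- tab[complete.cases(tab[, need]), , drop = FALSE]
  attr(tab, "target_col") <- target_col
  attr(tab, "covariate_set") <- cov_set
  tab
}

#' Partial correlation between treatment specificity and a selection measure
#'
#' Builds the per-target analysis table and computes the partial Spearman
#' correlation between `tau_treatment` and the target, controlling for the
#' target's covariate set.
#'
#' @inheritParams build_analysis_table
#' @return A one-row tibble as from [spearman_partial()].
#' @export
target_partial_correlation <- function(stats, covariates, target) {
  tab <- build_analysis_table(stats, covariates, target)
  spearman_partial(tab, tau_treatment, !!rlang::sym(attr(tab, "target_col")),
                   covariates = all_of(attr(tab, "covariate_set")))
}
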