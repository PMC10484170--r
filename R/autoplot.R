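# ggplot2 views of the main result types

#' Heatmap of a partial-correlation matrix
#'
#' @param object A `pcor_matrix` from [correlation_heatmap()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pcor_matrix <- function(object, ...) {
  ggplot(object, aes(x = .data$var_x, y = .data$var_y, fill = .data$rho)) +
    geom_tile() +
    geom_text(aes(label = sprintf("%.2f", .data$rho)), size = 3) +
    scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b",
                         limits = c(-1, 1)) +
    labs(x = NULL, y = NULL, fill = "partial rho") +
    theme_minimal()
}

#' Correlation distributions from the ZINB experiment
#'
#' Densities of the per-matrix Spearman correlations between tau and average
#' expression, including vs excluding zero expression values.
#'
#' @param object A `zinb_experiment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.zinb_experiment <- function(object, ...) {
  long <- tidy(object) |>
    pivot_longer(c("cor_including", "cor_excluding"),
                 names_to = "average", values_to = "rho") |>
    mutate(average = ifelse(.data$average == "cor_including",
                            "including zeros", "excluding zeros"))
  ggplot(long, aes(x = .data$rho, fill = .data$average)) +
    geom_density(alpha = 0.5) +
    geom_vline(xintercept = 0, linetype = 2) +
    labs(x = "Spearman correlation of tau with average expression",
         y = "density", fill = NULL) +
    theme_minimal()
}

#' Singular-value variance shares of a surrogate-variable fit
#'
#' @param object An `sva_fit`.
#' @param n_components How many leading components to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sva_fit <- function(object, n_components = 10, ...) {
  d <- tidy(object, "variance") |>
    filter(.data$component <= n_components)
  ggplot(d, aes(x = factor(.data$component), y = .data$variance_share,
                fill = .data$selected)) +
    geom_col() +
    labs(x = "residual singular component", y = "variance share",
         fill = "retained") +
    theme_minimal()
}
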