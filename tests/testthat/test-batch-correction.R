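# surrogate-variable estimation and removal

test_that("treatment design fit is exact and additive", {
  sim <- simulate_expression_study(n_genes = 50, noise_sd = 0, batch_sd = 0,
                                   seed = 31)
  fit <- fit_treatment_design(sim$expr, sim$samples)
  # no noise, no batch: residuals vanish
  expect_lt(max(abs(fit$residuals)), 1e-10)
  # fitted + residuals reconstructs the transformed matrix exactly
  noisy <- simulate_expression_study(n_genes = 50, noise_sd = 0.5,
                                     batch_sd = 0.5, seed = 32)
  f2 <- fit_treatment_design(noisy$expr, noisy$samples)
  expect_equal(f2$fitted + f2$residuals, f2$y, tolerance = 1e-12)
  # one gene, two categories with means 2 and 4 -> deviations -1, +1
  samples <- tibble::tibble(sample_id = paste0("e", 1:4),
                            run_id = paste0("e", 1:4),
                            experiment_id = paste0("e", 1:4),
                            study_id = "s1", tissue_label = "leaf",
                            treatment_label = c("a", "a", "b", "b"))
  expr <- dplyr::bind_cols(tibble::tibble(gene_id = "g1"),
                           tibble::as_tibble(as.data.frame(
                             matrix(c(2, 2, 4, 4), nrow = 1,
                                    dimnames = list(NULL, samples$sample_id)))))
  f3 <- fit_treatment_design(expr, samples, transform = FALSE)
  dev <- f3$fitted[1, ] - mean(f3$y[1, ])
  expect_equal(unname(dev), c(-1, -1, 1, 1))
  # category present in labels but absent in the matrix
  expect_error(fit_treatment_design(expr, samples[1:3, ]),
               class = "specsel_format_error")
})

test_that("k = 0 makes removal the identity; surrogates are orthonormal", {
  sim <- simulate_expression_study(n_genes = 100, batch_sd = 1, seed = 33)
  fit <- fit_treatment_design(sim$expr, sim$samples)
  m0 <- estimate_surrogates(fit, k = 0, seed = 34)
  expect_equal(remove_surrogates(sim$expr, m0), sim$expr, tolerance = 1e-10)
  m2 <- estimate_surrogates(fit, k = 2, seed = 34)
  expect_equal(t(m2$surrogates) %*% m2$surrogates, diag(2), tolerance = 1e-10)
  expect_error(estimate_surrogates(fit, k = 50),
               class = "specsel_format_error")
})

test_that("a directly supplied planted batch term is removed exactly", {
  withr::with_seed(35, {
    n_g <- 80
    samples <- tibble::tibble(
      sample_id = paste0("e", 1:12), run_id = paste0("e", 1:12),
      experiment_id = paste0("e", 1:12), study_id = "s1",
      tissue_label = "leaf",
      treatment_label = rep(c("a", "b", "c"), each = 4)
    )
    clean_y <- matrix(rnorm(n_g * 12, mean = 6), nrow = n_g,
                      dimnames = list(paste0("g", 1:n_g), samples$sample_id))
    h <- qr.Q(qr(matrix(rnorm(12), ncol = 1)))
    lam <- matrix(rnorm(n_g), ncol = 1)
    y <- clean_y + lam %*% t(h)
    expr <- dplyr::bind_cols(
      tibble::tibble(gene_id = rownames(y)),
      tibble::as_tibble(as.data.frame(y)))
    fit <- fit_treatment_design(expr, samples, transform = FALSE)
    model <- structure(list(surrogates = h, loadings = lam, k = 1L,
                            variance_share = NA, p_values = NA,
                            groups = fit$groups, transform = FALSE,
                            sample_ids = fit$sample_ids,
                            gene_ids = fit$gene_ids, B = 0, alpha = 0.05),
                       class = "sva_fit")
    corrected <- remove_surrogates(expr, model)
    got <- as.matrix(corrected[, -1])
    expect_lt(max(abs(got - clean_y)), 1e-8)
  })
})

test_that("corrected residuals are orthogonal to the surrogates", {
  sim <- simulate_expression_study(n_genes = 200, batch_sd = 1, noise_sd = 0.3,
                                   seed = 36)
  fit <- fit_treatment_design(sim$expr, sim$samples)
  model <- estimate_surrogates(fit, k = 1, seed = 37)
  corrected <- remove_surrogates(sim$expr, model)
  cfit <- fit_treatment_design(corrected, sim$samples)
  ortho <- cfit$residuals %*% model$surrogates
  expect_lt(max(abs(ortho)) / sqrt(nrow(ortho)), 1e-6)
})

test_that("re-estimating surrogates after correction finds none", {
  k_after <- vapply(1:10, function(i) {
    sim <- simulate_expression_study(n_genes = 400, batch_sd = 1.5,
                                     noise_sd = 0.3, seed = 40 + i)
    sv <- sva_correct(sim$expr, sim$samples, seed = 60 + i)
    refit <- fit_treatment_design(sv$expr, sim$samples)
    estimate_surrogates(refit, B = 100, seed = 80 + i)$k
  }, integer(1))
  expect_gte(mean(k_after == 0), 0.9)
})

test_that("the leading surrogate agrees with svaseq on planted batch data", {
  skip_if_not_installed("sva")
  sim <- simulate_expression_study(n_genes = 500, batch_sd = 1.5,
                                   noise_sd = 0.3, seed = 51)
  fit <- fit_treatment_design(sim$expr, sim$samples)
  model <- estimate_surrogates(fit, seed = 52)
  expect_gte(model$k, 1L)
  m <- as.matrix(sim$expr[, -1])
  mod <- stats::model.matrix(~ sim$samples$treatment_label)
  mod0 <- stats::model.matrix(~ 1, data = sim$samples)
  ref <- suppressMessages(sva::svaseq(m, mod, mod0, n.sv = 1))
  expect_gt(abs(stats::cor(model$surrogates[, 1], ref$sv[, 1])), 0.9)
  expect_gt(abs(stats::cor(model$surrogates[, 1], sim$batch$batch_score)), 0.9)
})
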