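# synthetic-data generators: distributional moments, determinism, planted
# structure, and compatibility with the validators

test_that("ZINB draws match their closed-form moments", {
  m <- simulate_zinb_matrix(n_genes = 40000, seed = 71)
  x <- as.vector(m)
  n <- length(x)
  # zero mass: (1 - p2) + p2 * p^size; the NB term is numerically 0 here
  zero_target <- 0.6 + 0.4 * 0.1^100
  se_zero <- sqrt(zero_target * (1 - zero_target) / n)
  expect_lt(abs(mean(x == 0) - zero_target), 3 * se_zero)
  # mean of the non-zero component: size (1 - p) / p
  nb <- x[x > 0]
  nb_mean <- 100 * 0.9 / 0.1
  expect_lt(abs(mean(nb) - nb_mean), 3 * sd(nb) / sqrt(length(nb)))
  # degenerate inflation
  expect_true(all(simulate_zinb_matrix(n_genes = 100, prob_nonzero = 0,
                                       seed = 1) == 0))
})

test_that("generators are bit-reproducible and shapes are as declared", {
  a <- simulate_zinb_matrix(n_genes = 200, seed = 72)
  b <- simulate_zinb_matrix(n_genes = 200, seed = 72)
  expect_identical(a, b)
  expect_equal(dim(a), c(200L, 25L))
  expect_equal(table(attr(a, "groups")), table(rep(paste0("g", 1:5), 5)))
  e1 <- zinb_specificity_experiment(n_matrices = 5, n_genes = 100, seed = 73)
  e2 <- zinb_specificity_experiment(n_matrices = 5, n_genes = 100, seed = 73)
  expect_identical(e1$correlations, e2$correlations)
  expect_equal(nrow(e1$correlations), 5L)
  g1 <- simulate_genotypes(n_genes = 20, seed = 74)
  g2 <- simulate_genotypes(n_genes = 20, seed = 74)
  expect_identical(g1, g2)
  c1 <- simulate_codon_pair_set(n_genes = 5, n_codons = 50, seed = 75)
  c2 <- simulate_codon_pair_set(n_genes = 5, n_codons = 50, seed = 75)
  expect_identical(c1, c2)
  s1 <- simulate_expression_study(n_genes = 30, seed = 76)
  s2 <- simulate_expression_study(n_genes = 30, seed = 76)
  expect_identical(s1, s2)
})

test_that("generated data pass the package validators unmodified", {
  g <- simulate_genotypes(n_genes = 10, seed = 77)
  expect_true(validate_sites(g$sites))
  s <- simulate_expression_study(n_genes = 20, seed = 78)
  expect_true(validate_expression(s$expr, s$samples))
  j <- simulate_joined_study(n_genes = 50, n_nonsyn_sites = 100,
                             n_syn_sites = 50, n_codons = 30, seed = 79)
  expect_true(validate_expression(j$expr, j$samples))
  expect_true(validate_sites(j$sites))
})

test_that("genotype generator plants the requested diversity structure", {
  none <- simulate_genotypes(n_genes = 30, theta_n = 0, theta_s = 0.01,
                             seed = 80)
  expect_equal(sum(none$sites$site_class == "missense"), 0L)
  # per-site n reflects missingness
  g <- simulate_genotypes(n_genes = 50, n_ind = 20, missing_rate = 0.25,
                          seed = 81)
  expect_lt(mean(g$sites$n_chromosomes[g$sites$weight == 1]), 2 * 20 * 0.8)
  expect_true(all(g$sites$n_chromosomes <= 40))
})

test_that("codon-pair generator plants divergence and flags saturation", {
  ident <- simulate_codon_pair_set(n_genes = 10, n_codons = 60, d_n = 0,
                                   d_s = 0, seed = 82)
  expect_identical(ident$pairs$seq_a, ident$pairs$seq_b)
  expect_error(simulate_codon_pair_set(n_genes = 2, n_codons = 20, d_n = 50,
                                       d_s = 50, seed = 83),
               class = "specsel_format_error")
})

test_that("expression-study generator controls true specificity", {
  flat <- simulate_expression_study(n_genes = 300, specificity = 0,
                                    noise_sd = 0.1, seed = 84)
  tau_hat <- tau_specificity(flat$expr, flat$samples)$tau
  expect_lt(stats::quantile(tau_hat, 0.95, na.rm = TRUE), 0.15)
  varied <- simulate_expression_study(n_genes = 2000, noise_sd = 0.25,
                                      seed = 85)
  tau_hat <- tau_specificity(varied$expr, varied$samples)$tau
  expect_gt(cor(tau_hat, varied$truth$tau_true, method = "spearman",
                use = "complete.obs"), 0.8)
  expect_error(simulate_expression_study(n_studies = 1, batch_sd = 1,
                                         seed = 1),
               class = "specsel_format_error")
})

test_that("joined-study truth serializes and targets validate", {
  j <- simulate_joined_study(n_genes = 40, n_nonsyn_sites = 80,
                             n_syn_sites = 40, n_codons = 0, seed = 86)
  tp <- withr::local_tempfile(fileext = ".tsv")
  write_gene_table(j$truth, tp)
  back <- read_gene_table(tp)
  plain_truth <- j$truth
  attr(plain_truth, "partial_targets") <- NULL
  expect_equal(back, plain_truth, tolerance = 1e-9)
  # the planted structure itself rides along on the truth object
  expect_equal(unname(attr(j$truth, "partial_targets")),
               unname(default_partial_targets()))
  # three mutual partial correlations of +0.9 cannot coexist
  bad <- diag(5)
  bad[1, 2] <- bad[2, 1] <- 0.9
  bad[1, 3] <- bad[3, 1] <- 0.9
  bad[2, 3] <- bad[3, 2] <- 0.9
  expect_error(simulate_joined_study(n_genes = 10, partial_targets = bad,
                                     seed = 1),
               class = "specsel_format_error")
})

test_that("the ZINB experiment reports both correlation distributions", {
  e <- zinb_specificity_experiment(n_matrices = 20, n_genes = 200, seed = 87)
  expect_named(e$correlations, c("matrix", "cor_including", "cor_excluding"))
  expect_equal(nrow(e$correlations), 20L)
  g <- glance(e)
  expect_lt(g$mean_cor_including, 0)
  expect_lt(abs(g$mean_cor_excluding), abs(g$mean_cor_including))
})
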