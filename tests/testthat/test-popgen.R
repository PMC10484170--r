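# per-site diversity statistics, gene-level Tajima's D, pixy-style pi, DoS

test_that("site-level statistics match closed forms", {
  expect_equal(site_pi(2, 0.5), 1.0)
  expect_equal(site_pi(10, 0.1), 0.2)
  expect_equal(site_pi(4, 0), 0)
  expect_true(is.na(site_pi(1, 0.5)))
  expect_equal(harmonic_number(2), 1)
  expect_equal(harmonic_number(4), 11 / 6)
  expect_error(harmonic_number(1), class = "specsel_format_error")
  expect_equal(site_theta_w(2), 1)
  expect_equal(site_theta_w(4), 6 / 11)
  # consistency at n = 2: balanced site pi equals thetaW
  expect_equal(site_pi(2, 0.5), site_theta_w(2))
  expect_equal(site_d_variance(4), (5 / 9 - 6 / 11) / (11 / 6))
  expect_true(all(site_d_variance(4:2000) > 0))
  expect_true(is.na(site_d_variance(3)))
  # harmonic numbers against high-precision cumulative sums
  expect_equal(harmonic_number(100), sum(1 / (1:99)), tolerance = 1e-12)
})

test_that("per-site D has the expected sign structure", {
  # singleton: pi below thetaW, D negative
  expect_lt(site_d(10, 1 / 10), 0)
  # balanced intermediate frequency: D positive
  expect_gt(site_d(10, 0.5), 0)
})

test_that("gene Tajima's D equals the textbook statistic for one segregating site", {
  for (n in c(4, 7, 10, 25, 60, 100)) {
    for (c_alt in c(1, n %/% 2, n - 1)) {
      s <- tibble::tibble(gene_id = "g", site_class = "missense",
                          n_chromosomes = as.integer(n),
                          n_alt = as.integer(c_alt))
      expect_equal(gene_tajima_d(s)$tajima_d, oracle_tajima_d(n, c_alt),
                   tolerance = 1e-12)
    }
  }
})

test_that("gene Tajima's D averages per-site values and handles edge cases", {
  # the gene value is the unweighted mean of the per-site values
  s <- tibble::tibble(gene_id = "g", site_class = "missense",
                      n_chromosomes = 10L, n_alt = c(1L, 5L, 9L))
  expect_equal(gene_tajima_d(s)$tajima_d,
               mean(site_d(10, c(1, 5, 9) / 10)), tolerance = 1e-12)
  # a single variant site gives exactly that site's d
  expect_equal(gene_tajima_d(s[2, ])$tajima_d, site_d(10, 0.5))
  # no variant sites -> NA
  inv <- tibble::tibble(gene_id = "g", site_class = "invariant",
                        n_chromosomes = 10L, n_alt = 0L)
  expect_true(is.na(gene_tajima_d(inv)$tajima_d))
  # sites with n < 4 are excluded, not propagated as values
  mix <- tibble::tibble(gene_id = "g", site_class = "missense",
                        n_chromosomes = c(2L, 10L), n_alt = c(1L, 5L))
  out <- gene_tajima_d(mix)
  expect_equal(out$n_sites_excluded, 1L)
  expect_equal(out$tajima_d, site_d(10, 0.5))
  # monotonicity: adding a site with d above the mean raises the average
  base <- tibble::tibble(gene_id = "g", site_class = "missense",
                         n_chromosomes = 20L, n_alt = c(1L, 2L))
  more <- dplyr::bind_rows(base, tibble::tibble(gene_id = "g",
                                                site_class = "missense",
                                                n_chromosomes = 20L,
                                                n_alt = 10L))
  expect_gt(gene_tajima_d(more)$tajima_d, gene_tajima_d(base)$tajima_d)
})

test_that("gene_pi reproduces the hand-counted example and basic identities", {
  s <- tibble::tibble(gene_id = "g",
                      site_class = c("missense", rep("invariant", 9)),
                      n_chromosomes = 4L, n_alt = c(2L, rep(0L, 9)))
  expect_equal(gene_pi(s, class_filter = "missense", denominator_sites = 10),
               1 / 15)
  # all invariant -> 0
  inv <- tibble::tibble(gene_id = "g", site_class = "invariant",
                        n_chromosomes = 8L, n_alt = 0L)[rep(1, 5), ]
  expect_equal(gene_pi(inv, denominator_sites = 5), 0)
  expect_true(is.na(gene_pi(s, class_filter = "missense",
                            denominator_sites = 0)))
  # invariant to site order and to splitting/recombining the sums
  withr::with_seed(5, {
    big <- tibble::tibble(gene_id = "g",
                          site_class = sample(c("missense", "invariant"), 60,
                                              replace = TRUE),
                          n_chromosomes = sample(c(8L, 10L), 60, replace = TRUE))
    big$n_alt <- ifelse(big$site_class == "invariant", 0L,
                        sample(1:7, 60, replace = TRUE))
    shuffled <- big[sample(nrow(big)), ]
    expect_equal(gene_pi(big, denominator_sites = 60),
                 gene_pi(shuffled, denominator_sites = 60))
    # weighted invariant representation agrees with expanded rows
    ex <- dplyr::count(big, .data$site_class, .data$n_chromosomes, .data$n_alt,
                       name = "weight")
    ex$gene_id <- "g"
    expect_equal(gene_pi(ex, denominator_sites = 60),
                 gene_pi(big, denominator_sites = 60))
  })
})

test_that("polymorphism counts and DoS follow their definitions", {
  s <- tibble::tibble(
    gene_id = "g",
    site_class = c("missense", "missense", "missense", "synonymous",
                   "synonymous", "invariant", "other"),
    n_chromosomes = 10L,
    n_alt = c(1L, 5L, 9L, 2L, 3L, 0L, 4L)
  )
  pc <- count_polymorphisms(s)
  expect_equal(pc$p_n_count, 3L)
  expect_equal(pc$p_s_count, 2L)
  expect_equal(direction_of_selection(1, 1, 1, 1), 0)
  expect_equal(direction_of_selection(2, 0, 0, 2), 1)
  expect_equal(direction_of_selection(3, 1, 1, 3), 0.5)
  expect_true(is.na(direction_of_selection(0, 0, 1, 1)))
  expect_true(is.na(direction_of_selection(1, 1, 0, 0)))
})

test_that("neutral simulated genes have pi/thetaW near 1 and DoS centred on 0", {
  # neutral divergence first: its N:S ratio fixes the polymorphism site split
  # so that nonsynonymous and synonymous opportunity match between the two
  sim <- simulate_codon_pair_set(n_genes = 300, n_codons = 200, d_n = 0.08,
                                 d_s = 0.08, seed = 22)
  est <- pairwise_dnds(sim$pairs)
  frac_n <- mean(est$n_sites) / mean(est$n_sites + est$s_sites)
  l_n <- round(1200 * frac_n)
  g <- simulate_genotypes(n_genes = 300, n_ind = 20, n_nonsyn_sites = l_n,
                          n_syn_sites = 1200 - l_n, theta_n = 0.008,
                          theta_s = 0.008, missing_rate = 0.1, seed = 21)
  div <- gene_diversity(g$sites, g$site_counts)
  # E(pi) = theta for every class under neutrality
  expect_lt(abs(mean(div$pi_s) / 0.008 - 1), 0.05)
  expect_lt(abs(mean(div$pi_n) / 0.008 - 1), 0.05)
  stats <- gene_selection_stats(g$sites, g$site_counts, est)
  dos <- stats$dos[!is.na(stats$dos)]
  expect_gt(length(dos), 100)
  expect_lt(abs(mean(dos)), 3 * sd(dos) / sqrt(length(dos)) + 0.02)
})
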