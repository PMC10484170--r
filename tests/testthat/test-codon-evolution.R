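# Nei-Gojobori site counting, pathway-averaged differences, and the
# pairwise divergence estimator

test_that("per-codon site counts match hand-derived values and conserve 3", {
  tt <- codon_site_counts("TTT")
  expect_equal(unname(tt["n_sites"]), 8 / 3)
  expect_equal(unname(tt["s_sites"]), 1 / 3)
  atg <- codon_site_counts("ATG")
  expect_equal(unname(atg["s_sites"]), 0)
  expect_equal(unname(atg["n_sites"]), 3)
  for (cod in SENSE_CODONS) {
    cs <- codon_site_counts(cod)
    expect_equal(unname(sum(cs)), 3, tolerance = 1e-12)
  }
  expect_error(codon_site_counts("TAA"), class = "specsel_format_error")
  expect_error(codon_site_counts("TNT"), class = "specsel_format_error")
})

test_that("stop-exclusion convention removes stop mutants from the denominator", {
  # TAT (Tyr): two of the three third-position mutants are stops, the third
  # is synonymous, so excluding stops turns a 1/3 synonymous fraction into 1
  default <- codon_site_counts("TAT")
  excl <- codon_site_counts("TAT", stop_handling = "excluded")
  expect_equal(unname(default["s_sites"]), 1 / 3)
  expect_equal(unname(excl["s_sites"]), 1)
  expect_equal(unname(sum(default)), 3)
  expect_equal(unname(sum(excl)), 3)
})

test_that("sequence site counts sum per-codon values and drop bad codons", {
  res <- count_sequence_sites("TTTTTT")
  expect_equal(res$n_sites, 16 / 3)
  expect_equal(res$s_sites, 2 / 3)
  expect_equal(count_sequence_sites("")$n_sites, 0)
  expect_error(count_sequence_sites("TTTT"), class = "specsel_format_error")
  withr::with_seed(7, {
    for (rep in 1:5) {
      seq <- paste(sample(SENSE_CODONS, 100, replace = TRUE), collapse = "")
      got <- count_sequence_sites(seq)
      want <- rowSums(vapply(substring(seq, seq(1, 298, 3), seq(3, 300, 3)),
                             oracle_site_counts, numeric(2)))
      expect_equal(got$n_sites, unname(want["n"]), tolerance = 1e-9)
      expect_equal(got$s_sites, unname(want["s"]), tolerance = 1e-9)
      expect_equal(got$n_sites + got$s_sites, 3 * got$codons_counted,
                   tolerance = 1e-9)
    }
  })
  # codons with N or stops are excluded but counted as skipped
  withN <- count_sequence_sites("TTTNTTTAA")
  expect_equal(withN$codons_counted, 1L)
  expect_equal(withN$codons_skipped, 2L)
})

test_that("pathway-averaged differences match the exhaustive enumerator", {
  expect_equal(codon_pair_differences("TTT", "TTT")[c("nd", "sd")],
               list(nd = 0, sd = 0))
  expect_equal(codon_pair_differences("TTT", "GTT")$nd, 1)
  d <- codon_pair_differences("TTT", "GTA")
  expect_equal(d$nd, 1.5)
  expect_equal(d$sd, 0.5)
  withr::with_seed(11, {
    picks <- cbind(sample(SENSE_CODONS, 250, replace = TRUE),
                   sample(SENSE_CODONS, 250, replace = TRUE))
    for (i in seq_len(nrow(picks))) {
      got <- codon_pair_differences(picks[i, 1], picks[i, 2])
      want <- oracle_pair_diffs(picks[i, 1], picks[i, 2])
      expect_equal(got$nd, unname(want["nd"]), tolerance = 1e-12)
      expect_equal(got$sd, unname(want["sd"]), tolerance = 1e-12)
      k <- sum(strsplit(picks[i, 1], "")[[1]] != strsplit(picks[i, 2], "")[[1]])
      if (!got$stop_fallback) expect_equal(got$nd + got$sd, k)
    }
  })
})

test_that("jukes_cantor matches the closed form and flags saturation", {
  expect_equal(jukes_cantor(0), 0)
  expect_equal(jukes_cantor(0.5), -0.75 * log(1 / 3))
  expect_true(is.na(jukes_cantor(0.75)))
  expect_true(is.na(jukes_cantor(0.9)))
  p <- seq(0, 0.7, by = 0.01)
  expect_true(all(diff(jukes_cantor(p)) > 0)) # monotone increasing
})

test_that("pairwise_dnds handles identity, symmetry, saturation and N-codons", {
  seq <- paste(rep("TTTGCTAAAGGT", 25), collapse = "")
  ident <- pairwise_dnds(tibble::tibble(gene_id = "g", seq_a = seq, seq_b = seq))
  expect_equal(ident$d_n, 0)
  expect_equal(ident$d_s, 0)
  expect_false(ident$saturated)
  expect_true(is.na(ident$dnds)) # d_s = 0 gives no ratio

  sim <- simulate_codon_pair_set(n_genes = 5, n_codons = 80, d_n = 0.1,
                                 d_s = 0.2, seed = 3)
  ab <- pairwise_dnds(sim$pairs)
  ba <- pairwise_dnds(dplyr::rename(sim$pairs, seq_a = seq_b, seq_b = seq_a))
  expect_equal(ab$d_n, ba$d_n)
  expect_equal(ab$d_s, ba$d_s)
  expect_equal(ab$n_sites, ba$n_sites)

  # a pair with N-containing codons drops them from both sequences
  pn <- pairwise_dnds(tibble::tibble(gene_id = "g",
                                     seq_a = "TTTNTTGCT", seq_b = "TTCTTTGCT"))
  expect_equal(pn$codons_used, 2L)
  expect_equal(pn$codons_skipped, 1L)

  # heavy synonymous divergence saturates
  sat <- simulate_codon_pair_set(n_genes = 30, n_codons = 200, d_n = 0.05,
                                 d_s = 1.2, seed = 5)
  est <- pairwise_dnds(sat$pairs)
  expect_gt(mean(est$saturated), 0.5)
})
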