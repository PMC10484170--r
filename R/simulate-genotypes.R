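# Genotype simulation with planted per-gene diversity: segregating-site
# counts follow the neutral expectation theta * L * a_n, allele frequencies
# the neutral site-frequency spectrum P(count = i) proportional to 1/i, and
# missing genotype calls remove whole diploid individuals (allele counts are
# then hypergeometric subsamples, which preserves the expectation of pi).

#' Simulate genotyped coding sites with planted diversity
#'
#' Generates, per gene, nonsynonymous (`missense`) and synonymous segregating
#' sites plus the invariant remainder of the genotyped sequence. Segregating
#' counts are Poisson with mean `theta * L * a_n` per class; derived-allele
#' counts are drawn from the neutral SFS on the full panel and thinned by
#' individual-level missingness. Invariant sites are returned as weighted
#' rows grouped by their non-missing chromosome count, which keeps the output
#' compact without changing any diversity statistic.
#'
#' @param n_genes Number of genes.
#' @param n_ind Diploid individuals in the panel.
#' @param n_nonsyn_sites,n_syn_sites Genotyped sites per class per gene
#'   (these also serve as the Nei-Gojobori N and S denominators in `site_counts`).
#' @param theta_n,theta_s Per-site diversity parameters (scalar or per-gene
#'   vectors).
#' @param missing_rate Probability that an individual's genotype call is
#'   missing at a site.
#' @param seed Integer seed.
#' @return A list: `sites` (tibble with `gene_id`, `site_class`,
#'   `n_chromosomes`, `n_alt`, `p_ref`, `p_alt`, `weight`), `site_counts`
#'   (`gene_id`, `n_sites`, `s_sites`), and `truth` (`gene_id`, `theta_n`,
#'   `theta_s`).
#' @export
simulate_genotypes <- function(n_genes = 500, n_ind = 25,
                               n_nonsyn_sites = 1500, n_syn_sites = 500,
                               theta_n = 0.002, theta_s = 0.01,
                               missing_rate = 0.1, seed = 1L) {
  theta_n <- rep_len(theta_n, n_genes)
  theta_s <- rep_len(theta_s, n_genes)
  n_chr <- 2L * n_ind
  a_n <- harmonic_number(n_chr)
  gene_ids <- sprintf("gene%05d", seq_len(n_genes))
  with_seed(as.integer(seed), {
    seg <- .draw_segregating(gene_ids, n_nonsyn_sites, theta_n, "missense",
                             n_ind, missing_rate, a_n)
    seg2 <- .draw_segregating(gene_ids, n_syn_sites, theta_s, "synonymous",
                              n_ind, missing_rate, a_n)
    seg <- bind_rows(seg, seg2)
    # invariant remainder per gene, grouped by non-missing chromosome count
    k_per_gene <- tibble(gene_id = seg$gene_id) |> count(.data$gene_id)
    k <- setNames(rep(0L, n_genes), gene_ids)
    k[k_per_gene$gene_id] <- k_per_gene$n
    l_inv <- pmax((n_nonsyn_sites + n_syn_sites) - as.vector(k), 0L)
    probs <- dbinom(0:n_ind, n_ind, 1 - missing_rate)
    inv_rows <- map(seq_len(n_genes), function(g) {
      if (l_inv[g] == 0L) return(NULL)
      cnt <- as.vector(rmultinom(1, l_inv[g], probs))
      m_ok <- which(cnt > 0 & (0:n_ind) >= 1)
      tibble(gene_id = gene_ids[g], site_class = "invariant",
             n_chromosomes = 2L * (m_ok - 1L), n_alt = 0L,
             weight = cnt[m_ok])
    }) |> list_rbind()
    sites <- bind_rows(seg, inv_rows) |>
      mutate(p_alt = .data$n_alt / .data$n_chromosomes,
             p_ref = 1 - .data$p_alt) |>
      arrange(.data$gene_id)
  })
  list(
    sites = sites,
    site_counts = tibble(gene_id = gene_ids, n_sites = n_nonsyn_sites,
                         s_sites = n_syn_sites),
    truth = tibble(gene_id = gene_ids, theta_n = theta_n, theta_s = theta_s)
  )
}

# draw all segregating sites of one class across genes (vectorized)
.draw_segregating <- function(gene_ids, l_sites, theta, class, n_ind,
                              missing_rate, a_n) {
  n_chr <- 2L * n_ind
  k <- rpois(length(gene_ids), theta * l_sites * a_n)
  k <- pmin(k, l_sites)
  total <- sum(k)
  if (total == 0L) {
    return(tibble(gene_id = character(0), site_class = character(0),
                  n_chromosomes = integer(0), n_alt = integer(0),
                  weight = numeric(0)))
  }
  sfs <- (1 / seq_len(n_chr - 1L))
  i_derived <- sample.int(n_chr - 1L, total, replace = TRUE, prob = sfs)
  m_ind <- rbinom(total, n_ind, 1 - missing_rate)
  n_obs <- 2L * m_ind
  c_obs <- rhyper(total, i_derived, n_chr - i_derived, n_obs)
  keep <- n_obs >= 2L
  # sites monomorphic after thinning are invariant; fixed-derived sites are
  # relabelled to the reference (allele labels are arbitrary, differences 0)
  mono <- c_obs == 0L | c_obs == n_obs
  cls <- ifelse(mono, "invariant", class)
  c_obs[mono] <- 0L
  tibble(gene_id = rep(gene_ids, k)[keep],
         site_class = cls[keep],
         n_chromosomes = n_obs[keep], n_alt = c_obs[keep],
         weight = 1) |>
    arrange(.data$gene_id)
}
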