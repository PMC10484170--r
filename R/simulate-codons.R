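# Codon-pair simulation with planted divergence. Planted dN/dS are
# Jukes-Cantor-inverted to target difference proportions; Poisson numbers of
# single-base substitutions are then placed at most once per codon along the
# two lineages, so the pathway counter recovers the event counts exactly. The
# event intensity is calibrated against the expected Nei-Gojobori site counts
# of the *pair* (substituted codons shift the fractional site counts slightly
# away from the ancestor's), making the planted rate the estimand of
# pairwise_dnds() rather than a nearby quantity.

.neighbor_tables <- function() {
  if (is.null(.codon_env$syn_nbr)) {
    cd <- .codon_data()
    tab <- .site_count_table("nonsynonymous")
    syn_nbr <- nonsyn_nbr <- vector("list", 64)
    dn_syn <- ds_syn <- dn_non <- ds_non <- rep(NA_real_, 64)
    for (i in which(cd$sense)) {
      nb <- match(.codon_mutants(cd$codons[i])$codon, cd$codons)
      nb <- nb[cd$sense[nb]]
      syn <- nb[cd$aa[nb] == cd$aa[i]]
      non <- nb[cd$aa[nb] != cd$aa[i]]
      syn_nbr[[i]] <- syn
      nonsyn_nbr[[i]] <- non
      if (length(syn)) {
        dn_syn[i] <- mean(tab$n[syn] - tab$n[i])
        ds_syn[i] <- mean(tab$s[syn] - tab$s[i])
      }
      dn_non[i] <- mean(tab$n[non] - tab$n[i])
      ds_non[i] <- mean(tab$s[non] - tab$s[i])
    }
    .codon_env$syn_nbr <- syn_nbr
    .codon_env$nonsyn_nbr <- nonsyn_nbr
    .codon_env$delta <- list(dn_syn = dn_syn, ds_syn = ds_syn,
                             dn_non = dn_non, ds_non = ds_non)
  }
  list(syn = .codon_env$syn_nbr, non = .codon_env$nonsyn_nbr,
       delta = .codon_env$delta)
}

# expected event intensities solving the site-count drift fixed point
.codon_event_rates <- function(anc_idx, p_n, p_s, nbr) {
  tab <- .site_count_table("nonsynonymous")
  n_anc <- sum(tab$n[anc_idx])
  s_anc <- sum(tab$s[anc_idx])
  has_syn <- lengths(nbr$syn[anc_idx]) > 0
  mu <- list(
    dn_non = mean(nbr$delta$dn_non[anc_idx]),
    ds_non = mean(nbr$delta$ds_non[anc_idx]),
    dn_syn = mean(nbr$delta$dn_syn[anc_idx][has_syn]),
    ds_syn = mean(nbr$delta$ds_syn[anc_idx][has_syn])
  )
  lam_n <- p_n * n_anc
  lam_s <- p_s * s_anc
  for (it in 1:3) {
    n_bar <- n_anc + 0.5 * (lam_n * mu$dn_non + lam_s * mu$dn_syn)
    s_bar <- s_anc + 0.5 * (lam_n * mu$ds_non + lam_s * mu$ds_syn)
    lam_n <- p_n * n_bar
    lam_s <- p_s * s_bar
  }
  list(lam_n = lam_n, lam_s = lam_s, has_syn = has_syn)
}

#' Simulate pairwise codon alignments with planted divergence
#'
#' Each gene descends from a random sense-codon ancestor; nonsynonymous and
#' synonymous substitutions (Poisson counts targeted to the planted per-site
#' rates, with the Jukes-Cantor forward map applied so the planted values are
#' corrected distances) are assigned to distinct codons and to one of the two
#' lineages at random. Substitution classes follow the same standard-code
#' classification the estimator uses, so `pairwise_dnds()` recovers the
#' planted rates without systematic bias.
#'
#' @param n_genes Number of alignment pairs.
#' @param n_codons Codons per gene.
#' @param d_n,d_s Planted per-site rates (scalar or per-gene vectors).
#' @param seed Integer seed.
#' @return A list: `pairs` (tibble `gene_id`, `seq_a`, `seq_b`) and `truth`
#'   (tibble `gene_id`, `d_n`, `d_s`).
#' @export
simulate_codon_pair_set <- function(n_genes = 1000, n_codons = 300,
                                    d_n = 0.1, d_s = 0.1, seed = 1L) {
  d_n <- rep_len(d_n, n_genes)
  d_s <- rep_len(d_s, n_genes)
  if (any(!is.finite(d_n)) || any(!is.finite(d_s)) ||
      any(d_n < 0) || any(d_s < 0)) {
    stop_format("planted rates must be finite and non-negative")
  }
  p_n <- 0.75 * (1 - exp(-4 * d_n / 3))
  p_s <- 0.75 * (1 - exp(-4 * d_s / 3))
  if (any(p_n >= 0.75) || any(p_s >= 0.75)) {
    stop_format("planted rates imply difference proportions >= 3/4 (saturated by construction)")
  }
  cd <- .codon_data()
  nbr <- .neighbor_tables()
  sense_idx <- which(cd$sense)
  gene_ids <- sprintf("gene%05d", seq_len(n_genes))
  pairs <- with_seed(as.integer(seed), {
    map(seq_len(n_genes), function(g) {
      anc <- sample(sense_idx, n_codons, replace = TRUE)
      rates <- .codon_event_rates(anc, p_n[g], p_s[g], nbr)
      k_n <- rpois(1, rates$lam_n)
      k_s <- rpois(1, rates$lam_s)
      syn_pool <- which(rates$has_syn)
      if (k_s > length(syn_pool) || k_n + k_s > n_codons) {
        stop_format("planted divergence saturates the sequence (too many substitutions)")
      }
      pos_s <- if (k_s > 0) sample(syn_pool, k_s) else integer(0)
      pool_n <- setdiff(seq_len(n_codons), pos_s)
      pos_n <- if (k_n > 0) sample(pool_n, k_n) else integer(0)
      a <- b <- anc
      for (t in pos_s) {
        new <- nbr$syn[[anc[t]]]
        new <- new[[sample.int(length(new), 1)]]
        if (runif(1) < 0.5) a[t] <- new else b[t] <- new
      }
      for (t in pos_n) {
        new <- nbr$non[[anc[t]]]
        new <- new[[sample.int(length(new), 1)]]
        if (runif(1) < 0.5) a[t] <- new else b[t] <- new
      }
      tibble(gene_id = gene_ids[g],
             seq_a = paste(cd$codons[a], collapse = ""),
             seq_b = paste(cd$codons[b], collapse = ""))
    }) |> list_rbind()
  })
  list(pairs = pairs, truth = tibble(gene_id = gene_ids, d_n = d_n, d_s = d_s))
}
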