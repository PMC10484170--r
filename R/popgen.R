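# Within-species selection statistics per gene: nucleotide diversity with
# invariant-site denominators (pixy-style ratio of sums), Tajima's D computed
# per variant site (S = 1) and averaged across a gene, polymorphism counts and
# the direction of selection.

#' Harmonic number a_n = sum_{j=1}^{n-1} 1/j
#'
#' The Watterson correction factor for a sample of `n` chromosomes, summed in
#' ascending order of `j`.
#'
#' @param n Integer vector of chromosome counts, all `>= 2`.
#' @return Numeric vector of harmonic numbers.
#' @export
harmonic_number <- function(n) {
  if (any(is.na(n)) || any(n < 2)) stop_format("`n` must be >= 2")
  cs <- cumsum(1 / seq_len(max(n) - 1L))
  cs[n - 1L]
}

#' Per-site Watterson's theta (one segregating site)
#'
#' `1 / a_n`: Watterson's estimator with the number of segregating sites set
#' to one.
#'
#' @inheritParams harmonic_number
#' @export
site_theta_w <- function(n) 1 / harmonic_number(n)

#' Per-site nucleotide diversity
#'
#' `pi_i = (n / (n - 1)) * (1 - p_ref^2 - p_alt^2)` for a biallelic site with
#' `n` non-missing chromosomes; 0 for invariant sites, `NA` when `n < 2`.
#'
#' @param n_chromosomes Integer vector: non-missing genotyped chromosomes per
#'   site.
#' @param p_alt Numeric vector: alternate-allele frequency per site.
#' @export
site_pi <- function(n_chromosomes, p_alt) {
  n <- n_chromosomes
  p_ref <- 1 - p_alt
  out <- (n / (n - 1)) * (1 - p_ref^2 - p_alt^2)
  out[n < 2] <- NA_real_
  out
}

#' Variance of (pi_i - thetaW_i) for a single segregating site
#'
#' `Var = ((n + 1) / (3 (n - 1)) - 1 / a_n) / a_n`, i.e. Tajima's (1989) `e1`
#' with `S = 1`. Sites with `n < 4` return `NA`: for `n` in (2, 3) the
#' expression is zero or numerically fragile and such sites are excluded from
#' the per-gene average.
#'
#' @inheritParams harmonic_number
#' @export
site_d_variance <- function(n) {
  a <- harmonic_number(n)
  v <- ((n + 1) / (3 * (n - 1)) - 1 / a) / a
  v[n < 4] <- NA_real_
  v
}

#' Per-site Tajima's D
#'
#' `d_i = (pi_i - thetaW_i) / sqrt(Var(pi_i - thetaW_i))`; `NA` for sites
#' excluded by the variance rule (`n < 4`).
#'
#' @inheritParams site_pi
#' @export
site_d <- function(n_chromosomes, p_alt) {
  n <- n_chromosomes
  (site_pi(n, p_alt) - site_theta_w(n)) / sqrt(site_d_variance(n))
}

.is_variant <- function(sites) {
  sites$n_alt > 0L & sites$n_alt < sites$n_chromosomes
}

#' Per-gene Tajima's D (mean of per-site D over variant sites)
#'
#' Computes the per-site D of every biallelic variant site and averages it,
#' unweighted, within each gene. Sites with fewer than 4 non-missing
#' chromosomes are excluded (logged); genes with no usable variant site get
#' `NA`.
#'
#' @param sites A sites tibble (see [read_sites_vcf()]) with columns
#'   `gene_id`, `site_class`, `n_chromosomes`, `n_alt`.
#' @return A tibble: `gene_id`, `tajima_d`, `n_variant_sites`,
#'   `n_sites_excluded`.
#' @export
gene_tajima_d <- function(sites) {
  v <- sites[.is_variant(sites), , drop = FALSE]
  if (nrow(v) == 0L) {
    return(tibble(gene_id = unique(sites$gene_id), tajima_d = NA_real_,
                  n_variant_sites = 0L, n_sites_excluded = 0L))
  }
  d <- site_d(v$n_chromosomes, v$n_alt / v$n_chromosomes)
  log_skip("variant sites with n < 4 (Tajima's D)", sum(is.na(d)))
  out <- tibble(gene_id = v$gene_id, d = d) |>
    group_by(.data$gene_id) |>
    summarise(tajima_d = mean(.data$d, na.rm = TRUE),
              n_variant_sites = sum(!is.na(.data$d)),
              n_sites_excluded = sum(is.na(.data$d)), .groups = "drop")
  out$tajima_d[out$n_variant_sites == 0L] <- NA_real_
  # genes present in the input but with no variant sites at all
  missing <- setdiff(unique(sites$gene_id), out$gene_id)
  if (length(missing)) {
    out <- bind_rows(out, tibble(gene_id = missing, tajima_d = NA_real_,
                                 n_variant_sites = 0L, n_sites_excluded = 0L))
  }
  arrange(out, .data$gene_id)
}

#' Gene-level nucleotide diversity (pixy-style, single gene)
#'
#' Ratio-of-sums estimator across genotyped sites: per site with `n`
#' non-missing chromosomes and alternate count `c`, the pairwise differences
#' are `c (n - c)` and the pairwise comparisons `n (n - 1) / 2`. The per-site
#' estimate `sum(diff) / sum(comp)` is then multiplied by the number of sites
#' included in the analysis and divided by `denominator_sites` (the
#' Nei-Gojobori N or S count of the gene, or the total site count for overall
#' diversity).
#'
#' @param sites Sites tibble for one gene; an optional `weight` column gives
#'   site multiplicities (used by the synthetic generator to collapse blocks
#'   of invariant sites).
#' @param class_filter Optional character vector of site classes to keep
#'   (invariant sites are always kept); `NULL` keeps every class.
#' @param n_sites_included Number of genotyped sites in the analysis; defaults
#'   to the (weighted) number of sites after class filtering.
#' @param denominator_sites Final per-site denominator (N, S, or total sites).
#' @return A single numeric value (`NA` when no comparisons are possible or
#'   the denominator is zero).
#' @export
gene_pi <- function(sites, class_filter = NULL, n_sites_included = NULL,
                    denominator_sites = NULL) {
  w <- if ("weight" %in% names(sites)) sites$weight else rep(1, nrow(sites))
  keep <- if (is.null(class_filter)) rep(TRUE, nrow(sites)) else
    sites$site_class %in% c(class_filter, "invariant")
  s <- sites[keep, , drop = FALSE]
  w <- w[keep]
  if (is.null(denominator_sites)) denominator_sites <- sum(w)
  if (is.null(n_sites_included)) n_sites_included <- sum(w)
  if (is.na(denominator_sites) || denominator_sites <= 0) return(NA_real_)
  n <- s$n_chromosomes
  c_alt <- s$n_alt
  diffs <- sum(c_alt * (n - c_alt) * w)
  comps <- sum(n * (n - 1) / 2 * w)
  if (comps <= 0) return(NA_real_)
  (diffs / comps) * n_sites_included / denominator_sites
}

#' Per-gene pi, piN and piS with invariant-site denominators
#'
#' Applies [gene_pi()] three times per gene, following the analysis design of
#' computing diversity over (a) all sites, (b) missense variants plus all
#' invariant sites, and (c) synonymous variants plus all invariant sites, then
#' converting (b) and (c) to per-nonsynonymous-site and per-synonymous-site
#' rates by dividing by the Nei-Gojobori N and S counts.
#'
#' @param sites Sites tibble with columns `gene_id`, `site_class`,
#'   `n_chromosomes`, `n_alt` (optional `weight`).
#' @param site_counts Tibble with `gene_id`, `n_sites` (N) and `s_sites` (S)
#'   per gene, e.g. from [pairwise_dnds()] or [count_sequence_sites()].
#' @return A tibble: `gene_id`, `pi`, `pi_n`, `pi_s`, `n_sites_used`.
#' @export
gene_diversity <- function(sites, site_counts) {
  stopifnot(all(c("gene_id", "n_sites", "s_sites") %in% names(site_counts)))
  w <- if ("weight" %in% names(sites)) sites$weight else rep(1, nrow(sites))
  n <- sites$n_chromosomes
  c_alt <- sites$n_alt
  base <- tibble(
    gene_id = sites$gene_id,
    class = sites$site_class,
    diffs = c_alt * (n - c_alt) * w,
    comps = n * (n - 1) / 2 * w,
    w = w
  )
  agg <- base |>
    group_by(.data$gene_id) |>
    summarise(
      d_all = sum(.data$diffs), c_all = sum(.data$comps), w_all = sum(.data$w),
      d_mis = sum(.data$diffs[.data$class %in% c("missense", "invariant")]),
      c_mis = sum(.data$comps[.data$class %in% c("missense", "invariant")]),
      w_mis = sum(.data$w[.data$class %in% c("missense", "invariant")]),
      d_syn = sum(.data$diffs[.data$class %in% c("synonymous", "invariant")]),
      c_syn = sum(.data$comps[.data$class %in% c("synonymous", "invariant")]),
      w_syn = sum(.data$w[.data$class %in% c("synonymous", "invariant")]),
      .groups = "drop"
    ) |>
    left_join(site_counts[, c("gene_id", "n_sites", "s_sites")], by = "gene_id")
  ratio <- function(d, co) ifelse(co > 0, d / co, NA_real_)
  agg |>
    transmute(
      gene_id = .data$gene_id,
      pi = ratio(.data$d_all, .data$c_all),
      pi_n = ifelse(!is.na(.data$n_sites) & .data$n_sites > 0,
                    ratio(.data$d_mis, .data$c_mis) * .data$w_mis / .data$n_sites,
                    NA_real_),
      pi_s = ifelse(!is.na(.data$s_sites) & .data$s_sites > 0,
                    ratio(.data$d_syn, .data$c_syn) * .data$w_syn / .data$s_sites,
                    NA_real_),
      n_sites_used = .data$w_all
    )
}

#' Counts of nonsynonymous and synonymous polymorphisms per gene
#'
#' `PN` is the number of segregating missense sites, `PS` the number of
#' segregating synonymous sites.
#'
#' @inheritParams gene_tajima_d
#' @return A tibble: `gene_id`, `p_n_count`, `p_s_count`.
#' @export
count_polymorphisms <- function(sites) {
  v <- .is_variant(sites)
  tibble(gene_id = sites$gene_id,
         mis = v & sites$site_class == "missense",
         syn = v & sites$site_class == "synonymous") |>
    group_by(.data$gene_id) |>
    summarise(p_n_count = sum(.data$mis), p_s_count = sum(.data$syn),
              .groups = "drop")
}

#' Direction of selection
#'
#' `DoS = DN / (DN + DS) - PN / (PN + PS)` (Stoletzki & Eyre-Walker 2011).
#' Positive values suggest adaptive divergence, negative values segregating
#' deleterious variation. `NA` (never 0) when either denominator is zero.
#'
#' @param dn_count,ds_count Nonsynonymous/synonymous fixed differences.
#' @param pn_count,ps_count Nonsynonymous/synonymous polymorphism counts.
#' @return Numeric vector in `[-1, 1]` (or `NA`).
#' @export
direction_of_selection <- function(dn_count, ds_count, pn_count, ps_count) {
  div <- dn_count + ds_count
  pol <- pn_count + ps_count
  ifelse(div > 0 & pol > 0,
         dn_count / div - pn_count / pol,
         NA_real_)
}

#' Assemble per-gene selection statistics
#'
#' Joins diversity ([gene_diversity()]), per-gene Tajima's D
#' ([gene_tajima_d()]), polymorphism counts and, when a divergence table is
#' supplied, the between-species estimates and the direction of selection.
#'
#' @inheritParams gene_diversity
#' @param divergence Optional tibble from [pairwise_dnds()].
#' @return A tibble with one row per gene.
#' @export
gene_selection_stats <- function(sites, site_counts, divergence = NULL) {
  out <- gene_diversity(sites, site_counts) |>
    left_join(gene_tajima_d(sites)[, c("gene_id", "tajima_d")], by = "gene_id") |>
    left_join(count_polymorphisms(sites), by = "gene_id")
  if (!is.null(divergence)) {
    div <- divergence[, intersect(c("gene_id", "nd", "sd", "d_n", "d_s",
                                    "dnds", "saturated"), names(divergence))]
    out <- left_join(out, div, by = "gene_id") |>
      mutate(dos = direction_of_selection(.data$nd, .data$sd,
                                          .data$p_n_count, .data$p_s_count))
  }
  out
}
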