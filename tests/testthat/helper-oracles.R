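# Independent oracles used across the suite. These deliberately re-derive
# every quantity from first principles (brute-force enumeration, textbook
# formulas, residual regressions) without touching package internals.

GC <- Biostrings::GENETIC_CODE
BASES <- c("A", "C", "G", "T")
ALL_CODONS <- apply(expand.grid(BASES, BASES, BASES), 1, paste, collapse = "")
SENSE_CODONS <- ALL_CODONS[GC[ALL_CODONS] != "*"]

# single-mutant scan: synonymous fraction per position, stops as nonsynonymous
oracle_site_counts <- function(codon) {
  s <- 0
  for (p in 1:3) {
    for (b in setdiff(BASES, substr(codon, p, p))) {
      mut <- codon
      substr(mut, p, p) <- b
      if (GC[mut] != "*" && GC[mut] == GC[codon]) s <- s + 1 / 3
    }
  }
  c(n = 3 - s, s = s)
}

# exhaustive pathway enumeration by depth-first search over substitution orders
oracle_pair_diffs <- function(a, b) {
  pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  if (!length(pos)) return(c(nd = 0, sd = 0))
  paths <- list()
  walk <- function(cur, remaining, nd, sd, hit_stop) {
    if (!length(remaining)) {
      paths[[length(paths) + 1]] <<- c(nd = nd, sd = sd, stop = hit_stop)
      return(invisible())
    }
    for (p in remaining) {
      nxt <- cur
      substr(nxt, p, p) <- substr(b, p, p)
      is_stop <- GC[cur] == "*" || GC[nxt] == "*"
      syn <- !is_stop && GC[cur] == GC[nxt]
      walk(nxt, setdiff(remaining, p), nd + !syn, sd + syn,
           hit_stop || is_stop)
    }
  }
  walk(a, pos, 0, 0, FALSE)
  m <- do.call(rbind, paths)
  valid <- m[, "stop"] == 0
  if (any(valid)) m <- m[valid, , drop = FALSE]
  c(nd = mean(m[, "nd"]), sd = mean(m[, "sd"]))
}

# classic Tajima (1989) D from the textbook e1/e2 coefficients, S = 1
oracle_tajima_d <- function(n, c_alt) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  pi_hat <- c_alt * (n - c_alt) / choose(n, 2)
  (pi_hat - 1 / a1) / sqrt(e1 + e2 * 0)
}

# partial Spearman by the rank-residual route: regress the ranks of x and y
# on the covariate ranks, correlate the residuals
oracle_partial_spearman <- function(d, x, y, covs) {
  r <- as.data.frame(lapply(d[, c(x, y, covs), drop = FALSE],
                            rank, ties.method = "average"))
  if (length(covs)) {
    fx <- stats::lm(stats::reformulate(covs, response = x), data = r)
    fy <- stats::lm(stats::reformulate(covs, response = y), data = r)
    stats::cor(stats::resid(fx), stats::resid(fy))
  } else {
    stats::cor(r[[x]], r[[y]])
  }
}

# small random expression fixture (matrix + metadata)
random_expr_fixture <- function(n_genes = 6, n_samples = 5, seed = 1) {
  withr::with_seed(seed, {
    expr <- dplyr::bind_cols(
      tibble::tibble(gene_id = paste0("g", seq_len(n_genes))),
      tibble::as_tibble(setNames(
        as.data.frame(matrix(round(stats::rexp(n_genes * n_samples, 0.05), 3),
                             nrow = n_genes)),
        paste0("s", seq_len(n_samples))))
    )
    exp_idx <- ceiling(seq_len(n_samples) / 2) # runs 2k-1, 2k share an experiment
    samples <- tibble::tibble(
      sample_id = paste0("s", seq_len(n_samples)),
      run_id = paste0("run", seq_len(n_samples)),
      experiment_id = paste0("exp", exp_idx),
      study_id = paste0("study", 1 + exp_idx %% 2),
      tissue_label = "leaf",
      treatment_label = c("control", "cold")[1 + exp_idx %% 2]
    )
    list(expr = expr, samples = samples)
  })
}
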