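# Study-scale generators: a treatment-structured expression corpus with
# study-level batch shifts, and the joined study tying expression, genotypes,
# codon pairs and gene covariates to shared latent traits through a Gaussian
# copula with a planted partial-correlation structure.

#' Simulate a treatment-structured multi-study expression matrix
#'
#' Log-scale model: per-gene baseline + treatment effects (shaped so each
#' gene's true tau is the supplied specificity) + a rank-one study-level
#' batch term (per-gene loading times per-study score) + gene-level
#' log-normal noise, exponentiated to TPM. Every treatment is observed in
#' every study, so treatment and batch variation are not confounded.
#'
#' @param n_genes Number of genes.
#' @param treatments Treatment category labels.
#' @param n_studies Studies (each covering all treatments); must be at least
#'   2 when `batch_sd > 0`.
#' @param reps_per_study Experiments per treatment per study.
#' @param specificity Per-gene true tau (scalar, vector, or `NULL` for
#'   uniform draws on `[0, 0.9]`).
#' @param batch_sd SD of the per-gene batch loadings (log2 scale).
#' @param noise_sd SD of the per-observation log2 noise.
#' @param mean_log2_tpm,sd_log2_tpm Baseline expression distribution.
#' @param tissue Tissue label stamped on all samples.
#' @param seed Integer seed.
#' @return A list: `expr`, `samples`, `truth` (per gene: `tau_true`,
#'   `peak_treatment`, `baseline_tpm`, `batch_loading`) and `batch` (per
#'   sample: `batch_score`).
#' @export
simulate_expression_study <- function(n_genes = 2000,
                                      treatments = c("control", "cold",
                                                     "heat", "drought"),
                                      n_studies = 2, reps_per_study = 2,
                                      specificity = NULL, batch_sd = 0,
                                      noise_sd = 0.25, mean_log2_tpm = 6,
                                      sd_log2_tpm = 1.5, tissue = "leaf",
                                      seed = 1L) {
  if (batch_sd > 0 && n_studies < 2) {
    stop_format("batch recovery needs every treatment in at least two studies")
  }
  grid <- expand.grid(rep = seq_len(reps_per_study),
                      study = seq_len(n_studies),
                      treatment = treatments,
                      stringsAsFactors = FALSE)
  samples <- tibble(
    sample_id = sprintf("%s_s%d_r%d", grid$treatment, grid$study, grid$rep),
    run_id = sprintf("%s_s%d_r%d", grid$treatment, grid$study, grid$rep),
    experiment_id = sprintf("%s_s%d_r%d", grid$treatment, grid$study, grid$rep),
    study_id = paste0("study", grid$study),
    tissue_label = tissue,
    treatment_label = grid$treatment
  )
  u_study <- if (n_studies > 1) {
    as.vector(scale(seq_len(n_studies)))
  } else {
    0
  }
  gene_ids <- sprintf("gene%05d", seq_len(n_genes))
  out <- with_seed(as.integer(seed), {
    tau_true <- if (is.null(specificity)) runif(n_genes, 0, 0.9) else
      rep_len(specificity, n_genes)
    if (any(tau_true < 0 | tau_true > 1)) stop_format("specificity outside [0, 1]")
    peak <- sample(treatments, n_genes, replace = TRUE)
    baseline <- 2^rnorm(n_genes, mean_log2_tpm, sd_log2_tpm)
    gamma <- rnorm(n_genes, 0, batch_sd)
    profile <- outer(tau_true, rep(1, length(treatments)))
    profile <- 1 - profile
    profile[cbind(seq_len(n_genes), match(peak, treatments))] <- 1
    dimnames(profile) <- list(gene_ids, treatments)
    mean_tpm <- baseline * profile[, samples$treatment_label, drop = FALSE]
    batch_term <- outer(gamma, u_study[grid$study])
    eps <- matrix(rnorm(n_genes * nrow(samples), 0, noise_sd),
                  nrow = n_genes)
    tpm <- mean_tpm * 2^(batch_term + eps)
    colnames(tpm) <- samples$sample_id
    rownames(tpm) <- gene_ids
    list(tpm = tpm, tau_true = tau_true, peak = peak, baseline = baseline,
         gamma = gamma)
  })
  list(
    expr = matrix_to_expr(out$tpm),
    samples = samples,
    truth = tibble(gene_id = gene_ids, tau_true = out$tau_true,
                   peak_treatment = out$peak, baseline_tpm = out$baseline,
                   batch_loading = out$gamma),
    batch = tibble(sample_id = samples$sample_id,
                   batch_score = u_study[grid$study])
  )
}

#' Default planted partial-correlation structure
#'
#' A 5 x 5 partial-correlation matrix over the gene-level traits
#' `tau_treatment`, `avg_expr`, `length_bp`, `gc_fraction`, `pi_n`, with the
#' specificity and expression-level effects on nonsynonymous diversity set to
#' +0.10 and -0.19 (the magnitudes observed for leaf tissue) and weaker
#' realistic couplings among the covariates.
#'
#' @return A symmetric matrix with unit diagonal.
#' @export
default_partial_targets <- function() {
  v <- c("tau_treatment", "avg_expr", "length_bp", "gc_fraction", "pi_n")
  p <- diag(5)
  dimnames(p) <- list(v, v)
  set <- function(a, b, val) {
    p[a, b] <<- val
    p[b, a] <<- val
  }
  set("tau_treatment", "length_bp", 0.05)
  set("tau_treatment", "pi_n", 0.10)
  set("avg_expr", "length_bp", -0.10)
  set("avg_expr", "gc_fraction", 0.05)
  set("avg_expr", "pi_n", -0.19)
  set("length_bp", "gc_fraction", -0.10)
  set("length_bp", "pi_n", -0.12)
  set("gc_fraction", "pi_n", 0.05)
  p
}

# partial-correlation matrix -> latent correlation matrix (via the precision
# matrix); errors on non-positive-definite targets
.partial_to_sigma <- function(p) {
  omega <- -p
  diag(omega) <- 1
  ev <- eigen(omega, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    stop_format("target partial-correlation matrix is not positive definite")
  }
  sigma <- solve(omega)
  d <- 1 / sqrt(diag(sigma))
  sigma * outer(d, d)
}

#' Simulate a joined study with a planted partial-correlation structure
#'
#' Gene-level latent traits are drawn from a Gaussian copula whose partial
#' correlations are the supplied targets; expression (treatment profiles
#' shaped by the latent specificity, peak level by the latent average
#' expression), genotypes (per-site theta from the latent constraint trait),
#' codon pairs, and the gene covariate table are all generated from those
#' shared traits, so the partial correlations recovered by the pipeline can
#' be compared against a known truth.
#'
#' @param n_genes Number of genes.
#' @param partial_targets Partial-correlation matrix over `tau_treatment`,
#'   `avg_expr`, `length_bp`, `gc_fraction`, `pi_n` (default
#'   [default_partial_targets()]); the identity matrix gives the null study.
#' @param n_treatments,reps_per_treatment Expression design (single study, no
#'   batch term).
#' @param noise_sd Log2-scale expression noise SD.
#' @param n_ind,n_nonsyn_sites,n_syn_sites,missing_rate Genotype design (see
#'   [simulate_genotypes()]).
#' @param n_codons Codons per simulated alignment pair; `0` skips divergence
#'   simulation.
#' @param seed Integer seed.
#' @return A list: `expr`, `samples`, `sites`, `site_counts`, `covariates`
#'   (`gene_id`, `length_bp`, `gc_fraction`, `family_size`, `one_to_one`,
#'   `tau_tissue`), `pairs` (codon alignments or `NULL`), and `truth`
#'   (per-gene latent traits plus the planted matrix as attribute
#'   `partial_targets`).
#' @export
simulate_joined_study <- function(n_genes = 10000,
                                  partial_targets = default_partial_targets(),
                                  n_treatments = 10, reps_per_treatment = 3,
                                  noise_sd = 0.15, n_ind = 25,
                                  n_nonsyn_sites = 1500, n_syn_sites = 500,
                                  missing_rate = 0.05, n_codons = 150,
                                  seed = 1L) {
  stopifnot(nrow(partial_targets) == 5, ncol(partial_targets) == 5)
  sigma <- .partial_to_sigma(partial_targets)
  gene_ids <- sprintf("gene%05d", seq_len(n_genes))
  treatments <- sprintf("treat%02d", seq_len(n_treatments))
  lat <- with_seed(derive_seed(seed, 101), {
    z <- matrix(rnorm(n_genes * 5), ncol = 5) %*% chol(sigma)
    peak <- sample.int(n_treatments, n_genes, replace = TRUE)
    list(z = z, peak = peak)
  })
  z <- lat$z
  tau_true <- 0.05 + 0.90 * pnorm(z[, 1])
  avg_true <- 300 * exp(0.6 * z[, 2])
  length_bp <- pmax(200L, as.integer(round(2000 * exp(0.5 * z[, 3]))))
  gc_fraction <- 0.30 + 0.20 * plogis(z[, 4])
  theta_n <- 0.003 * exp(1.1 * z[, 5])

  # expression: peak level chosen so the across-treatment mean equals the
  # latent average-expression trait; off-peak categories at (1 - tau) times
  # the peak
  n_t <- n_treatments
  peak_level <- avg_true * n_t / (1 + (n_t - 1) * (1 - tau_true))
  profile <- outer(1 - tau_true, rep(1, n_t))
  profile[cbind(seq_len(n_genes), lat$peak)] <- 1
  profile <- profile * peak_level
  grid <- expand.grid(rep = seq_len(reps_per_treatment),
                      treatment = treatments, stringsAsFactors = FALSE)
  samples <- tibble(
    sample_id = sprintf("%s_r%d", grid$treatment, grid$rep),
    run_id = sprintf("%s_r%d", grid$treatment, grid$rep),
    experiment_id = sprintf("%s_r%d", grid$treatment, grid$rep),
    study_id = "study1", tissue_label = "leaf",
    treatment_label = grid$treatment
  )
  tpm <- with_seed(derive_seed(seed, 202), {
    eps <- matrix(rnorm(n_genes * nrow(samples), 0, noise_sd), nrow = n_genes)
    profile[, match(grid$treatment, treatments), drop = FALSE] * 2^eps
  })
  dimnames(tpm) <- list(gene_ids, samples$sample_id)

  geno <- simulate_genotypes(
    n_genes = n_genes, n_ind = n_ind, n_nonsyn_sites = n_nonsyn_sites,
    n_syn_sites = n_syn_sites, theta_n = theta_n, theta_s = 0.008,
    missing_rate = missing_rate, seed = derive_seed(seed, 303)
  )
  geno$sites$gene_id <- gene_ids[match(geno$sites$gene_id, geno$truth$gene_id)]
  geno$site_counts$gene_id <- gene_ids
  geno$truth$gene_id <- gene_ids

  pairs <- NULL
  if (n_codons > 0) {
    cps <- simulate_codon_pair_set(
      n_genes = n_genes, n_codons = n_codons,
      d_n = 0.03 * exp(0.5 * z[, 5]), d_s = 0.15,
      seed = derive_seed(seed, 404)
    )
    cps$pairs$gene_id <- gene_ids
    pairs <- cps$pairs
  }

  covariates <- with_seed(derive_seed(seed, 505), {
    family_size <- 1L + rpois(n_genes, 1.5)
    tibble(gene_id = gene_ids, length_bp = length_bp,
           gc_fraction = gc_fraction, family_size = family_size,
           one_to_one = family_size == 1L,
           tau_tissue = runif(n_genes, 0, 0.6))
  })
  truth <- tibble(gene_id = gene_ids, tau_true = tau_true,
                  avg_true = avg_true, length_bp = length_bp,
                  gc_fraction = gc_fraction, theta_n = theta_n)
  attr(truth, "partial_targets") <- partial_targets
  list(expr = matrix_to_expr(tpm), samples = samples,
       sites = geno$sites, site_counts = geno$site_counts,
       covariates = covariates, pairs = pairs, truth = truth)
}
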