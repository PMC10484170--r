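---
title: "Methods: selection statistics, expression specificity, and their covariate-adjusted correlation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: selection statistics, expression specificity, and their covariate-adjusted correlation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specsel)
```

specsel links treatment-specific gene expression to signatures of relaxed
selection. This vignette documents the models, the parameters that matter,
the numerical choices at the edges, and what the synthetic-data generators do
and do not emulate.

## Divergence: Nei–Gojobori site and difference counting

`pairwise_dnds()` consumes gapless pairwise codon alignments. Each sense
codon contributes fractional site counts: at each of its three positions the
synonymous fraction is the share of the possible single-base changes that
preserve the amino acid, and the two fractions sum to 3 per codon. Pairwise
differences are averaged over substitution pathways: for codons differing at
*k* positions all *k*! orderings of single-base steps are enumerated, each
step classified synonymous or nonsynonymous, and pathways passing through a
stop codon are excluded whenever any stop-free pathway exists. Proportions
are corrected with the Jukes–Cantor map d = −(3/4)·ln(1 − 4p/3).

Choices a user should know about:

* **Stop-codon convention.** Mutations *to* stop codons are counted as
  nonsynonymous with the per-position denominator fixed at 3
  (`stop_handling = "nonsynonymous"`, the default). The alternative
  convention — dropping stop mutants from the denominator — is available as
  `stop_handling = "excluded"` so the difference between the two is
  measurable on any dataset. The two conventions differ most for codons such
  as TAT, where stop-adjacent third positions exist.
* **Degenerate pathways.** If *every* pathway between two codons crosses a
  stop (possible for doubly/triply substituted codons), the estimator falls
  back to averaging over all pathways with stop-crossing steps counted as
  nonsynonymous, and reports the pair in `stop_fallback_codons`.
* **Ambiguity.** Codons containing non-ACGT bases, and stop codons in either
  sequence, are dropped *pairwise*, so site counts and difference counts stay
  consistent; `codons_skipped` reports how many.
* **Saturation.** `saturated` is `TRUE` when d~S~ > 1 or the correction is
  undefined (p ≥ 3/4); the d~N~/d~S~ ratio is `NA` when d~S~ = 0 — never a
  division by zero. Saturated genes are excluded from the d~N~ analyses by
  `build_analysis_table()`.

All 61 × 61 sense-codon difference pairs and all 61 site counts are verified
in the test suite against an independent exhaustive enumerator.

## Polymorphism: diversity with invariant-site denominators, per-site Tajima's D

Diversity uses the ratio-of-sums estimator across genotyped sites (the
convention of invariant-site-aware callers): per site, differences
c(n−c) and comparisons n(n−1)/2, summed before dividing. Each site uses its
own non-missing chromosome count *n*; there is no gene-wide *n*. The
per-site estimate is multiplied by the number of sites included and divided
by the target denominator — the Nei–Gojobori *N* for πN (missense variants
plus all invariant sites enter the per-site estimate), *S* for πS, and the
genotyped site count itself for overall π (which therefore remains a
per-site quantity; the conversion is only material for πN and πS).

Tajima's D is computed per variant site with the segregating-site count set
to one — π~i~ = (n/(n−1))(1 − p²~ref~ − p²~alt~), θ~Wi~ = 1/a~i~,
Var = ((n+1)/(3(n−1)) − 1/a~i~)/a~i~ — and the per-gene value is the
unweighted mean of D~i~ over variant sites. The variance expression equals
the classical e₁ coefficient with S = 1; the suite checks the per-gene value
against a textbook implementation for every n in 4..100 and every allele
count, to 1e−12.

Edge rules: sites with n &lt; 4 are excluded from D (the variance is zero or
negative for n ∈ {2, 3}; panels of interest have n ≫ 3) and logged;
statistics that are undefined (no variant sites, zero denominators,
D~N~+D~S~ = 0 or P~N~+P~S~ = 0 for DoS) propagate as `NA`, never as 0.
Variant sites whose class annotation is neither missense nor synonymous
(`other`) count toward overall π but not πN/πS.

## Expression: group means, τ, thresholded averages

Technical replicates (runs sharing an experiment ID) are averaged first;
labels must agree within an experiment or the collapse errors. Group means
include zeros. τ = Σ(1 − x~i~/max x)/(N−1) over the per-category means is 0
for uniform expression, 1 for single-category expression, `NA` when the gene
is silent everywhere or fewer than two categories exist. τ is computed on
raw TPM means (a log transform would change the index; the defining formula
is on the measurement scale), and tissue specificity applies the same
formula across tissue means restricted to control samples.

Average expression excludes values below 5 TPM (`>= 5` is kept — the literal
reading of "excluding values &lt; 5"). The threshold exists because a gene
expressed in few conditions necessarily has a low across-condition mean, so
the unthresholded average is correlated with specificity by construction.
The ZINB experiment (`zinb_specificity_experiment()`) makes this concrete:
expression matrices drawn as zero with probability 0.6 and otherwise
negative-binomial(size 100, prob 0.1) — the (size, success-probability)
parameterization with mean size(1−p)/p — in five groups of five columns.
Per matrix, τ is correlated with the row mean including zeros and with the
mean over non-zero entries. The number of rows per matrix is not part of the
published design; 500 genes is used as a realistic desk-scale default. The
acceptance suite asserts the qualitative finding: the zero-excluding
correlation is closer to zero in at least 95% of 1,000 matrices.

## Batch correction: surrogate variables

Expression is modelled on the log2(TPM+1) scale as
x~ij~ = μ~i~ + f(y~j~) + Σ~k~ λ~ki~ h~kj~ + e\*~ij~, with f the
per-treatment mean deviation and h~k~ orthonormal sample-space vectors
spanning the residual batch structure. The transform moderates count-scale
heteroscedasticity; it is inverted after removal and negative TPM is clipped
to 0. Design choices:

* **Estimator.** Surrogates are the leading right singular vectors of the
  design residuals. This is deliberately simpler than the
  iteratively-reweighted svaseq algorithm: the model contract (design fit,
  surrogate span, joint removal) is the same, the internals are not, and no
  empirical-Bayes shrinkage or known-batch adjustment is attempted.
* **Choosing K.** A Buja–Eyuboglu-style permutation test (B = 200,
  α = 0.05 by default; the RNG seed is a required argument): each gene's
  residuals are permuted independently, the permuted matrix is
  re-residualized on the design, and a component is retained while its
  statistic exceeds the permutation null (add-one p-values). The statistic
  is each eigenvalue divided by the **median** eigenvalue of its own
  spectrum rather than its share of the total: a share-based test is
  miscalibrated on spectra with removed or deficient directions (after one
  correction pass, every share is inflated by (n−G)/(n−G−1) and a second
  pass would hallucinate surrogates), whereas median normalization is
  insensitive to a vanished component. This is what makes re-estimation
  after correction return K = 0.
* **Removal.** Loadings λ are estimated per gene by least squares on the
  design and surrogates *jointly*, so removal does not absorb treatment
  signal; corrected residuals are orthogonal to each h~k~ by construction.
* **Subsetting rule.** `filter_min_studies()` drops treatments observed in
  fewer than two studies before estimation, since a single-study treatment
  confounds its effect with that study's batch.

## Partial Spearman correlations

All variables are rank-transformed (average ranks for ties — the standard
choice, stated because it matters for heavily tied variables such as counts)
and the partial correlation is read off the precision matrix of the rank
correlations: ρ = −Ω~xy~/√(Ω~xx~Ω~yy~). p-values use the t statistic with
df = n − 2 − k; no multiple-testing correction is applied (coefficients are
reported with raw p-values and the per-analysis n). With no covariates the
estimator reduces exactly to ordinary Spearman ρ. Degenerate cases: if x and
y are perfectly rank-correlated the precision matrix is singular and the
partial correlation is returned as ±1; any other singularity is a collinear
covariate pair and errors with the pair named. Complete cases only; no
imputation.

Per-target analysis rules (`build_analysis_table()`): covariates are always
average expression, gene length, GC content and tissue specificity; family
size is added for πN and Tajima's D; d~N~ and DoS analyses are restricted to
1:1 orthologs (these measures are undefined off 1:1 orthologs) and d~N~
additionally drops saturated genes. `correlation_heatmap()` defaults to
controlling each pair for *all remaining* displayed variables, with
`control = "fixed"` available for the fixed-covariate-set convention, since
heatmap captions rarely pin this down.

## Synthetic data: what is emulated, what is not

Every generator is a pure function of its arguments and a seed (child seeds
are derived deterministically), and its output passes the package
validators.

* **Genotypes.** Segregating-site counts are Poisson with mean θ·L·a~n~ per
  class; derived counts follow the neutral SFS (P(i) ∝ 1/i) on the full
  panel; missingness removes whole diploid individuals, making observed
  counts hypergeometric subsamples — which preserves E[π] = θ exactly, the
  property the recovery tests use. Invariant sites are emitted as weighted
  rows grouped by chromosome count; the `weight` column is understood by the
  diversity functions and changes no statistic. Not emulated: linkage (sites
  are independent, so between-gene variance is smaller than coalescent
  reality), selection (constraint differences are planted through θ~N~/θ~S~,
  not simulated forward), sequencing error, and genotype-caller artifacts.
  Passing tests therefore show estimator correctness, not robustness to call
  quality.
* **Codon pairs.** Planted d~N~/d~S~ are Jukes–Cantor-inverted to target
  proportions; Poisson event counts are placed at most once per codon and
  assigned to one of the two lineages at random, with replacement codons
  drawn from the same standard-code classification the estimator uses. The
  event intensity solves a small fixed point so that the expected difference
  proportion is taken relative to the site counts of the generated *pair*
  (substituted codons shift fractional site counts slightly off the
  ancestor's); without this the planted rate would be the estimand only up
  to a site-count drift of a few tenths of a percent. Multiple hits within a
  codon are excluded by construction — the planted rate is an expectation
  the estimator should recover, not a mechanistic substitution process.
* **Expression studies.** Log-scale baseline + treatment profile + rank-one
  study batch term + log-normal noise. True τ is controlled exactly through
  the profile (off-peak categories at (1−τ) times the peak). Real corpora
  have full-rank, non-additive batch structure, unbalanced designs, and
  mapping-rate artifacts; none of that is emulated.
* **Joined study.** Five gene-level latent traits (τ, average expression,
  length, GC, πN-scale θ) from a Gaussian copula whose precision matrix
  encodes the target partial correlations (supplied matrices must be
  positive definite; the identity gives the null study). The expression peak
  level is set so the across-treatment mean equals the latent
  average-expression trait, which keeps the thresholded average a clean
  proxy for it; θ spans about an order of magnitude (log-SD 1.1 around
  0.003) so that measured πN rank-tracks the latent trait tightly enough for
  end-to-end recovery within the ±0.03 band at 10,000 genes. Spearman
  partials on monotone transforms of latent Gaussians differ from the latent
  Pearson partials by well under 0.01 at these magnitudes, so the planted
  matrix is quoted as the truth.

## Problem sizes and runtimes

The shipped tests use sizes chosen to give tight Monte-Carlo error at
interactive runtimes: 1,000 matrices for the ZINB experiment; 1,000 genes ×
300 codons per planted d~N~; 500 neutral genes for πS; 10,000 genes for the
joined-study recovery (Monte-Carlo SE of a partial correlation ≈ 0.01);
2,000 × 24 for batch recovery and 20 seeded runs of 500 × 24 for the null
calibration of K.

## Known limitations

* The Nei–Gojobori estimator assumes equal rates among the three changes at
  a site (no transition/transversion or codon-usage weighting); no
  maximum-likelihood or branch models are provided.
* Per-site Tajima's D averaged across sites is not the classical per-gene
  statistic when a gene has more than one segregating site; it is the
  per-site-averaged variant by design, and equals the classical statistic
  exactly in the single-site case.
* The surrogate estimator assumes additive batch structure on the log scale
  and will not separate batch from treatment when they are confounded —
  hence the minimum-studies rule.
* Complete-case analysis can induce selection effects if missingness is
  informative; n is reported with every coefficient so this is visible.
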