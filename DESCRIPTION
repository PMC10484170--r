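Package: specsel
Title: Treatment-Specific Gene Expression and Signatures of Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical machinery for linking condition-specific gene
    expression to relaxed selection. Implements per-gene selection statistics
    (Nei-Gojobori dN/dS with explicit site counting, nucleotide diversity at
    nonsynonymous and synonymous sites with invariant-site denominators,
    per-site-averaged Tajima's D, and the direction of selection), the tau
    expression-specificity index with thresholded expression averaging,
    surrogate-variable correction of between-study batch effects, partial
    Spearman correlation analysis, and a synthetic-data generator (including a
    zero-inflated negative-binomial confounding experiment) so the whole
    pipeline can be exercised with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tidyselect,
    utils,
    vcfR,
    withr
Suggests:
    jsonlite,
    sva,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
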