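# External representations: expression TSV + sample metadata, VCF 4.x with
# invariant sites, BED-derived site-class tables, and the per-gene results
# table. VCF records are 1-based; interval tables are 0-based half-open; all
# internal positions are stored 1-based.

.META_COLS <- c("sample_id", "run_id", "experiment_id", "study_id",
                "tissue_label", "treatment_label")

#' Validate an expression matrix and its sample metadata
#'
#' Checks the invariants of the expression representation: unique gene and
#' sample identifiers, finite non-negative TPM values, one metadata row per
#' sample with non-empty tissue and treatment labels.
#'
#' @param expr Wide tibble: `gene_id` column plus one numeric column per
#'   sample.
#' @param samples Metadata tibble with columns `sample_id`, `run_id`,
#'   `experiment_id`, `study_id`, `tissue_label`, `treatment_label`.
#' @return Invisibly `TRUE`; aborts with a format error otherwise.
#' @export
validate_expression <- function(expr, samples) {
  if (!is.data.frame(expr) || names(expr)[1] != "gene_id") {
    stop_format("expression table must have `gene_id` as its first column")
  }
  if (anyDuplicated(expr$gene_id)) stop_format("duplicated gene IDs")
  sample_ids <- names(expr)[-1]
  if (anyDuplicated(sample_ids)) stop_format("duplicated sample IDs")
  vals <- as.matrix(expr[, -1, drop = FALSE])
  if (!is.numeric(vals)) stop_format("non-numeric TPM values")
  if (anyNA(vals) || any(!is.finite(vals))) stop_format("non-finite TPM values")
  if (any(vals < 0)) stop_format("negative TPM values")
  missing_cols <- setdiff(.META_COLS, names(samples))
  if (length(missing_cols)) {
    stop_format(paste0("metadata lacks columns: ",
                       paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(samples$sample_id)) stop_format("duplicated metadata rows")
  absent <- setdiff(sample_ids, samples$sample_id)
  if (length(absent)) {
    stop_format(paste0("samples missing metadata rows: ",
                       paste(head(absent, 5), collapse = ", ")))
  }
  meta <- samples[match(sample_ids, samples$sample_id), ]
  if (any(is.na(meta$tissue_label) | meta$tissue_label == "") ||
      any(is.na(meta$treatment_label) | meta$treatment_label == "")) {
    stop_format("every sample needs non-empty tissue and treatment labels")
  }
  invisible(TRUE)
}

#' Read a gene-by-sample TPM matrix with its sample metadata
#'
#' @param path TSV with a header row of sample IDs and gene IDs in the first
#'   column.
#' @param meta_path Metadata TSV keyed by `sample_id`.
#' @return A list of class `expr_data` with elements `expr` (wide tibble) and
#'   `samples` (metadata tibble restricted and ordered to the matrix columns).
#' @export
read_expression_tsv <- function(path, meta_path) {
  expr <- read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(expr)[1] <- "gene_id"
  expr$gene_id <- as.character(expr$gene_id)
  samples <- read_tsv(meta_path, show_col_types = FALSE, progress = FALSE,
                      col_types = cols(.default = col_character()))
  validate_expression(expr, samples)
  samples <- samples[match(names(expr)[-1], samples$sample_id), ]
  structure(list(expr = as_tibble(expr), samples = as_tibble(samples)),
            class = "expr_data")
}

#' Write an expression matrix (and optionally its metadata) to TSV
#'
#' @inheritParams validate_expression
#' @param path Output TSV path for the matrix.
#' @param meta_path Optional output path for the metadata.
#' @export
write_expression_tsv <- function(expr, path, samples = NULL, meta_path = NULL) {
  write_tsv(expr, path, na = "NA", progress = FALSE)
  if (!is.null(samples) && !is.null(meta_path)) {
    write_tsv(samples, meta_path, na = "NA", progress = FALSE)
  }
  invisible(path)
}

#' Read a BED-derived site-class table
#'
#' Columns `chrom`, `start`, `end`, `gene_id`, `class` with 0-based half-open
#' intervals. Rows with class `cds` delimit the genotyped extent of a gene;
#' rows with class `missense` or `synonymous` classify variant positions.
#'
#' @param path TSV path (with header).
#' @return A tibble with the five columns above.
#' @export
read_site_classes <- function(path) {
  tab <- read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("chrom", "start", "end", "gene_id", "class")
  if (!all(need %in% names(tab))) {
    stop_format("site-class table needs columns chrom, start, end, gene_id, class")
  }
  if (any(tab$end <= tab$start)) stop_format("empty or inverted intervals")
  ov <- tab |>
    group_by(.data$gene_id, .data$class) |>
    arrange(.data$start, .by_group = TRUE) |>
    summarise(bad = any(.data$start[-1] < .data$end[-length(.data$end)]),
              .groups = "drop")
  if (any(ov$bad)) stop_format("overlapping intervals within a gene")
  as_tibble(tab[, need])
}

# locate the class-table rows covering 1-based positions; returns row index
# into `classes` (first match) or NA
.match_interval <- function(chrom, pos, classes) {
  idx <- rep(NA_integer_, length(pos))
  for (ch in unique(chrom)) {
    rows <- which(classes$chrom == ch)
    if (!length(rows)) next
    sel <- which(chrom == ch)
    for (i in sel) {
      hit <- rows[classes$start[rows] < pos[i] & pos[i] <= classes$end[rows]]
      if (length(hit)) idx[i] <- hit[1]
    }
  }
  idx
}

#' Read per-gene genotyped sites from a VCF with invariant records
#'
#' Parses a VCF 4.x file (plain or gzipped) containing both variant and
#' invariant records, keeps biallelic SNPs among the variants, and attaches
#' each site to a gene and functional class via a BED-derived class table.
#' `n_chromosomes` is twice the number of non-missing diploid genotype calls;
#' allele frequencies use only non-missing chromosomes. Multiallelic records,
#' indels and malformed genotype fields are skipped with a logged count; a VCF
#' without any invariant record triggers a warning because diversity
#' denominators will then be variant-only.
#'
#' @param path VCF path.
#' @param class_table Site-class tibble from [read_site_classes()].
#' @return A sites tibble: `chrom`, `pos`, `gene_id`, `site_class`
#'   (`missense`, `synonymous`, `other`, or `invariant`), `n_chromosomes`,
#'   `n_alt`, `p_ref`, `p_alt`.
#' @export
read_sites_vcf <- function(path, class_table) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  alt[is.na(alt)] <- "."
  invariant <- alt == "." | alt == ""
  multi <- grepl(",", alt, fixed = TRUE)
  indel <- nchar(ref) > 1L | (!invariant & !multi & nchar(alt) > 1L)
  keep <- invariant | (!multi & !indel)
  log_skip("multiallelic records", sum(multi))
  log_skip("indel records", sum(indel & !multi))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = length(pos))
  counts <- .count_gt(gt)
  malformed <- counts$malformed & keep
  log_skip("records with malformed genotype fields", sum(malformed))
  keep <- keep & !counts$malformed & counts$n > 0
  if (!any(invariant[keep])) {
    warn("VCF contains no invariant records: diversity denominators will be variant-only")
  }
  chrom <- chrom[keep]; pos <- pos[keep]
  n <- counts$n[keep]; n_alt <- counts$alt[keep]
  inv <- invariant[keep] | n_alt == 0L
  hit <- .match_interval(chrom, pos, class_table)
  log_skip("sites outside any class interval", sum(is.na(hit)))
  ok <- !is.na(hit)
  cls <- ifelse(inv[ok], "invariant",
                ifelse(class_table$class[hit[ok]] %in% c("missense", "synonymous"),
                       class_table$class[hit[ok]], "other"))
  tibble(
    chrom = chrom[ok], pos = pos[ok],
    gene_id = class_table$gene_id[hit[ok]],
    site_class = cls,
    n_chromosomes = n[ok], n_alt = n_alt[ok],
    p_ref = 1 - n_alt[ok] / n[ok], p_alt = n_alt[ok] / n[ok]
  ) |> arrange(.data$gene_id, .data$chrom, .data$pos)
}

# tally 0/1 alleles across diploid GT strings; half calls and anything not
# matching a diploid 0/1 genotype count as missing; a record whose every call
# is unparseable (but not "./.") is flagged malformed
.count_gt <- function(gt) {
  n <- alt <- integer(nrow(gt))
  malformed <- logical(nrow(gt))
  for (i in seq_len(nrow(gt))) {
    g <- gt[i, ]
    g[is.na(g)] <- "./."
    called <- grepl("^[01][/|][01]$", g)
    missing <- grepl("^\\.[/|]\\.$", g)
    if (!any(called) && !all(missing)) malformed[i] <- TRUE
    a1 <- substr(g[called], 1, 1)
    a2 <- substr(g[called], 3, 3)
    n[i] <- 2L * sum(called)
    alt[i] <- sum(a1 == "1") + sum(a2 == "1")
  }
  list(n = n, alt = alt, malformed = malformed)
}

#' Write a sites tibble as a VCF with fabricated genotype columns
#'
#' Serialises per-site allele counts back to a VCF 4.2 file, assigning
#' alternate alleles and missing genotypes to pseudo-individuals so the
#' per-site `(n_chromosomes, n_alt)` pair is reproduced exactly. Mainly used
#' to exercise the VCF reader on generated data.
#'
#' @param sites Sites tibble (one gene or many).
#' @param n_ind Number of diploid individuals (columns); must satisfy
#'   `2 * n_ind >= max(n_chromosomes)`.
#' @param path Output path.
#' @param seed Seed for the (arbitrary) placement of alleles.
#' @export
write_sites_vcf <- function(sites, n_ind, path, seed = 1L) {
  stopifnot(2L * n_ind >= max(sites$n_chromosomes))
  with_seed(seed, {
    hdr <- c("##fileformat=VCFv4.2",
             "##source=specsel synthetic genotypes",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", paste0("ind", seq_len(n_ind))),
                   collapse = "\t"))
    rows <- character(nrow(sites))
    for (i in seq_len(nrow(sites))) {
      n_called <- sites$n_chromosomes[i] / 2L
      gts <- rep("./.", n_ind)
      called_idx <- sample.int(n_ind, n_called)
      alleles <- integer(2L * n_called)
      if (sites$n_alt[i] > 0) {
        alleles[sample.int(2L * n_called, sites$n_alt[i])] <- 1L
      }
      gts[called_idx] <- paste(alleles[c(TRUE, FALSE)], alleles[c(FALSE, TRUE)],
                               sep = "/")
      alt <- if (sites$n_alt[i] > 0) "G" else "."
      rows[i] <- paste(c(sites$chrom[i], sites$pos[i], ".", "A", alt, ".",
                         "PASS", ".", "GT", gts), collapse = "\t")
    }
    writeLines(c(hdr, rows), path)
  })
  invisible(path)
}

#' Write / read the per-gene results table
#'
#' TSV with a stable column order (as supplied) and `NA` encoded literally.
#'
#' @param table A per-gene tibble (e.g. from [gene_selection_stats()] or
#'   [build_analysis_table()]).
#' @param path Output path.
#' @export
write_gene_table <- function(table, path) {
  write_tsv(table, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' @rdname write_gene_table
#' @export
read_gene_table <- function(path) {
  read_tsv(path, show_col_types = FALSE, progress = FALSE, na = "NA")
}

#' Validate a sites tibble
#'
#' Checks the per-site invariants: frequencies sum to one, at least two
#' chromosomes for sites used in diversity statistics, invariant sites carry
#' no alternate alleles.
#'
#' @inheritParams gene_tajima_d
#' @return Invisibly `TRUE`.
#' @export
validate_sites <- function(sites) {
  need <- c("gene_id", "site_class", "n_chromosomes", "n_alt")
  if (!all(need %in% names(sites))) {
    stop_format(paste("sites table needs columns:", paste(need, collapse = ", ")))
  }
  if (any(sites$n_chromosomes < 2L)) stop_format("sites with n_chromosomes < 2")
  if (any(sites$n_alt < 0L | sites$n_alt > sites$n_chromosomes)) {
    stop_format("alternate-allele counts outside [0, n]")
  }
  if (any(sites$site_class == "invariant" & sites$n_alt != 0L)) {
    stop_format("invariant sites must have no alternate alleles")
  }
  if (all(c("p_ref", "p_alt") %in% names(sites))) {
    if (any(abs(sites$p_ref + sites$p_alt - 1) > 1e-12)) {
      stop_format("allele frequencies do not sum to 1")
    }
  }
  invisible(TRUE)
}
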