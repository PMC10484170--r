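# Nei-Gojobori (1986) pairwise dN/dS: fractional synonymous/nonsynonymous site
# counting per codon, pathway-averaged difference counting between codons, and
# the Jukes-Cantor multiple-hit correction. Per-codon quantities are
# precomputed once into lookup tables so whole-gene estimates are table sums.

.codon_env <- new.env(parent = emptyenv())

.codon_data <- function() {
  if (is.null(.codon_env$codons)) {
    bases <- c("A", "C", "G", "T")
    grid <- expand.grid(p3 = bases, p2 = bases, p1 = bases,
                        stringsAsFactors = FALSE)
    codons <- paste0(grid$p1, grid$p2, grid$p3)
    aa <- unname(Biostrings::GENETIC_CODE[codons])
    .codon_env$codons <- codons
    .codon_env$aa <- aa
    .codon_env$sense <- aa != "*"
    .codon_env$bases <- bases
  }
  .codon_env
}

# all nine single-base mutants of a codon, as (position, codon) pairs
.codon_mutants <- function(codon) {
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  pos <- integer(0)
  for (p in 1:3) {
    ref <- substr(codon, p, p)
    for (b in setdiff(bases, ref)) {
      mut <- codon
      substr(mut, p, p) <- b
      out <- c(out, mut)
      pos <- c(pos, p)
    }
  }
  list(pos = pos, codon = out)
}

#' Synonymous and nonsynonymous site counts for one codon
#'
#' Counts the expected number of synonymous (`s_sites`) and nonsynonymous
#' (`n_sites`) sites in a single sense codon under the Nei-Gojobori (1986)
#' mutational scheme: at each of the three positions the synonymous fraction
#' is the proportion of the possible single-base changes that preserve the
#' encoded amino acid. The two quantities always sum to 3 (or to the number of
#' counted positions when `stop_handling = "excluded"`).
#'
#' @param codon A single codon string over `A`, `C`, `G`, `T` encoding a sense
#'   amino acid (standard genetic code).
#' @param stop_handling How mutations *to* stop codons enter the site count:
#'   `"nonsynonymous"` (default) counts them as nonsynonymous changes with the
#'   per-position denominator fixed at 3; `"excluded"` removes them from the
#'   denominator.
#' @return A named numeric vector with elements `n_sites` and `s_sites`.
#' @examples
#' codon_site_counts("TTT") # c(n_sites = 8/3, s_sites = 1/3)
#' codon_site_counts("ATG") # no synonymous single-base change exists
#' @export
codon_site_counts <- function(codon,
                              stop_handling = c("nonsynonymous", "excluded")) {
  stop_handling <- match.arg(stop_handling)
  cd <- .codon_data()
  if (!is.character(codon) || length(codon) != 1L || nchar(codon) != 3L) {
    stop_format("`codon` must be a single 3-base string")
  }
  i <- match(codon, cd$codons)
  if (is.na(i)) stop_format(sprintf("'%s' contains a non-ACGT base", codon))
  if (!cd$sense[i]) stop_format(sprintf("'%s' is a stop codon", codon))
  tab <- .site_count_table(stop_handling)
  c(n_sites = tab$n[i], s_sites = tab$s[i])
}

.site_count_table <- function(stop_handling = "nonsynonymous") {
  cd <- .codon_data()
  key <- paste0("sites_", stop_handling)
  if (is.null(.codon_env[[key]])) {
    n <- s <- rep(NA_real_, 64L)
    for (i in which(cd$sense)) {
      muts <- .codon_mutants(cd$codons[i])
      aa0 <- cd$aa[i]
      aa1 <- cd$aa[match(muts$codon, cd$codons)]
      s_i <- n_pos <- 0
      for (p in 1:3) {
        sel <- muts$pos == p
        aap <- aa1[sel]
        if (stop_handling == "excluded") aap <- aap[aap != "*"]
        denom <- length(aap)
        if (denom > 0) {
          s_i <- s_i + sum(aap == aa0) / denom
          n_pos <- n_pos + 1
        }
      }
      s[i] <- s_i
      n[i] <- n_pos - s_i
    }
    .codon_env[[key]] <- list(n = n, s = s)
  }
  .codon_env[[key]]
}

#' Site counts for a whole coding sequence
#'
#' Sums [codon_site_counts()] over the codons of a gapless coding sequence.
#' Codons containing bases other than A/C/G/T and stop codons are excluded
#' from the totals (their count is reported).
#'
#' @param seq A gapless nucleotide string whose length is divisible by 3.
#' @inheritParams codon_site_counts
#' @return A one-row tibble: `n_sites`, `s_sites`, `codons_counted`,
#'   `codons_skipped`.
#' @export
count_sequence_sites <- function(seq,
                                 stop_handling = c("nonsynonymous", "excluded")) {
  stop_handling <- match.arg(stop_handling)
  if (!is.character(seq) || length(seq) != 1L) {
    stop_format("`seq` must be a single string")
  }
  if (nchar(seq) %% 3L != 0L) {
    stop_format("sequence length is not divisible by 3")
  }
  cd <- .codon_data()
  idx <- .seq_to_codon_idx(seq)
  ok <- !is.na(idx) & cd$sense[pmax(idx, 1L)]
  ok[is.na(idx)] <- FALSE
  tab <- .site_count_table(stop_handling)
  tibble(
    n_sites = sum(tab$n[idx[ok]]),
    s_sites = sum(tab$s[idx[ok]]),
    codons_counted = sum(ok),
    codons_skipped = sum(!ok)
  )
}

.seq_to_codon_idx <- function(seq) {
  cd <- .codon_data()
  n <- nchar(seq) %/% 3L
  if (n == 0L) return(integer(0))
  starts <- 3L * (seq_len(n) - 1L) + 1L
  match(substring(seq, starts, starts + 2L), cd$codons)
}

.PERMS <- list(
  matrix(1L, 1, 1),
  rbind(c(1L, 2L), c(2L, 1L)),
  rbind(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
        c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
)

# pathway-averaged differences between two sense codons; returns nd, sd and
# whether the stop-crossing fallback was used
.pair_differences <- function(codon_a, codon_b) {
  cd <- .codon_data()
  diff_pos <- which(strsplit(codon_a, "")[[1]] != strsplit(codon_b, "")[[1]])
  k <- length(diff_pos)
  if (k == 0L) return(list(nd = 0, sd = 0, stop_fallback = FALSE))
  perms <- .PERMS[[k]]
  n_path <- nrow(perms)
  nd <- sd_ <- numeric(n_path)      # stop-free classification
  nd_fb <- sd_fb <- numeric(n_path) # fallback: stop steps are nonsynonymous
  has_stop <- logical(n_path)
  for (r in seq_len(n_path)) {
    cur <- codon_a
    for (p in diff_pos[perms[r, ]]) {
      nxt <- cur
      substr(nxt, p, p) <- substr(codon_b, p, p)
      aa_cur <- cd$aa[match(cur, cd$codons)]
      aa_nxt <- cd$aa[match(nxt, cd$codons)]
      stop_step <- aa_cur == "*" || aa_nxt == "*"
      syn <- !stop_step && aa_cur == aa_nxt
      if (stop_step) has_stop[r] <- TRUE
      nd[r] <- nd[r] + as.numeric(!syn)
      sd_[r] <- sd_[r] + as.numeric(syn)
      nd_fb[r] <- nd_fb[r] + as.numeric(!syn)
      sd_fb[r] <- sd_fb[r] + as.numeric(syn)
      cur <- nxt
    }
  }
  if (any(!has_stop)) {
    keep <- !has_stop
    list(nd = mean(nd[keep]), sd = mean(sd_[keep]), stop_fallback = FALSE)
  } else {
    list(nd = mean(nd_fb), sd = mean(sd_fb), stop_fallback = TRUE)
  }
}

#' Pathway-averaged substitution counts between two codons
#'
#' Enumerates all orderings of the single-base substitutions separating two
#' sense codons, classifies every step as synonymous or nonsynonymous, and
#' averages over the valid pathways (Nei-Gojobori 1986). Pathways passing
#' through a stop codon are excluded whenever at least one stop-free pathway
#' exists; if every pathway crosses a stop, all pathways are used with
#' stop-crossing steps counted as nonsynonymous and the pair is flagged.
#'
#' @param codon_a,codon_b Sense codons (3-base strings over A/C/G/T).
#' @return A list with `nd` (nonsynonymous differences), `sd` (synonymous
#'   differences) and `stop_fallback` (logical flag). `nd + sd` equals the
#'   number of differing positions.
#' @examples
#' codon_pair_differences("TTT", "GTA") # (1.5, 0.5): average of two pathways
#' @export
codon_pair_differences <- function(codon_a, codon_b) {
  cd <- .codon_data()
  ia <- match(codon_a, cd$codons)
  ib <- match(codon_b, cd$codons)
  if (is.na(ia) || is.na(ib)) stop_format("codons must be 3-base ACGT strings")
  if (!cd$sense[ia] || !cd$sense[ib]) stop_format("stop codons are not counted")
  .pair_differences(codon_a, codon_b)
}

# 64 x 64 lookup matrices of pathway-averaged nd/sd (sense pairs only)
.diff_tables <- function() {
  if (is.null(.codon_env$nd_tab)) {
    cd <- .codon_data()
    nd <- sd_ <- matrix(NA_real_, 64, 64)
    fb <- matrix(FALSE, 64, 64)
    sense_idx <- which(cd$sense)
    for (i in sense_idx) {
      for (j in sense_idx) {
        if (j < i) next
        d <- .pair_differences(cd$codons[i], cd$codons[j])
        nd[i, j] <- nd[j, i] <- d$nd
        sd_[i, j] <- sd_[j, i] <- d$sd
        fb[i, j] <- fb[j, i] <- d$stop_fallback
      }
    }
    .codon_env$nd_tab <- nd
    .codon_env$sd_tab <- sd_
    .codon_env$fb_tab <- fb
  }
  list(nd = .codon_env$nd_tab, sd = .codon_env$sd_tab, fb = .codon_env$fb_tab)
}

#' Jukes-Cantor distance correction
#'
#' `d = -(3/4) log(1 - (4/3) p)`, the expected number of substitutions per
#' site given an observed proportion `p` of differing sites under the
#' one-parameter substitution model. Undefined (returns `NA`) for
#' `p >= 3/4` (saturation).
#'
#' @param p Proportion(s) of observed differences, in `[0, 3/4)`.
#' @return Corrected distance(s); `NA` where the correction is undefined.
#' @export
jukes_cantor <- function(p) {
  d <- rep(NA_real_, length(p))
  ok <- !is.na(p) & p >= 0 & p < 0.75
  d[ok] <- -0.75 * log(1 - (4 / 3) * p[ok])
  d
}

# single-pair estimate; a and b are equal-length gapless codon sequences
.dnds_one <- function(seq_a, seq_b, stop_handling = "nonsynonymous") {
  cd <- .codon_data()
  if (nchar(seq_a) != nchar(seq_b)) stop_format("aligned sequences differ in length")
  if (nchar(seq_a) %% 3L != 0L) stop_format("alignment length not divisible by 3")
  if (grepl("-", seq_a, fixed = TRUE) || grepl("-", seq_b, fixed = TRUE)) {
    stop_format("alignments must be gapless")
  }
  ia <- .seq_to_codon_idx(seq_a)
  ib <- .seq_to_codon_idx(seq_b)
  ok <- !is.na(ia) & !is.na(ib)
  ok[ok] <- cd$sense[ia[ok]] & cd$sense[ib[ok]]
  tab <- .site_count_table(stop_handling)
  dt <- .diff_tables()
  n_a <- sum(tab$n[ia[ok]]); s_a <- sum(tab$s[ia[ok]])
  n_b <- sum(tab$n[ib[ok]]); s_b <- sum(tab$s[ib[ok]])
  n_sites <- (n_a + n_b) / 2
  s_sites <- (s_a + s_b) / 2
  pairs <- cbind(ia[ok], ib[ok])
  nd <- sum(dt$nd[pairs])
  sd_ <- sum(dt$sd[pairs])
  n_fb <- sum(dt$fb[pairs])
  p_n <- if (n_sites > 0) nd / n_sites else NA_real_
  p_s <- if (s_sites > 0) sd_ / s_sites else NA_real_
  d_n <- jukes_cantor(p_n)
  d_s <- jukes_cantor(p_s)
  saturated <- if (is.na(p_s)) NA else (p_s >= 0.75 || (!is.na(d_s) && d_s > 1))
  dnds <- if (!is.na(d_s) && d_s > 0 && !is.na(d_n)) d_n / d_s else NA_real_
  tibble(
    codons_used = sum(ok), codons_skipped = sum(!ok),
    n_sites = n_sites, s_sites = s_sites,
    nd = nd, sd = sd_, p_n = p_n, p_s = p_s,
    d_n = d_n, d_s = d_s, dnds = dnds,
    saturated = saturated, stop_fallback_codons = n_fb
  )
}

#' Pairwise Nei-Gojobori dN/dS for aligned codon sequence pairs
#'
#' For each gene's gapless pairwise codon alignment, computes synonymous and
#' nonsynonymous site counts (averaged between the two sequences),
#' pathway-averaged difference counts, the proportions `p_n = nd / N` and
#' `p_s = sd / S`, and Jukes-Cantor corrected rates `d_n`, `d_s`. Codons where
#' either sequence carries an ambiguous base or a stop are dropped pairwise so
#' sites and differences stay consistent. A gene is flagged `saturated` when
#' `d_s > 1` or the correction is undefined; `dnds` is `NA` when `d_s = 0`.
#'
#' @param pairs A data frame with columns `gene_id`, `seq_a`, `seq_b`
#'   (equal-length gapless codon alignments), e.g. from [read_codon_pairs()].
#' @inheritParams codon_site_counts
#' @return A tibble with one row per gene: `gene_id`, `codons_used`,
#'   `codons_skipped`, `n_sites`, `s_sites`, `nd`, `sd`, `p_n`, `p_s`, `d_n`,
#'   `d_s`, `dnds`, `saturated`, `stop_fallback_codons`.
#' @export
pairwise_dnds <- function(pairs,
                          stop_handling = c("nonsynonymous", "excluded")) {
  stop_handling <- match.arg(stop_handling)
  stopifnot(is.data.frame(pairs),
            all(c("gene_id", "seq_a", "seq_b") %in% names(pairs)))
  res <- map2(pairs$seq_a, pairs$seq_b, .dnds_one,
              stop_handling = stop_handling) |> list_rbind()
  bind_cols(tibble(gene_id = pairs$gene_id), res)
}

#' Read pairwise codon alignments from FASTA
#'
#' Accepts either a single FASTA file holding exactly two aligned sequences
#' (one gene) or a directory of such files; the gene identifier is the file
#' base name without extension.
#'
#' @param path A FASTA file or a directory of FASTA files (`.fa`, `.fasta`).
#' @return A tibble with columns `gene_id`, `seq_a`, `seq_b`.
#' @export
read_codon_pairs <- function(path) {
  files <- if (dir.exists(path)) {
    list.files(path, pattern = "\\.(fa|fasta)$", full.names = TRUE)
  } else {
    path
  }
  if (length(files) == 0L) stop_format("no FASTA files found")
  rows <- map(files, function(f) {
    ss <- Biostrings::readDNAStringSet(f)
    if (length(ss) != 2L) {
      stop_format(sprintf("'%s' must contain exactly two aligned sequences", f))
    }
    tibble(gene_id = sub("\\.(fa|fasta)$", "", basename(f)),
           seq_a = as.character(ss[[1]]), seq_b = as.character(ss[[2]]))
  })
  list_rbind(rows)
}
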