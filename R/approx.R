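# Approximate (counting-based) Ka/Ks estimators: NG, LWL, LPB and the
# Tzeng-style modified variants MLWL, MLPB. The YN and MYN iterative
# estimators live in yn.R.

check_coding_pair <- function(seq1, seq2) {
  if (nchar(seq1) != nchar(seq2)) {
    stop("aligned sequences differ in length", call. = FALSE)
  }
  if (nchar(seq1) == 0) stop("empty alignment", call. = FALSE)
}

assert_no_stops <- function(counts, tab) {
  bad <- !tab$sense
  if (any(counts[bad, ] > 0) || any(counts[, bad] > 0)) {
    stop("alignment contains in-frame stop codons; run clean_codon_alignment() first",
         call. = FALSE)
  }
}

new_kaks_row <- function(sequence, method, ka, ks, s_sites, n_sites,
                         sd, nd, length, kappa = NA_real_,
                         model = NA_character_, converged = TRUE) {
  ka_ks <- if (isTRUE(is.finite(ka)) && isTRUE(is.finite(ks)) && ks > 0) {
    ka / ks
  } else {
    NA_real_
  }
  tibble::tibble(
    sequence = sequence, method = method,
    ka = ka, ks = ks, ka_ks = ka_ks,
    p_value = fisher_test_kaks(sd, nd, s_sites, n_sites),
    length = length, s_sites = s_sites, n_sites = n_sites,
    sd = sd, nd = nd,
    substitutions = if (is.na(sd) || is.na(nd)) NA_real_ else sd + nd,
    kappa = kappa, model = model, converged = converged
  )
}

#' Jukes-Cantor multiple-hit correction
#'
#' Corrects an observed proportion of differing sites for multiple
#' substitutions: `d = -(3/4) * log(1 - 4p/3)`. Saturated proportions
#' (`p >= 3/4`) are returned as `NA`.
#'
#' @param p Observed difference proportion(s) in `[0, 1]`.
#' @return Corrected distance(s); `NA` where saturated.
#' @examples
#' jc_correct(c(0, 0.3))
#' @export
jc_correct <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p) & p >= 0 & p < 0.75
  out[ok] <- -0.75 * log(1 - 4 * p[ok] / 3)
  out
}

#' Expected synonymous and nonsynonymous sites of a coding sequence
#'
#' Nei-Gojobori style site counting: each codon position contributes the
#' fraction of its single-nucleotide mutations that are synonymous to the
#' synonymous-site total, with mutations creating stop codons excluded from
#' the per-position divisor.
#'
#' @param seq In-frame, gap-free coding sequence (A/C/G/T).
#' @param code_table NCBI translation-table number.
#' @return Named numeric vector `c(s_sites, n_sites)`.
#' @examples
#' ng_site_counts("TTT") # c(1/3, 8/3)
#' @export
ng_site_counts <- function(seq, code_table = 1L) {
  code <- genetic_code(code_table)
  tab <- codon_pair_tables(code)
  idx <- codon_indices(toupper(seq))
  if (any(!tab$sense[idx])) {
    stop("sequence contains stop codons", call. = FALSE)
  }
  c(s_sites = sum(tab$ng_s[idx]), n_sites = sum(tab$ng_n[idx]))
}

#' Pathway-averaged synonymous and nonsynonymous differences
#'
#' For every differing codon pair, classifies each single-nucleotide step as
#' synonymous or nonsynonymous, averaging over all orderings of the steps.
#' Pathways passing through stop codons are excluded from the average unless
#' every pathway does, in which case all are kept so that the synonymous and
#' nonsynonymous differences always sum to the nucleotide Hamming distance.
#'
#' @param seq1,seq2 Equal-length, in-frame, gap- and stop-free sequences.
#' @param code_table NCBI translation-table number.
#' @return Named numeric vector `c(sd, nd)`.
#' @examples
#' ng_difference_counts("TTT", "GTA") # c(0.5, 1.5)
#' @export
ng_difference_counts <- function(seq1, seq2, code_table = 1L) {
  check_coding_pair(seq1, seq2)
  code <- genetic_code(code_table)
  tab <- codon_pair_tables(code)
  counts <- codon_pair_counts(toupper(seq1), toupper(seq2))
  assert_no_stops(counts, tab)
  c(sd = sum(counts * tab$sd), nd = sum(counts * tab$nd))
}

#' @rdname kaks_methods
#' @export
ng86 <- function(seq1, seq2, code_table = 1L, sequence = "pair") {
  check_coding_pair(seq1, seq2)
  seq1 <- toupper(seq1); seq2 <- toupper(seq2)
  code <- genetic_code(code_table)
  tab <- codon_pair_tables(code)
  counts <- codon_pair_counts(seq1, seq2)
  assert_no_stops(counts, tab)
  rowc <- rowSums(counts); colc <- colSums(counts)
  s_sites <- (sum(rowc * tab$ng_s, na.rm = TRUE) +
              sum(colc * tab$ng_s, na.rm = TRUE)) / 2
  n_sites <- (sum(rowc * tab$ng_n, na.rm = TRUE) +
              sum(colc * tab$ng_n, na.rm = TRUE)) / 2
  sd <- sum(counts * tab$sd)
  nd <- sum(counts * tab$nd)
  ks <- if (s_sites > 0) jc_correct(sd / s_sites) else NA_real_
  ka <- if (n_sites > 0) jc_correct(nd / n_sites) else NA_real_
  new_kaks_row(sequence, "NG", ka, ks, s_sites, n_sites, sd, nd,
               nchar(seq1))
}

# Degeneracy-class site and difference counts shared by the LWL family.
# Returns per-class (0-, 2-, 4-fold) site counts L, transition counts ts and
# transversion counts tv (pathway-averaged, classes averaged across the two
# codons of each step).
lwl_class_counts <- function(counts, tab, adjusted = FALSE) {
  rowc <- rowSums(counts); colc <- colSums(counts)
  L <- (as.numeric(rowc %*% replace(tab$fold_count, is.na(tab$fold_count), 0)) +
        as.numeric(colc %*% replace(tab$fold_count, is.na(tab$fold_count), 0))) / 2
  arr <- if (adjusted) tab$steps_adj else tab$steps_raw
  ts <- tv <- numeric(3)
  for (cls in 1:3) {
    ts[cls] <- sum(counts * arr[, , cls, 1L]) + sum(counts * arr[, , cls, 2L])
    tv[cls] <- sum(counts * arr[, , cls, 3L])
  }
  list(L = L, ts = ts, tv = tv)
}

# K2P components per degeneracy class; classes with no sites contribute 0
lwl_ab <- function(cc) {
  A <- B <- numeric(3)
  for (cls in 1:3) {
    if (cc$L[cls] <= 0) next
    ab <- k2p_components(cc$ts[cls] / cc$L[cls], cc$tv[cls] / cc$L[cls])
    A[cls] <- ab[["A"]]; B[cls] <- ab[["B"]]
  }
  list(A = A, B = B)
}

lwl_family <- function(seq1, seq2, code_table, sequence, flavour,
                       kappa = NULL) {
  check_coding_pair(seq1, seq2)
  seq1 <- toupper(seq1); seq2 <- toupper(seq2)
  code <- genetic_code(code_table)
  tab <- codon_pair_tables(code)
  counts <- codon_pair_counts(seq1, seq2)
  assert_no_stops(counts, tab)
  modified <- flavour %in% c("MLWL", "MLPB")
  cc <- lwl_class_counts(counts, tab, adjusted = modified)
  ab <- lwl_ab(cc)
  L0 <- cc$L[1]; L2 <- cc$L[2]; L4 <- cc$L[3]
  A0 <- ab$A[1]; A2 <- ab$A[2]; A4 <- ab$A[3]
  B0 <- ab$B[1]; B2 <- ab$B[2]; B4 <- ab$B[3]

  if (modified) {
    if (is.null(kappa)) {
      Ltot <- sum(cc$L)
      kappa <- k2p_kappa(sum(cc$ts) / Ltot, sum(cc$tv) / Ltot, fallback = 1)
    }
    ts_frac <- kappa / (kappa + 2)
  } else {
    kappa <- NA_real_
    ts_frac <- 1 / 3
  }
  s_sites <- L2 * ts_frac + L4
  n_sites <- L0 + L2 * (1 - ts_frac)

  if (flavour %in% c("LWL", "MLWL")) {
    ks <- if (s_sites > 0) (L2 * A2 + L4 * (A4 + B4)) / s_sites else NA_real_
    ka <- if (n_sites > 0) (L0 * (A0 + B0) + L2 * B2) / n_sites else NA_real_
  } else { # LPB / MLPB
    ks <- if (L2 + L4 > 0) (L2 * A2 + L4 * A4) / (L2 + L4) + B4 else NA_real_
    ka <- if (L0 + L2 > 0) (L0 * B0 + L2 * B2) / (L0 + L2) + A0 else NA_real_
  }
  sd <- cc$ts[2] + cc$ts[3] + cc$tv[3]
  nd <- cc$ts[1] + cc$tv[1] + cc$tv[2]
  new_kaks_row(sequence, flavour, ka, ks, s_sites, n_sites, sd, nd,
               nchar(seq1), kappa = kappa)
}

#' Approximate Ka/Ks estimators for one aligned coding pair
#'
#' Counting-based estimators of the nonsynonymous (Ka) and synonymous (Ks)
#' substitution rates and their ratio for a pair of aligned, gap- and
#' stop-free, in-frame coding sequences:
#'
#' * `ng86()` - Nei-Gojobori: exact mutation enumeration for site counts,
#'   pathway-averaged difference counts, Jukes-Cantor correction.
#' * `lwl85()` - Li-Wu-Luo: 0/2/4-fold degeneracy classes with K2P-corrected
#'   per-class transition/transversion distances.
#' * `lpb93()` - Li-Pamilo-Bianchi: the LWL site classes with the revised
#'   combination of per-class distances that removes the assumption of equal
#'   transition rates across classes.
#' * `mlwl()` / `mlpb()` - modified LWL/LPB: an explicitly estimated
#'   transition/transversion rate ratio kappa reapportions 2-fold sites
#'   between the synonymous and nonsynonymous totals (a 2-fold site is
#'   synonymous for the fraction `kappa/(kappa + 2)` of mutations), and
#'   synonymous transversions at 2-fold sites (the arginine and isoleucine
#'   codon families) are counted as synonymous.
#'
#' @param seq1,seq2 Aligned coding sequences (equal length, divisible by 3,
#'   A/C/G/T only, no in-frame stops). Use [clean_codon_alignment()] first
#'   for raw alignments.
#' @param code_table NCBI translation-table number (default 1, standard code).
#' @param sequence Label used in the `sequence` column of the result.
#' @param kappa Optional fixed transition/transversion rate ratio for
#'   `mlwl()`/`mlpb()`; by default it is estimated from the pooled K2P
#'   distance components.
#' @return A one-row tibble with columns `sequence`, `method`, `ka`, `ks`,
#'   `ka_ks`, `p_value`, `length`, `s_sites`, `n_sites`, `sd`, `nd`,
#'   `substitutions`, `kappa`, `model`, `converged`. Undefined quantities
#'   (saturation, `ks = 0`) are `NA`, never infinite.
#' @seealso [yn00()], [myn()], [fit_gy()], [kaks()] for the batch interface.
#' @examples
#' ng86("TTTATG", "TTCATG")
#' lwl85("GGGAAACCC", "GGAAAGCCA")
#' @name kaks_methods
NULL

#' @rdname kaks_methods
#' @export
lwl85 <- function(seq1, seq2, code_table = 1L, sequence = "pair") {
  lwl_family(seq1, seq2, code_table, sequence, "LWL")
}

#' @rdname kaks_methods
#' @export
lpb93 <- function(seq1, seq2, code_table = 1L, sequence = "pair") {
  lwl_family(seq1, seq2, code_table, sequence, "LPB")
}

#' @rdname kaks_methods
#' @export
mlwl <- function(seq1, seq2, code_table = 1L, sequence = "pair",
                 kappa = NULL) {
  lwl_family(seq1, seq2, code_table, sequence, "MLWL", kappa = kappa)
}

#' @rdname kaks_methods
#' @export
mlpb <- function(seq1, seq2, code_table = 1L, sequence = "pair",
                 kappa = NULL) {
  lwl_family(seq1, seq2, code_table, sequence, "MLPB", kappa = kappa)
}

#' Fisher exact test for Ka/Ks significance
#'
#' Two-tailed Fisher exact test on the 2x2 table of rounded synonymous /
#' nonsynonymous differences against the remaining synonymous /
#' nonsynonymous sites, as reported in the `P-Value` column of the
#' tab-delimited output.
#'
#' @param sd,nd Synonymous and nonsynonymous differences.
#' @param s_sites,n_sites Synonymous and nonsynonymous site counts.
#' @return The p-value; 1 for degenerate tables, `NA` if any argument is
#'   missing.
#' @examples
#' fisher_test_kaks(5, 5, 10, 10)
#' @export
fisher_test_kaks <- function(sd, nd, s_sites, n_sites) {
  if (any(is.na(c(sd, nd, s_sites, n_sites)))) return(NA_real_)
  tab <- round(matrix(c(sd, s_sites - sd, nd, n_sites - nd), 2L,
                      byrow = TRUE))
  tab[tab < 0] <- 0
  tryCatch(stats::fisher.test(tab)$p.value, error = function(e) 1)
}
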