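# Selection on non-coding sequences: the substitution rate Kn under JC69,
# K2P or HKY85 multiple-hit corrections, and the statistic xi = Kn/Ks with
# the neutral rate Ks taken from an adjacent coding pair or supplied by the
# user.

#' Substitution counts of a non-coding pair
#'
#' Observed transition (`A<->G`, `T<->C`) and transversion difference
#' proportions and the base frequencies (averaged over both sequences) of a
#' gap-stripped aligned nucleotide pair.
#'
#' @param seq1,seq2 Equal-length gap-free DNA strings (A/C/G/T).
#' @return A list of class `"pair_counts"`: `S`, `V` (transition /
#'   transversion proportions), `pi` (named base frequencies), `pi_R`,
#'   `pi_Y`, `L` (compared sites), and `n_diff`.
#' @examples
#' count_pair("AAAA", "GGAA")
#' @export
count_pair <- function(seq1, seq2) {
  seq1 <- toupper(seq1); seq2 <- toupper(seq2)
  if (nchar(seq1) != nchar(seq2)) {
    stop("aligned sequences differ in length", call. = FALSE)
  }
  c1 <- strsplit(seq1, "")[[1]]
  c2 <- strsplit(seq2, "")[[1]]
  if (length(c1) == 0) stop("empty alignment", call. = FALSE)
  if (!all(c(c1, c2) %in% c("A", "C", "G", "T"))) {
    stop("non-ACGT characters; run clean_nucleotide_alignment() first",
         call. = FALSE)
  }
  diff <- c1 != c2
  ts <- diff & (c1 %in% PURINES) == (c2 %in% PURINES)
  L <- length(c1)
  pi <- pair_base_freqs(seq1, seq2)
  structure(list(
    S = sum(ts) / L, V = sum(diff & !ts) / L, pi = pi,
    pi_R = pi[["A"]] + pi[["G"]], pi_Y = pi[["T"]] + pi[["C"]],
    L = L, n_diff = sum(diff)
  ), class = "pair_counts")
}

as_pair_counts <- function(x) {
  if (inherits(x, "pair_counts")) return(x)
  stop("expected a count_pair() object", call. = FALSE)
}

#' Multiple-hit corrected non-coding distances
#'
#' Corrected substitutions per site (Kn) from the observed transition and
#' transversion proportions of a non-coding pair:
#' * `jc_distance()` - Jukes-Cantor: `-(3/4) log(1 - 4(S+V)/3)`.
#' * `k2p_distance()` - Kimura 2-parameter:
#'   `-(1/2) log(1 - 2S - V) - (1/4) log(1 - 2V)`.
#' * `hky_distance()` - HKY85, which additionally weighs the four base
#'   frequencies:
#'   `Kn = 2 (piT piC / piY + piA piG / piR) a - 2 (piT piC piR / piY + piA piG piY / piR - piY piR) b`
#'   with
#'   `a = -log(1 - S / (2 (piT piC / piY + piA piG / piR)) - (piT piC piR / piY + piA piG piY / piR) V / (2 (piT piC piR + piA piG piY)))`
#'   and `b = -log(1 - V / (2 piY piR))`. At equal base frequencies the HKY
#'   distance reduces exactly to K2P, and JC further requires equal
#'   transition and transversion rates.
#'
#' @param counts A [count_pair()] object.
#' @return The corrected distance, or `NA` when the observed proportions are
#'   outside the model's log domain (saturation).
#' @examples
#' cp <- count_pair("AAAATTTTGGGGCCCC", "AAGATTCTGGAGCCTC")
#' jc_distance(cp); k2p_distance(cp); hky_distance(cp)
#' @name noncoding_distances
NULL

#' @rdname noncoding_distances
#' @export
jc_distance <- function(counts) {
  counts <- as_pair_counts(counts)
  jc_correct(counts$S + counts$V)
}

#' @rdname noncoding_distances
#' @export
k2p_distance <- function(counts) {
  counts <- as_pair_counts(counts)
  ab <- k2p_components(counts$S, counts$V)
  if (anyNA(ab)) NA_real_ else ab[["A"]] + ab[["B"]]
}

#' @rdname noncoding_distances
#' @export
hky_distance <- function(counts) {
  counts <- as_pair_counts(counts)
  pi <- counts$pi
  piA <- pi[["A"]]; piC <- pi[["C"]]; piG <- pi[["G"]]; piT <- pi[["T"]]
  piR <- counts$pi_R; piY <- counts$pi_Y
  if (piR <= 0 || piY <= 0 || piT * piC <= 0 || piA * piG <= 0) {
    return(NA_real_)
  }
  S <- counts$S; V <- counts$V
  cts <- piT * piC / piY + piA * piG / piR
  ctv <- piT * piC * piR / piY + piA * piG * piY / piR
  arg_a <- 1 - S / (2 * cts) - ctv * V / (2 * (piT * piC * piR + piA * piG * piY))
  arg_b <- 1 - V / (2 * piY * piR)
  if (arg_a <= 0 || arg_b <= 0) return(NA_real_)
  a <- -log(arg_a)
  b <- -log(arg_b)
  2 * cts * a - 2 * (ctv - piY * piR) * b
}

noncoding_distance <- function(counts, model) {
  switch(model,
         JC = jc_distance(counts),
         K2P = k2p_distance(counts),
         HKY = hky_distance(counts))
}

#' Selective pressure on non-coding sequences (Kn/Ks)
#'
#' Computes the non-coding substitution rate Kn for each aligned non-coding
#' pair under the chosen nucleotide model and the selection statistic
#' `xi = Kn/Ks`. The neutral rate Ks is taken either from `ks` (a
#' user-specified value) or from adjacent coding pairs in `cds`, whose
#' synonymous rate is estimated with the chosen coding method. When several
#' coding pairs are supplied, one row is produced per non-coding x coding
#' combination, since each neighbour yields its own Ks and hence its own xi.
#' `xi > 1` indicates positive selection, `xi < 1` selective constraint.
#'
#' @param pairs Tibble of non-coding pairs with columns `name`, `seq1`,
#'   `seq2` (as returned by [read_axt()] / [read_fasta_pair()]).
#' @param model Nucleotide correction model: `"HKY"` (default), `"K2P"` or
#'   `"JC"`.
#' @param ks User-specified neutral rate (mutually exclusive with `cds`).
#' @param cds Tibble of adjacent coding pairs (`name`, `seq1`, `seq2`),
#'   cleaned or raw (raw pairs are passed through
#'   [clean_codon_alignment()]).
#' @param cds_method Coding method used on `cds`: one of NG, LWL, LPB,
#'   MLWL, MLPB, YN, MYN, GY, MS, MA.
#' @param code_table NCBI translation-table number for the coding pairs.
#' @param clean Gap/ambiguity-strip the non-coding pairs column-wise first
#'   (default TRUE).
#' @return A tibble with one row per pair (x coding pair), columns
#'   `sequence`, `method` (the nucleotide model), `kn`, `ks`, `kn_ks` (xi),
#'   `ks_source`, `p_value`, `length`, `s_sites`, `n_sites`,
#'   `substitutions`.
#' @examples
#' pairs <- tibble::tibble(name = "toy",
#'                         seq1 = "ACGTACGTACGTACGT",
#'                         seq2 = "ACGTACGAACGTATGT")
#' knks(pairs, model = "K2P", ks = 0.5)
#' @export
knks <- function(pairs, model = c("HKY", "K2P", "JC"), ks = NULL,
                 cds = NULL, cds_method = "MYN", code_table = 1L,
                 clean = TRUE) {
  model <- match.arg(toupper(model[1]), c("HKY", "K2P", "JC"))
  pairs <- as_pair_tbl(pairs)
  if (!is.null(ks) && !is.null(cds)) {
    stop("supply either a user `ks` value or adjacent coding pairs in ",
         "`cds`, not both", call. = FALSE)
  }
  if (is.null(ks) && is.null(cds)) {
    stop("a Ks source is required: `ks` or `cds`", call. = FALSE)
  }
  if (clean) pairs <- clean_nucleotide_alignment(pairs)

  if (!is.null(ks)) {
    stopifnot(is.numeric(ks), length(ks) == 1L)
    ks_tbl <- tibble::tibble(ks = as.numeric(ks), ks_source = "user")
  } else {
    cds <- as_pair_tbl(cds)
    cds_res <- kaks(cds, methods = cds_method, code_table = code_table)
    ks_tbl <- tibble::tibble(
      ks = cds_res$ks,
      ks_source = paste0(cds_res$method, ":", cds_res$sequence)
    )
  }

  out <- vector("list", nrow(pairs) * nrow(ks_tbl))
  r <- 0L
  for (i in seq_len(nrow(pairs))) {
    cp <- count_pair(pairs$seq1[i], pairs$seq2[i])
    kn <- noncoding_distance(cp, model)
    for (j in seq_len(nrow(ks_tbl))) {
      ksj <- ks_tbl$ks[j]
      xi <- if (is.na(kn) || is.na(ksj) || ksj <= 0) NA_real_ else kn / ksj
      r <- r + 1L
      out[[r]] <- tibble::tibble(
        sequence = pairs$name[i], method = model,
        kn = kn, ks = ksj, kn_ks = xi, ks_source = ks_tbl$ks_source[j],
        p_value = NA_real_, length = cp$L,
        s_sites = NA_real_, n_sites = NA_real_,
        substitutions = cp$n_diff
      )
    }
  }
  dplyr::bind_rows(out)
}
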