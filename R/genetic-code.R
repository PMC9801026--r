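# Genetic-code tables and per-position codon degeneracy classification.
# Every counting method in the package sits on top of these primitives.

BASES <- c("T", "C", "A", "G")

# 64 codons in TCAG order, first base slowest: TTT, TTC, TTA, TTG, TCT, ...
CODONS64 <- as.vector(t(outer(
  as.vector(t(outer(BASES, BASES, paste0))), BASES, paste0
)))

# NCBI translation tables: amino acids for the 64 codons in TCAG order,
# '*' marks stop codons.
GENETIC_CODE_TABLES <- c(
  `1` = "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG",
  `2` = "FFLLSSSSYY**CCWWLLLLPPPPHHQQRRRRIIMMTTTTNNKKSS**VVVVAAAADDEEGGGG",
  `3` = "FFLLSSSSYY**CCWWTTTTPPPPHHQQRRRRIIMMTTTTNNKKSSRRVVVVAAAADDEEGGGG",
  `4` = "FFLLSSSSYY**CCWWLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG",
  `5` = "FFLLSSSSYY**CCWWLLLLPPPPHHQQRRRRIIMMTTTTNNKKSSSSVVVVAAAADDEEGGGG",
  `6` = "FFLLSSSSYYQQCC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG",
  `9` = "FFLLSSSSYY**CCWWLLLLPPPPHHQQRRRRIIIMTTTTNNNKSSSSVVVVAAAADDEEGGGG",
  `10` = "FFLLSSSSYY**CCCWLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG",
  `11` = "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG",
  `12` = "FFLLSSSSYY**CC*WLLLSPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG",
  `13` = "FFLLSSSSYY**CCWWLLLLPPPPHHQQRRRRIIMMTTTTNNKKSSGGVVVVAAAADDEEGGGG",
  `14` = "FFLLSSSSYYY*CCWWLLLLPPPPHHQQRRRRIIIMTTTTNNNKSSSSVVVVAAAADDEEGGGG",
  `15` = "FFLLSSSSYY*QCC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG",
  `16` = "FFLLSSSSYY*LCC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG",
  `21` = "FFLLSSSSYY**CCWWLLLLPPPPHHQQRRRRIIMMTTTTNNNKSSSSVVVVAAAADDEEGGGG",
  `22` = "FFLLSS*SYY*LCC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG",
  `23` = "FF*LSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG",
  `24` = "FFLLSSSSYY**CCWWLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSSKVVVVAAAADDEEGGGG",
  `25` = "FFLLSSSSYY**CCGWLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG",
  `26` = "FFLLSSSSYY**CC*WLLLAPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG",
  `27` = "FFLLSSSSYYQQCCWWLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG",
  `28` = "FFLLSSSSYYQQCCWWLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG",
  `29` = "FFLLSSSSYYYYCC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG",
  `30` = "FFLLSSSSYYEECC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG",
  `31` = "FFLLSSSSYYEECCWWLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG",
  `32` = "FFLLSSSSYY*WCC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG",
  `33` = "FFLLSSSSYYY*CCWWLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSSKVVVVAAAADDEEGGGG"
)

#' Genetic-code object
#'
#' Builds a genetic-code object for one of the NCBI translation tables.
#' Table 1 is the standard code; the other defined tables (2--33, with the
#' usual gaps in the NCBI numbering) are available by id.
#'
#' @param table_id Integer NCBI translation-table number (default 1, the
#'   standard code).
#' @return A list of class `"genetic_code"` with elements `table_id`,
#'   `codon_to_aa` (named character vector over all 64 codons, `"*"` for
#'   stop), `sense_codons` (codons translating to an amino acid), and
#'   `stop_codons`.
#' @examples
#' gc <- genetic_code()
#' gc$codon_to_aa[["ATG"]]
#' gc$stop_codons
#' @export
genetic_code <- function(table_id = 1L) {
  key <- as.character(as.integer(table_id))
  if (!key %in% names(GENETIC_CODE_TABLES)) {
    stop("unknown NCBI translation table id: ", table_id, call. = FALSE)
  }
  aa <- strsplit(GENETIC_CODE_TABLES[[key]], "")[[1]]
  names(aa) <- CODONS64
  structure(
    list(
      table_id = as.integer(table_id),
      codon_to_aa = aa,
      sense_codons = CODONS64[aa != "*"],
      stop_codons = CODONS64[aa == "*"]
    ),
    class = "genetic_code"
  )
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("Genetic code, NCBI table", x$table_id, "-",
      length(x$sense_codons), "sense codons,",
      length(x$stop_codons), "stop codons\n")
  invisible(x)
}

#' Translate a codon
#'
#' @param codon 3-letter DNA string over A/C/G/T.
#' @param code A [genetic_code()] object.
#' @return One-letter amino-acid symbol, or `"*"` for a stop codon.
#' @examples
#' translate_codon("TTT")
#' translate_codon("TAA")
#' @export
translate_codon <- function(codon, code = genetic_code()) {
  codon <- toupper(codon)
  if (!codon %in% CODONS64) {
    stop("not an unambiguous DNA codon: ", codon, call. = FALSE)
  }
  unname(code$codon_to_aa[codon])
}

# All 9 single-nucleotide neighbours of a codon at one position.
codon_neighbours <- function(codon, position) {
  base <- substr(codon, position, position)
  vapply(setdiff(BASES, base), function(b) {
    `substr<-`(codon, position, position, b)
  }, character(1))
}

#' Degeneracy class of a codon position
#'
#' Classifies a position of a sense codon as non-degenerate (0-fold), 2-fold,
#' or 4-fold degenerate, the classification underlying the LWL family of
#' Ka/Ks estimators. A position is 4-fold if all three possible point
#' mutations are synonymous and 0-fold if none is; everything in between
#' (including the 3-fold isoleucine third position) is binned as 2-fold,
#' following the classical convention. Mutations to stop codons count as
#' nonsynonymous.
#'
#' @param codon Sense codon (3-letter DNA string).
#' @param position Codon position, 1, 2 or 3.
#' @param code A [genetic_code()] object.
#' @return Integer 0, 2 or 4.
#' @examples
#' degeneracy_class("GGG", 3) # 4-fold: glycine
#' degeneracy_class("TTT", 1) # 0-fold
#' degeneracy_class("TTT", 3) # 2-fold
#' @export
degeneracy_class <- function(codon, position, code = genetic_code()) {
  codon <- toupper(codon)
  aa <- code$codon_to_aa[[codon]]
  if (is.null(aa) || aa == "*") {
    stop("degeneracy_class() requires a sense codon, got: ", codon,
         call. = FALSE)
  }
  stopifnot(position %in% 1:3)
  n_syn <- sum(code$codon_to_aa[codon_neighbours(codon, position)] == aa)
  if (n_syn == 3L) 4L else if (n_syn == 0L) 0L else 2L
}
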