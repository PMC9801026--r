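# Reading pairwise alignments (AXT paired blocks, aligned FASTA), gap and
# stop-codon filtering, and the tab-delimited result writer. Sequences are
# upper-cased and U is normalized to T on read; gaps survive reading and are
# removed by the clean_* steps.

normalize_seq <- function(x) {
  stringr::str_replace_all(toupper(x), "U", "T")
}

as_pair_tbl <- function(pairs) {
  if (!is.data.frame(pairs) ||
      !all(c("name", "seq1", "seq2") %in% names(pairs))) {
    stop("expected a data frame with columns name, seq1, seq2",
         call. = FALSE)
  }
  tibble::as_tibble(pairs[, c("name", "seq1", "seq2")])
}

#' Read AXT-style paired alignment blocks
#'
#' Each block is one header line (the pair name) followed by exactly two
#' aligned sequence lines; blocks are separated by one or more blank lines.
#'
#' @param path Path to the file (or a connection).
#' @return A tibble with columns `name`, `seq1`, `seq2`, in input order.
#' @examples
#' f <- tempfile(fileext = ".axt")
#' writeLines(c("pairA", "ATGAAA", "ATGAAG"), f)
#' read_axt(f)
#' @export
read_axt <- function(path) {
  lines <- stringr::str_trim(readLines(path), side = "right")
  blank <- lines == ""
  grp <- cumsum(blank) # runs of non-blank lines share a group id
  out <- list()
  for (g in split(which(!blank), grp[!blank])) {
    if (length(g) != 3L) {
      stop("malformed AXT block starting at line ", g[1],
           ": expected a name line and exactly 2 sequence lines, got ",
           length(g) - 1L, " sequence line(s)", call. = FALSE)
    }
    name <- lines[g[1]]
    s1 <- normalize_seq(lines[g[2]])
    s2 <- normalize_seq(lines[g[3]])
    if (nchar(s1) != nchar(s2)) {
      stop("pair '", name, "': aligned sequences have unequal lengths (",
           nchar(s1), " vs ", nchar(s2), ")", call. = FALSE)
    }
    out[[length(out) + 1L]] <- tibble::tibble(name = name, seq1 = s1,
                                              seq2 = s2)
  }
  if (!length(out)) {
    return(tibble::tibble(name = character(), seq1 = character(),
                          seq2 = character()))
  }
  dplyr::bind_rows(out)
}

#' Read an aligned-FASTA pair
#'
#' Reads a FASTA file containing exactly two aligned records; the pair is
#' named `"name1_vs_name2"`.
#'
#' @param path Path to the FASTA file.
#' @return A one-row tibble with columns `name`, `seq1`, `seq2`.
#' @export
read_fasta_pair <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("the Biostrings package is required to read FASTA input",
         call. = FALSE)
  }
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) != 2L) {
    stop("expected exactly 2 aligned FASTA records, got ", length(recs),
         call. = FALSE)
  }
  s1 <- normalize_seq(as.character(recs[[1]]))
  s2 <- normalize_seq(as.character(recs[[2]]))
  nm <- stringr::str_split_i(names(recs), "\\s+", 1)
  if (nchar(s1) != nchar(s2)) {
    stop("pair '", paste(nm, collapse = "_vs_"),
         "': aligned sequences have unequal lengths (", nchar(s1), " vs ",
         nchar(s2), ")", call. = FALSE)
  }
  tibble::tibble(name = paste0(nm[1], "_vs_", nm[2]), seq1 = s1, seq2 = s2)
}

clean_one_codon_pair <- function(name, s1, s2, code) {
  n <- nchar(s1) - nchar(s1) %% 3L
  if (n < 3L) stop("pair '", name, "': no complete codon columns",
                   call. = FALSE)
  c1 <- substring(s1, seq(1L, n, 3L), seq(3L, n, 3L))
  c2 <- substring(s2, seq(1L, n, 3L), seq(3L, n, 3L))
  valid <- grepl("^[ACGT]{3}$", c1) & grepl("^[ACGT]{3}$", c2)
  is_stop <- rep(FALSE, length(c1))
  is_stop[valid] <- code$codon_to_aa[c1[valid]] == "*" |
    code$codon_to_aa[c2[valid]] == "*"
  keep <- valid & !is_stop
  if (!any(keep)) {
    stop("pair '", name, "': no codon columns remain after filtering",
         call. = FALSE)
  }
  tibble::tibble(
    name = name,
    seq1 = paste(c1[keep], collapse = ""),
    seq2 = paste(c2[keep], collapse = ""),
    removed_codons = sum(!keep) + (nchar(s1) - n) %/% 3L
  )
}

#' Filter a codon alignment to clean, in-frame codon columns
#'
#' Removes, codon-column-wise, every triplet in which either sequence has a
#' gap or ambiguity character, then every remaining column containing a stop
#' codon. The result is ready for the coding estimators. Idempotent.
#'
#' @param pairs Tibble with columns `name`, `seq1`, `seq2`.
#' @param code_table NCBI translation-table number.
#' @return The tibble with filtered `seq1`/`seq2` and a `removed_codons`
#'   column counting dropped codon columns.
#' @examples
#' clean_codon_alignment(tibble::tibble(name = "p",
#'                                      seq1 = "ATG---AAA",
#'                                      seq2 = "ATGCCCAAA"))
#' @export
clean_codon_alignment <- function(pairs, code_table = 1L) {
  pairs <- as_pair_tbl(pairs)
  code <- genetic_code(code_table)
  bad <- nchar(pairs$seq1) != nchar(pairs$seq2)
  if (any(bad)) {
    stop("pair '", pairs$name[which(bad)[1]],
         "': aligned sequences have unequal lengths", call. = FALSE)
  }
  purrr::pmap_dfr(pairs, function(name, seq1, seq2, ...) {
    clean_one_codon_pair(name, normalize_seq(seq1), normalize_seq(seq2),
                         code)
  })
}

#' Filter a non-coding alignment to clean columns
#'
#' Removes, single-column-wise, every alignment column in which either
#' sequence carries a gap or ambiguity character.
#'
#' @inheritParams clean_codon_alignment
#' @return The tibble with filtered sequences and a `removed_columns`
#'   column.
#' @export
clean_nucleotide_alignment <- function(pairs) {
  pairs <- as_pair_tbl(pairs)
  purrr::pmap_dfr(pairs, function(name, seq1, seq2, ...) {
    s1 <- strsplit(normalize_seq(seq1), "")[[1]]
    s2 <- strsplit(normalize_seq(seq2), "")[[1]]
    if (length(s1) != length(s2)) {
      stop("pair '", name, "': aligned sequences have unequal lengths",
           call. = FALSE)
    }
    keep <- s1 %in% c("A", "C", "G", "T") & s2 %in% c("A", "C", "G", "T")
    if (!any(keep)) {
      stop("pair '", name, "': no columns remain after filtering",
           call. = FALSE)
    }
    tibble::tibble(name = name, seq1 = paste(s1[keep], collapse = ""),
                   seq2 = paste(s2[keep], collapse = ""),
                   removed_columns = sum(!keep))
  })
}

fmt_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 6L, format = "g"))
}

#' Write results as tab-delimited text
#'
#' One header row, one row per (pair, method). Coding results use the
#' columns Sequence, Method, Ka, Ks, Ka/Ks, P-Value, Length, S-Sites,
#' N-Sites, Substitutions; non-coding results replace the first three rate
#' columns with Kn, Ks, Kn/Ks. Undefined values are written as `"NA"`;
#' numbers carry 6 significant digits.
#'
#' @param results A result tibble from [kaks()] or [knks()] (the two kinds
#'   may not be mixed in one file).
#' @param path Output path or connection.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  noncoding <- "kn" %in% names(results)
  header <- if (noncoding) {
    c("Sequence", "Method", "Kn", "Ks", "Kn/Ks", "P-Value", "Length",
      "S-Sites", "N-Sites", "Substitutions")
  } else {
    c("Sequence", "Method", "Ka", "Ks", "Ka/Ks", "P-Value", "Length",
      "S-Sites", "N-Sites", "Substitutions")
  }
  rate1 <- if (noncoding) results$kn else results$ka
  ratio <- if (noncoding) results$kn_ks else results$ka_ks
  body <- if (nrow(results)) {
    paste(results$sequence, results$method, fmt_num(rate1),
          fmt_num(results$ks), fmt_num(ratio), fmt_num(results$p_value),
          results$length, fmt_num(results$s_sites),
          fmt_num(results$n_sites), fmt_num(results$substitutions),
          sep = "\t")
  } else {
    character()
  }
  writeLines(c(paste(header, collapse = "\t"), body), path)
  invisible(path)
}
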