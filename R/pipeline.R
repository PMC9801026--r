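# Batch interfaces: kaks() maps methods over a tibble of pairs; run_coding()
# and run_noncoding() are the file-to-file entry points behind the CLI.

KAKS_METHODS <- c("NG", "LWL", "LPB", "MLWL", "MLPB", "YN", "MYN",
                  "GY", "MS", "MA")

na_kaks_row <- function(sequence, method, length = NA_integer_) {
  new_kaks_row(sequence, method, NA_real_, NA_real_, NA_real_, NA_real_,
               NA_real_, NA_real_, length, converged = FALSE)
}

#' Ka/Ks estimation for a table of aligned coding pairs
#'
#' Runs one or more of the ten estimators on every pair and stacks the
#' results, one row per (pair, method). Failures on individual pairs are
#' reported as NA rows with a warning, never aborting the batch.
#'
#' Methods: the approximate estimators `NG`, `LWL`, `LPB`, `MLWL`, `MLPB`,
#' `YN`, `MYN` (see [kaks_methods]) and the maximum-likelihood family `GY`
#' (HKY structure), `MS` (best AICc model over the candidate set) and `MA`
#' (Akaike-weight model average). Names are case-insensitive.
#'
#' @param pairs Tibble with columns `name`, `seq1`, `seq2` (e.g. from
#'   [read_axt()]).
#' @param methods Character vector of method names (default `"MA"`).
#' @param code_table NCBI translation-table number.
#' @param clean Pass the pairs through [clean_codon_alignment()] first
#'   (default TRUE).
#' @param models Candidate set for `MS`/`MA` (default [gy_models()]).
#' @return A tibble with one row per (pair, method): `sequence`, `method`,
#'   `ka`, `ks`, `ka_ks`, `p_value`, `length`, `s_sites`, `n_sites`, `sd`,
#'   `nd`, `substitutions`, `kappa`, `model`, `converged`.
#' @examples
#' pairs <- tibble::tibble(name = "toy",
#'                         seq1 = "ATGAAACCCGGGTTTCTG",
#'                         seq2 = "ATGAAGCCAGGATTCCTG")
#' kaks(pairs, methods = c("NG", "LWL"))
#' @export
kaks <- function(pairs, methods = "MA", code_table = 1L, clean = TRUE,
                 models = gy_models()) {
  pairs <- as_pair_tbl(pairs)
  methods <- toupper(methods)
  bad <- setdiff(methods, KAKS_METHODS)
  if (length(bad)) {
    stop("unknown method(s): ", paste(bad, collapse = ", "),
         "; valid methods are: ", paste(KAKS_METHODS, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(pairs) == 0L) return(na_kaks_row("x", "NG")[0, ])
  out <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    nm <- pairs$name[i]
    row <- pairs[i, ]
    cleaned <- tryCatch(
      if (clean) clean_codon_alignment(row, code_table) else row,
      error = function(e) {
        warning("pair '", nm, "' skipped: ", conditionMessage(e),
                call. = FALSE)
        NULL
      }
    )
    if (is.null(cleaned)) {
      out[[i]] <- dplyr::bind_rows(lapply(methods, function(m) {
        na_kaks_row(nm, m)
      }))
      next
    }
    s1 <- cleaned$seq1[1]; s2 <- cleaned$seq2[1]
    ms_fit <- NULL
    if (any(c("MS", "MA") %in% methods)) {
      ms_fit <- tryCatch(
        model_select(s1, s2, models = models, code_table = code_table,
                     sequence = nm),
        error = function(e) {
          warning("model selection failed for pair '", nm, "': ",
                  conditionMessage(e), call. = FALSE)
          NULL
        }
      )
    }
    rows <- lapply(methods, function(m) {
      tryCatch(
        switch(m,
          NG = ng86(s1, s2, code_table, sequence = nm),
          LWL = lwl85(s1, s2, code_table, sequence = nm),
          LPB = lpb93(s1, s2, code_table, sequence = nm),
          MLWL = mlwl(s1, s2, code_table, sequence = nm),
          MLPB = mlpb(s1, s2, code_table, sequence = nm),
          YN = yn00(s1, s2, code_table, sequence = nm),
          MYN = myn(s1, s2, code_table, sequence = nm),
          GY = gy_fit_as_row(fit_gy(s1, s2, model = "HKY",
                                    code_table = code_table,
                                    sequence = nm)),
          MS = if (is.null(ms_fit)) na_kaks_row(nm, "MS") else {
            gy_fit_as_row(ms_fit$best, method = "MS")
          },
          MA = if (is.null(ms_fit)) na_kaks_row(nm, "MA") else {
            model_average(ms_fit)
          }
        ),
        error = function(e) {
          warning("method ", m, " failed for pair '", nm, "': ",
                  conditionMessage(e), call. = FALSE)
          na_kaks_row(nm, m, nchar(s1))
        }
      )
    })
    out[[i]] <- dplyr::bind_rows(rows)
  }
  dplyr::bind_rows(out)
}

read_pairs_file <- function(path) {
  if (grepl("\\.(fa|fasta|fna)$", path, ignore.case = TRUE)) {
    read_fasta_pair(path)
  } else {
    read_axt(path)
  }
}

#' File-to-file coding-sequence pipeline
#'
#' Reads a batch of aligned coding pairs (AXT paired blocks, or aligned
#' FASTA for a single pair), estimates Ka/Ks with the requested methods and
#' writes the tab-delimited result table.
#'
#' @param input Input alignment path (`.axt` blocks or `.fa`/`.fasta`).
#' @param output Output TSV path.
#' @param methods Methods as in [kaks()].
#' @param code_table NCBI translation-table number.
#' @return The result tibble, invisibly.
#' @export
run_coding <- function(input, output, methods = "MA", code_table = 1L) {
  res <- kaks(read_pairs_file(input), methods = methods,
              code_table = code_table)
  write_results(res, output)
  invisible(res)
}

#' File-to-file non-coding pipeline
#'
#' Reads aligned non-coding pairs, computes Kn under the chosen nucleotide
#' model and xi = Kn/Ks against either a user-specified Ks or the Ks of
#' adjacent coding pairs, and writes the tab-delimited result table.
#'
#' @param input Input non-coding alignment path.
#' @param output Output TSV path.
#' @param model `"HKY"` (default), `"K2P"` or `"JC"`.
#' @param ks_value User-specified neutral rate (mutually exclusive with
#'   `cds_file`).
#' @param cds_file Path to the adjacent coding alignment(s).
#' @param cds_method Coding method used on `cds_file` (default `"MYN"`).
#' @param code_table NCBI translation-table number.
#' @return The result tibble, invisibly.
#' @export
run_noncoding <- function(input, output, model = "HKY", ks_value = NULL,
                          cds_file = NULL, cds_method = "MYN",
                          code_table = 1L) {
  if (!is.null(ks_value) && !is.null(cds_file)) {
    stop("--ks-value and --cds-file are mutually exclusive", call. = FALSE)
  }
  cds <- if (!is.null(cds_file)) read_pairs_file(cds_file)
  res <- knks(read_pairs_file(input), model = model, ks = ks_value,
              cds = cds, cds_method = cds_method, code_table = code_table)
  write_results(res, output)
  invisible(res)
}
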