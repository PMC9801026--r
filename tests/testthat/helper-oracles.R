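# Independent oracles used across the suite. They are written directly from
# first principles (exhaustive enumeration, closed forms) and never call the
# package's own counting machinery.

# Independent genetic-code source for cross-checks
oracle_translate <- function(codon) {
  as.character(Biostrings::GENETIC_CODE[codon])
}

oracle_bases <- c("T", "C", "A", "G")

oracle_codons <- function() {
  as.vector(t(outer(as.vector(t(outer(oracle_bases, oracle_bases, paste0))),
                    oracle_bases, paste0)))
}

oracle_sense_codons <- function() {
  all64 <- oracle_codons()
  all64[oracle_translate(all64) != "*"]
}

# Exhaustive per-codon synonymous site fraction: for each position, the
# share of non-stop point mutations that preserve the amino acid.
oracle_ng_sites <- function(codon) {
  aa <- oracle_translate(codon)
  s <- 0
  for (p in 1:3) {
    muts <- vapply(setdiff(c("A", "C", "G", "T"),
                           substr(codon, p, p)), function(b) {
      `substr<-`(codon, p, p, b)
    }, character(1))
    aas <- oracle_translate(muts)
    keep <- aas != "*"
    if (any(keep)) s <- s + sum(aas[keep] == aa) / sum(keep)
  }
  s
}

oracle_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (rest in oracle_permutations(n - 1)) {
      tail <- seq_len(n)[-i][rest]
      out[[length(out) + 1L]] <- c(i, tail)
    }
  }
  out
}

# Exhaustive pathway-averaged (sd, nd) for one codon pair, stop-free
# pathways preferred, equal-weight fallback when all pass through stops.
oracle_pathway_counts <- function(c1, c2) {
  dp <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (!length(dp)) return(c(sd = 0, nd = 0))
  paths <- list()
  for (ord in oracle_permutations(length(dp))) {
    cur <- c1
    sd <- nd <- 0
    stop_free <- TRUE
    for (p in dp[unlist(ord)]) {
      nxt <- `substr<-`(cur, p, p, substr(c2, p, p))
      a1 <- oracle_translate(cur); a2 <- oracle_translate(nxt)
      if (a2 == "*") stop_free <- FALSE
      if (a1 != "*" && a1 == a2) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    paths[[length(paths) + 1L]] <- c(sd, nd, stop_free)
  }
  m <- do.call(rbind, paths)
  use <- if (any(m[, 3] == 1)) m[m[, 3] == 1, , drop = FALSE] else m
  c(sd = mean(use[, 1]), nd = mean(use[, 2]))
}

# Matrix exponential by plain series summation (independent of the
# eigendecomposition route in the package)
oracle_expm_series <- function(M, nterms = 60) {
  out <- diag(nrow(M))
  term <- diag(nrow(M))
  for (k in seq_len(nterms)) {
    term <- term %*% M / k
    out <- out + term
  }
  out
}

# deterministic per-replicate seeds below 2^31
rep_seeds <- function(base, n) base + seq_len(n) * 1000L

sim_codon <- function(...) simulate_pair(sim_spec("codon", ...))
sim_nuc <- function(...) simulate_pair(sim_spec("nucleotide", ...))
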