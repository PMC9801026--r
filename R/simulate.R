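# Sequence-pair simulator: evolves an equilibrium ancestor along two
# branches of length t/2 using exact matrix-exponential transition
# probabilities, under the same models the estimators assume. Used for all
# parameter-recovery tests; no external data is ever needed.

with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# 4x4 nucleotide generator (ACGT order), scaled to 1 substitution/site
nuc_rate_matrix <- function(model, kappa = 2, kappa_R = NULL,
                            kappa_Y = NULL, base_freqs = NULL) {
  model <- match.arg(toupper(model), c("JC", "K2P", "HKY", "TN93"))
  acgt <- c("A", "C", "G", "T")
  pi <- if (model %in% c("JC", "K2P")) {
    stats::setNames(rep(0.25, 4), acgt)
  } else if (is.null(base_freqs)) {
    stats::setNames(rep(0.25, 4), acgt)
  } else {
    stopifnot(length(base_freqs) == 4, abs(sum(base_freqs) - 1) < 1e-6)
    stats::setNames(as.numeric(base_freqs), acgt)
  }
  if (model == "JC") kappa <- 1
  kR <- if (model == "TN93") kappa_R else kappa
  kY <- if (model == "TN93") kappa_Y else kappa
  stopifnot(!is.null(kR), !is.null(kY))
  R <- matrix(1, 4, 4, dimnames = list(acgt, acgt))
  R["A", "G"] <- R["G", "A"] <- kR
  R["C", "T"] <- R["T", "C"] <- kY
  Q <- R * rep(pi, each = 4)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q / -sum(pi * diag(Q))
}

# expm(Q t) for a reversible generator via symmetric eigendecomposition
reversible_pmatrix <- function(Q, pi, t) {
  s <- sqrt(pi)
  B <- Q * (s %o% (1 / s))
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  P <- (e$vectors %*% (exp(e$values * t) * t(e$vectors))) * ((1 / s) %o% s)
  P[P < 0] <- 0
  P / rowSums(P)
}

sample_descendant <- function(anc, P) {
  child <- integer(length(anc))
  for (a in unique(anc)) {
    sel <- anc == a
    child[sel] <- sample.int(ncol(P), sum(sel), replace = TRUE,
                             prob = P[a, ])
  }
  child
}

#' Specification of a simulated pair
#'
#' Collects and validates the parameters of one simulated alignment:
#' either a codon pair evolved under the Goldman-Yang model with a chosen
#' exchangeability structure, or a nucleotide pair under JC/K2P/HKY/TN93.
#' The seed is mandatory and is echoed into the pair name so fixtures are
#' traceable to their generator settings.
#'
#' @param kind `"codon"` or `"nucleotide"`.
#' @param model For codons, a structure from [gy_models()]; for
#'   nucleotides, `"JC"`, `"K2P"`, `"HKY"` or `"TN93"`.
#' @param length Number of codons (codon kind) or sites (nucleotide kind).
#' @param t Expected divergence between the two sequences: substitutions
#'   per codon for the codon kind, per site for the nucleotide kind.
#' @param seed Integer RNG seed (mandatory).
#' @param omega Nonsynonymous/synonymous ratio (codon kind).
#' @param kappa Transition/transversion rate ratio.
#' @param kappa_R,kappa_Y Separate purine/pyrimidine transition ratios
#'   (TN93 nucleotide model).
#' @param base_freqs Base frequencies (A, C, G, T) for frequency-aware
#'   models.
#' @param codon_freqs Sense-codon equilibrium frequencies (codon kind);
#'   default equal, or derived from `base_freqs` if those are given.
#' @param code_table NCBI translation-table number.
#' @return A validated list of class `"sim_spec"`.
#' @examples
#' sim_spec("nucleotide", model = "JC", length = 1000, t = 0.2, seed = 1)
#' @export
sim_spec <- function(kind = c("codon", "nucleotide"), model, length, t,
                     seed, omega = 1, kappa = 2, kappa_R = NULL,
                     kappa_Y = NULL, base_freqs = NULL, codon_freqs = NULL,
                     code_table = 1L) {
  kind <- match.arg(kind)
  if (missing(seed) || is.null(seed)) {
    stop("sim_spec(): a seed is mandatory", call. = FALSE)
  }
  stopifnot(t >= 0, length >= 1, omega >= 0, kappa >= 0)
  model <- toupper(model)
  if (kind == "codon") {
    model <- match.arg(model, gy_models())
  } else {
    model <- match.arg(model, c("JC", "K2P", "HKY", "TN93"))
  }
  structure(list(kind = kind, model = model, length = as.integer(length),
                 t = t, seed = as.integer(seed), omega = omega,
                 kappa = kappa, kappa_R = kappa_R, kappa_Y = kappa_Y,
                 base_freqs = base_freqs, codon_freqs = codon_freqs,
                 code_table = as.integer(code_table)),
            class = "sim_spec")
}

#' Simulate an aligned sequence pair
#'
#' Draws an ancestral sequence from the model's equilibrium frequencies and
#' evolves two independent descendants for `t/2` each, sampling from the
#' exact transition probabilities `P(t/2) = expm(Q t/2)`. Deterministic for
#' a fixed seed.
#'
#' @param spec A [sim_spec()] object.
#' @return A one-row tibble with columns `name`, `seq1`, `seq2`; the name
#'   encodes kind, model, divergence and seed.
#' @examples
#' simulate_pair(sim_spec("nucleotide", model = "K2P", length = 50,
#'                        t = 0.1, seed = 7))
#' @export
simulate_pair <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  name <- sprintf("sim_%s_%s_t%g_seed%d", spec$kind, spec$model, spec$t,
                  spec$seed)
  with_seed(spec$seed, {
    if (spec$kind == "nucleotide") {
      Q <- nuc_rate_matrix(spec$model, kappa = spec$kappa,
                           kappa_R = spec$kappa_R, kappa_Y = spec$kappa_Y,
                           base_freqs = spec$base_freqs)
      pi <- rep(0.25, 4)
      if (spec$model %in% c("HKY", "TN93") && !is.null(spec$base_freqs)) {
        pi <- as.numeric(spec$base_freqs)
      }
      P <- reversible_pmatrix(Q, pi, spec$t / 2)
      anc <- sample.int(4L, spec$length, replace = TRUE, prob = pi)
      acgt <- c("A", "C", "G", "T")
      s1 <- paste(acgt[sample_descendant(anc, P)], collapse = "")
      s2 <- paste(acgt[sample_descendant(anc, P)], collapse = "")
    } else {
      code <- genetic_code(spec$code_table)
      str <- gy_structure(code)
      pi <- spec$codon_freqs
      if (is.null(pi) && !is.null(spec$base_freqs)) {
        b <- stats::setNames(as.numeric(spec$base_freqs),
                             c("A", "C", "G", "T"))
        f <- vapply(CODONS64[str$sense64], function(cd) {
          prod(b[strsplit(cd, "")[[1]]])
        }, numeric(1))
        pi <- unname(f / sum(f))
      }
      if (is.null(pi)) pi <- rep(1 / str$n, str$n)
      params <- NULL
      if (spec$model %in% c("TN", "TNEF") && !is.null(spec$kappa_R)) {
        params <- c(spec$kappa_R, spec$kappa_Y)
      }
      mat <- build_rate_matrix(spec$model, omega = spec$omega,
                               kappa = spec$kappa, params = params,
                               codon_freqs = pi,
                               code_table = spec$code_table)
      P <- cpp_gy_pmatrix(spec$t / 2, mat$rates, mat$omega, pi, str$steps)
      P[P < 0] <- 0
      P <- P / rowSums(P)
      anc <- sample.int(str$n, spec$length, replace = TRUE, prob = pi)
      sense_codons <- CODONS64[str$sense64]
      s1 <- paste(sense_codons[sample_descendant(anc, P)], collapse = "")
      s2 <- paste(sense_codons[sample_descendant(anc, P)], collapse = "")
    }
    tibble::tibble(name = name, seq1 = s1, seq2 = s2)
  })
}

#' Observed summary statistics of a simulated pair
#'
#' Reports the observed transition/transversion proportions and, for codon
#' pairs, the pathway-averaged synonymous/nonsynonymous difference counts
#' and amino-acid differences, for use in simulator-calibration assertions.
#'
#' @param pair A one-row pair tibble (`name`, `seq1`, `seq2`).
#' @param kind `"codon"` or `"nucleotide"`.
#' @param code_table NCBI translation-table number (codon kind).
#' @return A one-row tibble of summary statistics.
#' @export
empirical_check <- function(pair, kind = c("codon", "nucleotide"),
                            code_table = 1L) {
  kind <- match.arg(kind)
  cp <- count_pair(pair$seq1[1], pair$seq2[1])
  base <- tibble::tibble(name = pair$name[1], S = cp$S, V = cp$V,
                         n_diff = cp$n_diff, length = cp$L)
  if (kind == "nucleotide") return(base)
  dc <- ng_difference_counts(pair$seq1[1], pair$seq2[1], code_table)
  code <- genetic_code(code_table)
  i1 <- codon_indices(pair$seq1[1]); i2 <- codon_indices(pair$seq2[1])
  aa <- unname(code$codon_to_aa)
  dplyr::mutate(base, sd = dc[["sd"]], nd = dc[["nd"]],
                aa_diff = sum(aa[i1] != aa[i2]))
}
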