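# Maximum-likelihood Ka/Ks under the Goldman-Yang codon model, with a fixed
# candidate set of nucleotide exchangeability structures, AICc model
# selection (MS) and Akaike-weight model averaging (MA).

# Exchangeability classes in ACGT pair order: AC, AG, AT, CG, CT, GT.
# A template assigns each class to a free parameter (0 = fixed at 1).
# AG and CT are the transition classes.
GY_MODELS <- list(
  JC    = list(equal_freq = TRUE,  template = c(0L, 0L, 0L, 0L, 0L, 0L)),
  F81   = list(equal_freq = FALSE, template = c(0L, 0L, 0L, 0L, 0L, 0L)),
  K2P   = list(equal_freq = TRUE,  template = c(0L, 1L, 0L, 0L, 1L, 0L)),
  HKY   = list(equal_freq = FALSE, template = c(0L, 1L, 0L, 0L, 1L, 0L)),
  TNEF  = list(equal_freq = TRUE,  template = c(0L, 1L, 0L, 0L, 2L, 0L)),
  TN    = list(equal_freq = FALSE, template = c(0L, 1L, 0L, 0L, 2L, 0L)),
  K3P   = list(equal_freq = TRUE,  template = c(0L, 1L, 2L, 2L, 1L, 0L)),
  K3PUF = list(equal_freq = FALSE, template = c(0L, 1L, 2L, 2L, 1L, 0L)),
  TIMEF = list(equal_freq = TRUE,  template = c(0L, 1L, 2L, 2L, 3L, 0L)),
  TIM   = list(equal_freq = FALSE, template = c(0L, 1L, 2L, 2L, 3L, 0L)),
  TVMEF = list(equal_freq = TRUE,  template = c(2L, 1L, 3L, 4L, 1L, 0L)),
  TVM   = list(equal_freq = FALSE, template = c(2L, 1L, 3L, 4L, 1L, 0L)),
  SYM   = list(equal_freq = TRUE,  template = c(2L, 1L, 3L, 4L, 5L, 0L)),
  GTR   = list(equal_freq = FALSE, template = c(2L, 1L, 3L, 4L, 5L, 0L))
)

# fixed multi-start initial points (t, omega, kappa)
GY_STARTS <- list(c(0.1, 0.5, 2), c(1, 1, 2), c(0.5, 0.1, 5))

#' Candidate substitution structures for the ML family
#'
#' The fixed, ordered candidate set used by [model_select()] and the MA
#' method: ten nucleotide exchangeability structures (JC, F81, K2P, HKY,
#' TN, K3P, TIM, TVM, SYM, GTR), the symmetric ones both with equal base
#' frequencies and with F3x4 frequencies (suffix-less vs `EF` variants),
#' 14 models in total.
#'
#' @return Character vector of model identifiers in candidate order.
#' @examples
#' gy_models()
#' @export
gy_models <- function() names(GY_MODELS)

# Codon-level structure for one genetic code: sense codon list and the
# single-step table (0-based indices for the C++ kernel).
gy_structure <- function(code) {
  key <- paste0("gy_", code$table_id)
  if (!is.null(.kaksr_cache[[key]])) return(.kaksr_cache[[key]])
  aa <- unname(code$codon_to_aa)
  sense64 <- which(aa != "*")
  n <- length(sense64)
  idx61 <- match(seq_len(64L), sense64) # 64 -> sense index or NA
  base_mat <- matrix(unlist(strsplit(CODONS64, "")), nrow = 3L)
  acgt <- c("A", "C", "G", "T")
  pair_class <- function(b1, b2) {
    p <- sort(match(c(b1, b2), acgt))
    c(`12` = 1L, `13` = 2L, `14` = 3L, `23` = 4L, `24` = 5L, `34` = 6L)[[
      paste0(p[1], p[2])]]
  }
  rows <- list()
  for (i64 in sense64) {
    for (p in 1:3) {
      for (nb in codon_neighbours(CODONS64[i64], p)) {
        j64 <- match(nb, CODONS64)
        if (is.na(idx61[j64])) next # no substitutions to stop codons
        rows[[length(rows) + 1L]] <- c(
          idx61[i64] - 1L, idx61[j64] - 1L,
          pair_class(base_mat[p, i64], base_mat[p, j64]) - 1L,
          as.integer(aa[i64] != aa[j64])
        )
      }
    }
  }
  steps <- do.call(rbind, rows)
  storage.mode(steps) <- "integer"
  out <- list(sense64 = sense64, idx61 = idx61, n = n, steps = steps)
  .kaksr_cache[[key]] <- out
  out
}

rates_from_template <- function(template, params) {
  r <- rep(1, 6)
  if (length(params)) r[template > 0] <- params[template[template > 0]]
  r
}

#' Goldman-Yang codon rate matrix
#'
#' Builds the scaled instantaneous rate matrix of the Goldman-Yang codon
#' model: zero for multi-nucleotide changes, `r_xy * pi_j` for synonymous
#' and `omega * r_xy * pi_j` for nonsynonymous single-nucleotide changes,
#' where `r_xy` is the nucleotide exchangeability of the chosen structure.
#' Rates to and from stop codons are zero (stop codons are excluded from the
#' state space). The matrix is scaled so one unit of time equals one
#' expected substitution per codon.
#'
#' @param model Model identifier from [gy_models()].
#' @param omega Nonsynonymous/synonymous rate ratio.
#' @param kappa Transition/transversion rate ratio used to fill the
#'   transition classes of the template when `params` is not given.
#' @param params Optional numeric vector of the model's free exchangeability
#'   parameters (overrides `kappa`).
#' @param codon_freqs Equilibrium frequencies over the sense codons (must
#'   sum to 1); default equal.
#' @param code_table NCBI translation-table number.
#' @return A list of class `"gy_matrix"` with elements `Q` (61 x 61 for the
#'   standard code), `pi`, `rates`, `omega`, `model`, and the internal step
#'   table.
#' @examples
#' m <- build_rate_matrix("HKY", omega = 0.5, kappa = 2)
#' range(rowSums(m$Q))
#' @export
build_rate_matrix <- function(model = "HKY", omega = 1, kappa = 2,
                              params = NULL, codon_freqs = NULL,
                              code_table = 1L) {
  model <- match.arg(toupper(model), gy_models())
  if (omega < 0 || kappa < 0 || any(params < 0)) {
    stop("rate parameters must be non-negative", call. = FALSE)
  }
  spec <- GY_MODELS[[model]]
  code <- genetic_code(code_table)
  str <- gy_structure(code)
  if (is.null(codon_freqs)) codon_freqs <- rep(1 / str$n, str$n)
  if (length(codon_freqs) != str$n || abs(sum(codon_freqs) - 1) > 1e-6) {
    stop("codon_freqs must be a frequency vector over the ", str$n,
         " sense codons", call. = FALSE)
  }
  npar <- max(spec$template)
  if (is.null(params)) {
    params <- rep(1, npar)
    params[unique(spec$template[c(2L, 5L)][spec$template[c(2L, 5L)] > 0])] <- kappa
  }
  if (length(params) != npar) {
    stop("model ", model, " has ", npar, " free exchangeability parameters",
         call. = FALSE)
  }
  rates <- rates_from_template(spec$template, params)
  Q <- cpp_gy_qmatrix(rates, omega, codon_freqs, str$steps)
  dimnames(Q) <- list(CODONS64[str$sense64], CODONS64[str$sense64])
  structure(list(Q = Q, pi = codon_freqs, rates = rates, omega = omega,
                 model = model, steps = str$steps, code_table = code_table),
            class = "gy_matrix")
}

# codon pair counts restricted to the sense codons
sense_pair_counts <- function(seq1, seq2, code) {
  str <- gy_structure(code)
  counts64 <- codon_pair_counts(seq1, seq2)
  bad <- setdiff(seq_len(64L), str$sense64)
  if (any(counts64[bad, ] > 0) || any(counts64[, bad] > 0)) {
    stop("alignment contains in-frame stop codons", call. = FALSE)
  }
  counts64[str$sense64, str$sense64, drop = FALSE]
}

#' Pairwise log-likelihood under a codon rate matrix
#'
#' Log-likelihood of an aligned codon pair at divergence `t`:
#' `sum over codon columns of log(pi_i P(t)_ij)` with `P(t) = expm(Q t)`.
#' Time reversibility makes the orientation of the pair irrelevant.
#'
#' @param seq1,seq2 Aligned, cleaned coding sequences.
#' @param matrix A [build_rate_matrix()] object.
#' @param t Divergence in expected substitutions per codon (`t >= 0`).
#' @return The log-likelihood (a large negative floor guards underflow).
#' @examples
#' m <- build_rate_matrix("JC", omega = 1)
#' pair_log_likelihood("ATGAAA", "ATGAAG", m, t = 0.2)
#' @export
pair_log_likelihood <- function(seq1, seq2, matrix, t) {
  stopifnot(inherits(matrix, "gy_matrix"), t >= 0)
  code <- genetic_code(matrix$code_table)
  counts <- sense_pair_counts(toupper(seq1), toupper(seq2), code)
  cpp_gy_loglik(t, matrix$rates, matrix$omega, matrix$pi, matrix$steps,
                counts)
}

# flux fractions of a scaled Q: share of substitutions that are synonymous
gy_syn_flux <- function(rates, omega, pi, steps) {
  Q <- cpp_gy_qmatrix(rates, omega, pi, steps)
  syn <- steps[, 4L] == 0L
  i <- steps[syn, 1L] + 1L
  j <- steps[syn, 2L] + 1L
  sum(pi[i] * Q[cbind(i, j)])
}

#' Fit the Goldman-Yang model to one aligned coding pair
#'
#' Maximizes the pairwise codon likelihood over divergence `t`, selection
#' `omega` and the exchangeability parameters of the chosen structure
#' (bounded quasi-Newton in log space, three fixed starting points). Codon
#' frequencies are held at their F3x4 estimates (or equal, for the `EF` /
#' JC / K2P-type structures). Ka and Ks are derived from the fitted matrix:
#' `Ks = t * rho_S / (3 * S_prop)` and `Ka = t * rho_N / (3 * N_prop)`,
#' where `rho_S`/`rho_N` are the synonymous/nonsynonymous flux fractions of
#' the fitted generator and `S_prop`/`N_prop` the corresponding mutational
#' opportunity fractions at `omega = 1`.
#'
#' @inheritParams kaks_methods
#' @param model Model identifier from [gy_models()].
#' @return An object of class `"gy_fit"`: a list with the estimates (`t`,
#'   `omega`, `rates`), `lnL`, `k` (free parameters), `n` (codons), `AICc`,
#'   `ka`, `ks`, `s_sites`, `n_sites` and a convergence flag. Use
#'   [tidy()][generics::tidy] / [glance()][generics::glance] to extract
#'   tibbles.
#' @examples
#' \donttest{
#' sim <- simulate_pair(sim_spec("codon", model = "HKY", length = 300,
#'                               t = 0.4, omega = 0.3, kappa = 2, seed = 1))
#' fit_gy(sim$seq1, sim$seq2, model = "HKY")
#' }
#' @export
fit_gy <- function(seq1, seq2, model = "HKY", code_table = 1L,
                   sequence = "pair") {
  check_coding_pair(seq1, seq2)
  seq1 <- toupper(seq1); seq2 <- toupper(seq2)
  model <- match.arg(toupper(model), gy_models())
  spec <- GY_MODELS[[model]]
  code <- genetic_code(code_table)
  str <- gy_structure(code)
  counts <- sense_pair_counts(seq1, seq2, code)
  n_codons <- sum(counts)
  if (n_codons < 30) {
    warning("fewer than 30 codons; ML estimates will be unstable",
            call. = FALSE)
  }
  pi61 <- if (spec$equal_freq) {
    rep(1 / str$n, str$n)
  } else {
    unname(f3x4_codon_freqs(seq1, seq2, code))
  }
  npar_e <- max(spec$template)
  is_ts_par <- unique(spec$template[c(2L, 5L)][spec$template[c(2L, 5L)] > 0])

  nll <- function(lpar) {
    rates <- rates_from_template(spec$template, exp(lpar[-(1:2)]))
    -cpp_gy_loglik(exp(lpar[1]), rates, exp(lpar[2]), pi61, str$steps,
                   counts)
  }
  lower <- log(c(1e-6, 1e-6, rep(1e-3, npar_e)))
  upper <- log(c(50, 50, rep(1e3, npar_e)))
  best <- NULL
  for (s in GY_STARTS) {
    epar0 <- rep(1, npar_e)
    if (length(is_ts_par)) epar0[is_ts_par] <- s[3]
    lpar0 <- log(c(s[1], s[2], epar0))
    res <- tryCatch(
      stats::optim(lpar0, nll, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(maxit = 500)),
      error = function(e) NULL
    )
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) {
    stop("optimizer failed for model ", model, call. = FALSE)
  }
  t_hat <- exp(best$par[1])
  omega_hat <- exp(best$par[2])
  rates_hat <- rates_from_template(spec$template, exp(best$par[-(1:2)]))

  rho_s <- gy_syn_flux(rates_hat, omega_hat, pi61, str$steps)
  s_prop <- gy_syn_flux(rates_hat, 1, pi61, str$steps)
  ks <- if (s_prop > 0) t_hat * rho_s / (3 * s_prop) else NA_real_
  ka <- if (s_prop < 1) t_hat * (1 - rho_s) / (3 * (1 - s_prop)) else NA_real_

  # free parameters: t, omega, exchangeabilities, and the 9 F3x4
  # position-specific base frequencies when those are data-estimated
  k <- 2L + npar_e + if (spec$equal_freq) 0L else 9L
  aicc <- if (n_codons - k - 1 > 0) {
    2 * best$value + 2 * k + 2 * k * (k + 1) / (n_codons - k - 1)
  } else {
    Inf
  }
  structure(list(
    sequence = sequence, model = model,
    t = t_hat, omega = omega_hat, rates = rates_hat,
    lnL = -best$value, k = k, n = n_codons, AICc = aicc,
    ka = ka, ks = ks,
    s_sites = 3 * n_codons * s_prop, n_sites = 3 * n_codons * (1 - s_prop),
    pi = pi61, converged = best$convergence == 0
  ), class = "gy_fit")
}

#' @export
print.gy_fit <- function(x, ...) {
  cat(sprintf(
    "Goldman-Yang fit [%s]  lnL = %.3f  AICc = %.3f\n  t = %.4f  omega = %.4f  Ka = %.4f  Ks = %.4f\n",
    x$model, x$lnL, x$AICc, x$t, x$omega, x$ka, x$ks))
  invisible(x)
}

gy_fit_as_row <- function(fit, method = "GY") {
  kappa <- mean(fit$rates[c(2L, 5L)]) / mean(fit$rates[c(1L, 3L, 4L, 6L)])
  new_kaks_row(fit$sequence, method, fit$ka, fit$ks, fit$s_sites,
               fit$n_sites,
               sd = fit$ks * fit$s_sites, nd = fit$ka * fit$n_sites,
               length = 3 * fit$n, kappa = kappa, model = fit$model,
               converged = fit$converged)
}

#' Model selection over the candidate structures
#'
#' Fits every candidate structure with [fit_gy()] and ranks the fits by
#' AICc (ascending), breaking ties by fewer free parameters and then by
#' candidate order. Akaike weights `w_m = exp(-delta_m/2) / sum(...)` are
#' computed over the successful fits.
#'
#' @inheritParams fit_gy
#' @param models Character vector of candidate identifiers (default the full
#'   fixed set from [gy_models()]; at least two).
#' @return An object of class `"gy_model_set"`: list with `table` (ranked
#'   tibble of model, k, lnL, AICc, delta, weight, t, omega, ka, ks),
#'   `fits` (named list of `gy_fit`), `best`, and `sequence`.
#' @seealso [model_average()]
#' @export
model_select <- function(seq1, seq2, models = gy_models(), code_table = 1L,
                         sequence = "pair") {
  models <- match.arg(toupper(models), gy_models(), several.ok = TRUE)
  if (length(models) < 1) stop("no candidate models", call. = FALSE)
  fits <- list()
  for (m in models) {
    f <- tryCatch(fit_gy(seq1, seq2, model = m, code_table = code_table,
                         sequence = sequence),
                  error = function(e) NULL)
    if (!is.null(f)) fits[[m]] <- f
  }
  if (!length(fits)) stop("all candidate model fits failed", call. = FALSE)
  tab <- purrr::map_dfr(fits, function(f) {
    tibble::tibble(model = f$model, k = f$k, lnL = f$lnL, AICc = f$AICc,
                   t = f$t, omega = f$omega, ka = f$ka, ks = f$ks)
  })
  tab$order <- match(tab$model, gy_models())
  tab <- dplyr::arrange(tab, .data$AICc, .data$k, .data$order)
  tab$order <- NULL
  tab$delta <- tab$AICc - tab$AICc[1]
  w <- exp(-tab$delta / 2)
  tab$weight <- w / sum(w)
  tab <- dplyr::relocate(tab, "delta", "weight", .after = "AICc")
  structure(list(table = tab, fits = fits, best = fits[[tab$model[1]]],
                 sequence = sequence),
            class = "gy_model_set")
}

#' @export
print.gy_model_set <- function(x, ...) {
  cat("Goldman-Yang model selection -", nrow(x$table), "fits; best:",
      x$table$model[1], "\n")
  print(x$table, ...)
  invisible(x)
}

#' Akaike-weight model averaging
#'
#' Averages Ka, Ks and the site counts over the fitted candidate models with
#' Akaike weights; the reported ratio is `mean(Ka)/mean(Ks)` so that the MA
#' row is internally consistent with its own Ka and Ks columns.
#'
#' @param ms A [model_select()] result.
#' @return A one-row tibble in the common Ka/Ks result format (method
#'   `"MA"`).
#' @export
model_average <- function(ms) {
  stopifnot(inherits(ms, "gy_model_set"))
  tab <- ms$table
  w <- tab$weight
  ka <- sum(w * tab$ka)
  ks <- sum(w * tab$ks)
  s_sites <- sum(w * vapply(tab$model, function(m) ms$fits[[m]]$s_sites,
                            numeric(1)))
  n_sites <- sum(w * vapply(tab$model, function(m) ms$fits[[m]]$n_sites,
                            numeric(1)))
  len <- 3 * ms$best$n
  new_kaks_row(ms$sequence, "MA", ka, ks, s_sites, n_sites,
               sd = ks * s_sites, nd = ka * n_sites, length = len,
               model = paste0("MA(", nrow(tab), ")"))
}
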