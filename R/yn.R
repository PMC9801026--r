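# Iterative approximate estimators: YN (transition bias + codon-frequency
# weighted site counting, K2P correction) and MYN (the same skeleton with
# separate purine and pyrimidine transition rates and TN93 corrections).

# TN93 distance from A<->G (P1) and T<->C (P2) transition proportions, the
# transversion proportion Q, and base frequencies. NA outside the log domain.
tn93_distance <- function(P1, P2, Q, pi) {
  piA <- pi[["A"]]; piC <- pi[["C"]]; piG <- pi[["G"]]; piT <- pi[["T"]]
  piR <- piA + piG; piY <- piT + piC
  if (piA * piG <= 0 || piT * piC <= 0) return(NA_real_)
  k1 <- 2 * piA * piG / piR
  k2 <- 2 * piT * piC / piY
  k3 <- 2 * (piR * piY - piA * piG * piY / piR - piT * piC * piR / piY)
  w1 <- 1 - P1 / k1 - Q / (2 * piR)
  w2 <- 1 - P2 / k2 - Q / (2 * piY)
  w3 <- 1 - Q / (2 * piR * piY)
  if (any(c(w1, w2, w3) <= 0)) return(NA_real_)
  -k1 * log(w1) - k2 * log(w2) - k3 * log(w3)
}

# Moment estimators of the purine (kappa_R) and pyrimidine (kappa_Y)
# transition/transversion rate ratios under TN93, from observed proportions.
tn93_kappas <- function(P1, P2, Q, pi, fallback = 2) {
  piA <- pi[["A"]]; piC <- pi[["C"]]; piG <- pi[["G"]]; piT <- pi[["T"]]
  piR <- piA + piG; piY <- piT + piC
  fail <- c(kR = fallback, kY = fallback)
  if (piA * piG <= 0 || piT * piC <= 0) return(fail)
  w3 <- 1 - Q / (2 * piR * piY)
  if (w3 <= 0) return(fail)
  bt <- -0.5 * log(w3)
  if (bt <= 0) return(fail)
  uR <- piR + piY * w3 - P1 * piR / (2 * piA * piG)
  uY <- piY + piR * w3 - P2 * piY / (2 * piT * piC)
  if (uR <= 0 || uY <= 0) return(fail)
  aRt <- (-0.5 * log(uR) - bt * piY) / piR
  aYt <- (-0.5 * log(uY) - bt * piR) / piY
  clamp <- function(x) min(max(x, 0.01), 99)
  c(kR = clamp(aRt / bt), kY = clamp(aYt / bt))
}

# Mutation-opportunity weighted site counting: each codon position splits
# its one site between synonymous and nonsynonymous in proportion to the
# rate-weighted fluxes kappa_ts * pi(target codon), mutations to stops
# excluded.
yn_site_counts <- function(counts, tab, pi64, kR, kY) {
  rowc <- rowSums(counts); colc <- colSums(counts)
  w_codon <- (rowc + colc) / (2 * sum(counts))
  tsfac <- c(kR, kY, 1)
  s_tot <- n_tot <- 0
  for (i in which(w_codon > 0)) {
    m <- tab$nbr[[i]]
    rate <- tsfac[m[, "tstype"]] * pi64[m[, "to64"]] * (m[, "stop"] == 0L)
    for (p in 1:3) {
      rows <- (3L * (p - 1L) + 1L):(3L * p)
      tot <- sum(rate[rows])
      if (tot <= 0) next
      fs <- sum(rate[rows][m[rows, "syn"] == 1L]) / tot
      s_tot <- s_tot + w_codon[i] * fs
      n_tot <- n_tot + w_codon[i] * (1 - fs)
    }
  }
  ncod <- sum(counts)
  c(s_sites = ncod * s_tot, n_sites = ncod * n_tot)
}

# Pathway-weighted difference counting at the current omega: pathway weight
# is the product of step rates kappa_ts * pi(target) * omega^(nonsyn);
# pathways through stops get zero weight (pi = 0) and the equal-weight
# fallback keeps sd + nd equal to the Hamming distance.
yn_difference_counts <- function(counts, tab, pi64, kR, kY, omega) {
  tsfac <- c(kR, kY, 1)
  obs <- which(counts > 0 & tab$ham > 0L, arr.ind = TRUE)
  sd_t <- c(0, 0, 0) # AG, TC, tv synonymous
  nd_t <- c(0, 0, 0)
  if (nrow(obs)) {
    for (r in seq_len(nrow(obs))) {
      i <- obs[r, 1L]; j <- obs[r, 2L]
      n_pair <- counts[i, j]
      pl <- tab$paths[[(i - 1L) * 64L + j]]
      w <- vapply(pl, function(st) {
        prod(tsfac[st[, 3L]] * pi64[st[, 1L]] *
               ifelse(st[, 2L] == 1L, 1, omega))
      }, numeric(1))
      if (sum(w) <= 0) w <- rep(1, length(w))
      w <- w / sum(w)
      for (pp in seq_along(pl)) {
        st <- pl[[pp]]
        for (sidx in seq_len(nrow(st))) {
          typ <- st[sidx, 3L]
          add <- w[pp] * n_pair
          if (st[sidx, 2L] == 1L) sd_t[typ] <- sd_t[typ] + add
          else nd_t[typ] <- nd_t[typ] + add
        }
      }
    }
  }
  list(sd_t = sd_t, nd_t = nd_t)
}

yn_core <- function(seq1, seq2, code_table, sequence, tn_model) {
  check_coding_pair(seq1, seq2)
  seq1 <- toupper(seq1); seq2 <- toupper(seq2)
  code <- genetic_code(code_table)
  tab <- codon_pair_tables(code)
  counts <- codon_pair_counts(seq1, seq2)
  assert_no_stops(counts, tab)
  method <- if (tn_model) "MYN" else "YN"
  len <- nchar(seq1)

  pi64 <- rep(0, 64)
  pi64[tab$sense] <- f3x4_codon_freqs(seq1, seq2, code)
  basef <- pair_base_freqs(seq1, seq2)

  # transition bias from the unconstrained site classes (0-fold + 4-fold)
  cc <- lwl_class_counts(counts, tab, adjusted = FALSE)
  arr <- tab$steps_raw
  cls_cnt <- function(cls, typ) sum(counts * arr[, , cls, typ])
  Lnf <- cc$L[1] + cc$L[3]
  P1 <- (cls_cnt(1, 1) + cls_cnt(3, 1)) / Lnf
  P2 <- (cls_cnt(1, 2) + cls_cnt(3, 2)) / Lnf
  Q <- (cc$tv[1] + cc$tv[3]) / Lnf
  if (tn_model) {
    kap <- tn93_kappas(P1, P2, Q, basef, fallback = 2)
    kR <- kap[["kR"]]; kY <- kap[["kY"]]
  } else {
    kR <- kY <- k2p_kappa(P1 + P2, Q, fallback = 2)
  }

  sites <- yn_site_counts(counts, tab, pi64, kR, kY)
  s_sites <- sites[["s_sites"]]; n_sites <- sites[["n_sites"]]

  if (sum(counts * tab$ham) == 0) { # identical pair
    return(new_kaks_row(sequence, method, 0, 0, s_sites, n_sites, 0, 0,
                        len, kappa = (kR + kY) / 2))
  }

  correct <- function(d_t, sites_n) {
    if (sites_n <= 0) return(NA_real_)
    if (tn_model) {
      tn93_distance(d_t[1] / sites_n, d_t[2] / sites_n, d_t[3] / sites_n,
                    basef)
    } else {
      ab <- k2p_components((d_t[1] + d_t[2]) / sites_n, d_t[3] / sites_n)
      if (anyNA(ab)) NA_real_ else ab[["A"]] + ab[["B"]]
    }
  }

  omega <- 0.5
  converged <- FALSE
  ks <- ka <- NA_real_
  sd <- nd <- NA_real_
  for (it in 1:100) {
    dc <- yn_difference_counts(counts, tab, pi64, kR, kY, omega)
    sd <- sum(dc$sd_t); nd <- sum(dc$nd_t)
    ks <- correct(dc$sd_t, s_sites)
    ka <- correct(dc$nd_t, n_sites)
    if (is.na(ks) || is.na(ka)) break
    if (ks <= 0) { converged <- TRUE; break } # no synonymous divergence
    omega_new <- ka / ks
    if (abs(omega_new - omega) < 1e-6) {
      omega <- omega_new
      converged <- TRUE
      break
    }
    omega <- omega_new
  }
  if (!converged && !is.na(ks) && !is.na(ka)) {
    warning(method, ": omega iteration did not converge for '", sequence,
            "'", call. = FALSE)
    return(new_kaks_row(sequence, method, NA_real_, NA_real_, s_sites,
                        n_sites, sd, nd, len, kappa = (kR + kY) / 2,
                        converged = FALSE))
  }
  new_kaks_row(sequence, method, ka, ks, s_sites, n_sites, sd, nd, len,
               kappa = (kR + kY) / 2, converged = converged)
}

#' @rdname kaks_methods
#' @export
yn00 <- function(seq1, seq2, code_table = 1L, sequence = "pair") {
  yn_core(seq1, seq2, code_table, sequence, tn_model = FALSE)
}

#' @rdname kaks_methods
#' @export
myn <- function(seq1, seq2, code_table = 1L, sequence = "pair") {
  yn_core(seq1, seq2, code_table, sequence, tn_model = TRUE)
}
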