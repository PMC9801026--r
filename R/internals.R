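# Internal codon machinery shared by every estimator: codon indexing,
# exhaustive single-step pathway enumeration between codon pairs, and
# per-code lookup tables. Tables are built once per genetic code and cached,
# so the per-alignment cost of the approximate methods is O(length + 64^2).

.kaksr_cache <- new.env(parent = emptyenv())

PURINES <- c("A", "G")

is_transition <- function(b1, b2) {
  (b1 %in% PURINES) == (b2 %in% PURINES)
}

# codon strings -> 1..64 indices in CODONS64 (TCAG order, first base slowest)
codon_indices <- function(seq) {
  b <- match(strsplit(seq, "")[[1]], BASES)
  if (anyNA(b)) stop("sequence contains non-ACGT characters", call. = FALSE)
  if (length(b) %% 3 != 0) {
    stop("sequence length not divisible by 3", call. = FALSE)
  }
  dim(b) <- c(3L, length(b) %/% 3L)
  (b[1, ] - 1L) * 16L + (b[2, ] - 1L) * 4L + b[3, ]
}

# 64 x 64 matrix of observed codon-pair counts for an aligned pair
codon_pair_counts <- function(seq1, seq2) {
  i1 <- codon_indices(seq1)
  i2 <- codon_indices(seq2)
  matrix(tabulate((i1 - 1L) * 64L + i2, nbins = 4096L), 64L, 64L, byrow = TRUE)
}

.perms <- list(
  matrix(1L, 1L, 1L),
  rbind(1:2, 2:1),
  rbind(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
        c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
)

# Lookup tables for one genetic code. Elements:
#   sense      logical(64)
#   aa         character(64)
#   ng_s/ng_n  per-codon expected synonymous / nonsynonymous sites, with
#              mutations to stop codons excluded from the per-position divisor
#   fold       64 x 3 degeneracy class (0/2/4), NA for stops
#   fold_count 64 x 3 count of positions per class (cols: 0-,2-,4-fold)
#   ham        64 x 64 codon Hamming distance
#   sd/nd      64 x 64 pathway-averaged synonymous / nonsynonymous differences
#   steps_raw  64 x 64 x 3 x 3 pathway-averaged difference counts by
#              degeneracy class (0/2/4) and type (A<->G transition, T<->C
#              transition, transversion)
#   steps_adj  same, with synonymous transversions at 2-fold sites re-pooled
#              as synonymous (transition-pool) counts: the arginine /
#              isoleucine special cases of the modified LWL counting
#   nbr        per sense codon: 9-row matrix of single-step neighbours
#              (cols to64, tstype 1=AG/2=TC/3=tv, syn, stop)
#   paths      per ordered sense pair: list of pathway step matrices
#              (cols to64, syn, tstype 1=AG/2=TC/3=tv) for likelihood-style
#              pathway weighting
codon_pair_tables <- function(code) {
  key <- paste0("tables_", code$table_id)
  if (!is.null(.kaksr_cache[[key]])) return(.kaksr_cache[[key]])

  aa <- unname(code$codon_to_aa)
  sense <- aa != "*"
  base_mat <- matrix(unlist(strsplit(CODONS64, "")), nrow = 3L)

  ng_s <- ng_n <- rep(NA_real_, 64L)
  fold <- matrix(NA_integer_, 64L, 3L)
  for (ci in which(sense)) {
    s <- n <- 0
    for (p in 1:3) {
      nb <- codon_neighbours(CODONS64[ci], p)
      keep <- code$codon_to_aa[nb] != "*"
      if (any(keep)) {
        syn <- sum(code$codon_to_aa[nb][keep] == aa[ci])
        s <- s + syn / sum(keep)
        n <- n + (sum(keep) - syn) / sum(keep)
      }
      fold[ci, p] <- degeneracy_class(CODONS64[ci], p, code)
    }
    ng_s[ci] <- s
    ng_n[ci] <- n
  }
  fold_count <- t(apply(fold, 1, function(f) {
    c(sum(f == 0L), sum(f == 2L), sum(f == 4L))
  }))
  fold_count[!sense, ] <- NA_integer_

  ham <- matrix(0L, 64L, 64L)
  sd <- nd <- matrix(0, 64L, 64L)
  steps_raw <- array(0, dim = c(64L, 64L, 3L, 3L))
  steps_adj <- array(0, dim = c(64L, 64L, 3L, 3L))
  paths <- vector("list", 4096L)

  cls_slot <- function(f) if (f == 0L) 1L else if (f == 2L) 2L else 3L
  step_tstype <- function(b1, b2) {
    if (!is_transition(b1, b2)) 3L
    else if (all(c(b1, b2) %in% PURINES)) 1L else 2L
  }

  nbr <- vector("list", 64L)
  for (i in which(sense)) {
    m <- matrix(0L, 9L, 4L)
    r <- 0L
    for (p in 1:3) {
      for (nb in codon_neighbours(CODONS64[i], p)) {
        r <- r + 1L
        to <- match(nb, CODONS64)
        m[r, ] <- c(to, step_tstype(base_mat[p, i], base_mat[p, to]),
                    as.integer(sense[to] && aa[to] == aa[i]),
                    as.integer(!sense[to]))
      }
    }
    colnames(m) <- c("to64", "tstype", "syn", "stop")
    nbr[[i]] <- m
  }

  for (i in which(sense)) {
    for (j in which(sense)) {
      dp <- which(base_mat[, i] != base_mat[, j])
      k <- length(dp)
      ham[i, j] <- k
      if (k == 0L) next
      pm <- .perms[[k]]
      npath <- nrow(pm)
      path_steps <- vector("list", npath)
      stop_free <- logical(npath)
      for (pp in seq_len(npath)) {
        cur <- i
        st <- matrix(0L, k, 5L) # from, to, pos, syn, tstype
        ok <- TRUE
        for (sidx in seq_len(k)) {
          pos <- dp[pm[pp, sidx]]
          nxt_codon <- `substr<-`(CODONS64[cur], pos, pos,
                                  base_mat[pos, j])
          nxt <- match(nxt_codon, CODONS64)
          b1 <- base_mat[pos, cur]; b2 <- base_mat[pos, nxt]
          tstype <- step_tstype(b1, b2)
          syn <- sense[cur] && sense[nxt] && aa[cur] == aa[nxt]
          st[sidx, ] <- c(cur, nxt, pos, as.integer(syn), tstype)
          if (!sense[nxt]) ok <- FALSE
          cur <- nxt
        }
        path_steps[[pp]] <- st
        stop_free[pp] <- ok
      }
      use <- if (any(stop_free)) which(stop_free) else seq_len(npath)
      w_path <- 1 / length(use)
      for (pp in use) {
        st <- path_steps[[pp]]
        for (sidx in seq_len(nrow(st))) {
          from <- st[sidx, 1L]; to <- st[sidx, 2L]; pos <- st[sidx, 3L]
          syn <- st[sidx, 4L] == 1L
          typ <- st[sidx, 5L]
          ts <- typ < 3L
          if (syn) sd[i, j] <- sd[i, j] + w_path
          else nd[i, j] <- nd[i, j] + w_path
          ff <- fold[from, pos]; ft <- fold[to, pos]
          if (is.na(ff) && is.na(ft)) { ff <- 0L; ft <- NA_integer_ }
          # conflicting classifications are resolved in favour of the more
          # degenerate class for synonymous differences and the less
          # degenerate class for nonsynonymous ones (the classical LWL
          # attribution rule)
          comps <- if (!is.na(ff) && !is.na(ft)) {
            if (ff == ft) {
              list(c(ff, 1))
            } else if (syn) {
              list(c(max(ff, ft), 1))
            } else {
              list(c(min(ff, ft), 1))
            }
          } else if (!is.na(ff)) list(c(ff, 1)) else list(c(ft, 1))
          for (cmp in comps) {
            cs <- cls_slot(cmp[1L]); w <- cmp[2L] * w_path
            steps_raw[i, j, cs, typ] <- steps_raw[i, j, cs, typ] + w
            # modified-LWL counting: classify 2-fold differences by actual
            # synonymity (arginine/isoleucine sites have synonymous
            # transversions and nonsynonymous transitions)
            atyp <- typ
            if (cmp[1L] == 2L) {
              if (syn && !ts) atyp <- 1L
              if (!syn && ts) atyp <- 3L
            }
            steps_adj[i, j, cs, atyp] <- steps_adj[i, j, cs, atyp] + w
          }
        }
      }
      paths[[(i - 1L) * 64L + j]] <- lapply(path_steps, function(st) {
        st[, c(2L, 4L, 5L), drop = FALSE]
      })
    }
  }

  out <- list(sense = sense, aa = aa, ng_s = ng_s, ng_n = ng_n,
              fold = fold, fold_count = fold_count, ham = ham,
              sd = sd, nd = nd, steps_raw = steps_raw,
              steps_adj = steps_adj, nbr = nbr, paths = paths)
  .kaksr_cache[[key]] <- out
  out
}

# Average base frequencies over both sequences of a pair
pair_base_freqs <- function(seq1, seq2) {
  ch <- c(strsplit(seq1, "")[[1]], strsplit(seq2, "")[[1]])
  tab <- table(factor(ch, levels = c("A", "C", "G", "T")))
  p <- as.numeric(tab) / sum(tab)
  names(p) <- c("A", "C", "G", "T")
  p
}

# F3x4 codon equilibrium frequencies over the sense codons of `code`,
# estimated from both sequences pooled; floored and renormalized so that
# every sense codon keeps positive mass.
f3x4_codon_freqs <- function(seq1, seq2, code) {
  ch1 <- strsplit(seq1, "")[[1]]
  ch2 <- strsplit(seq2, "")[[1]]
  pos <- rep_len(1:3, length(ch1))
  posfreq <- matrix(0, 4L, 3L, dimnames = list(BASES, NULL))
  for (p in 1:3) {
    tab <- table(factor(c(ch1[pos == p], ch2[pos == p]), levels = BASES))
    posfreq[, p] <- as.numeric(tab) / sum(tab)
  }
  b <- matrix(match(unlist(strsplit(CODONS64, "")), BASES), nrow = 3L)
  f <- posfreq[b[1, ], 1] * posfreq[b[2, ], 2] * posfreq[b[3, ], 3]
  sense <- code$codon_to_aa != "*"
  f <- f[sense]
  f <- (f + 1e-8) / sum(f + 1e-8)
  names(f) <- CODONS64[sense]
  f
}

# K2P transition (A) and transversion (B) distance components from observed
# transition/transversion proportions; NA outside the log domain.
k2p_components <- function(P, Q) {
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (is.na(w1) || is.na(w2) || w1 <= 0 || w2 <= 0) {
    return(c(A = NA_real_, B = NA_real_))
  }
  c(A = -0.5 * log(w1) + 0.25 * log(w2), B = -0.5 * log(w2))
}

# kappa = alpha/beta from pooled transition/transversion proportions
k2p_kappa <- function(P, Q, fallback = 1) {
  ab <- k2p_components(P, Q)
  if (anyNA(ab) || ab[["B"]] <= 0) return(fallback)
  kap <- 2 * ab[["A"]] / ab[["B"]]
  min(max(kap, 0.01), 99)
}
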