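# Non-coding substitution rates and the Kn/Ks selection statistic

mk_counts <- function(S, V, pi = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  structure(list(S = S, V = V, pi = pi, pi_R = pi[["A"]] + pi[["G"]],
                 pi_Y = pi[["T"]] + pi[["C"]], L = 1000,
                 n_diff = round(1000 * (S + V))),
            class = "pair_counts")
}

test_that("pair counting separates transitions from transversions", {
  cp <- count_pair("ACGT", "ACGT")
  expect_equal(cp$S, 0); expect_equal(cp$V, 0)
  cp <- count_pair("AAAA", "GGAA")
  expect_equal(cp$S, 0.5); expect_equal(cp$V, 0)
  cp <- count_pair("AAAA", "TTAA")
  expect_equal(cp$S, 0); expect_equal(cp$V, 0.5)
  expect_equal(sum(cp$pi), 1)
  expect_error(count_pair("", ""), "empty|length")
  expect_error(count_pair("AC-T", "ACGT"), "non-ACGT")
})

test_that("distances match closed forms and saturation guards", {
  z <- mk_counts(0, 0)
  expect_equal(jc_distance(z), 0)
  expect_equal(k2p_distance(z), 0)
  expect_equal(hky_distance(z), 0)
  expect_equal(k2p_distance(mk_counts(0.1, 0.05)), 0.170181,
               tolerance = 1e-6)
  expect_true(is.na(jc_distance(mk_counts(0.35, 0.4)))) # S+V = 0.75
  expect_true(is.na(k2p_distance(mk_counts(0.45, 0.2)))) # 2S+V >= 1
  expect_true(is.na(hky_distance(mk_counts(0.45, 0.2))))
})

test_that("HKY reduces to K2P at equal frequencies over an (S,V) grid", {
  for (S in seq(0.02, 0.4, by = 0.02)) {
    for (V in seq(0.02, 0.3, by = 0.02)) {
      if (2 * S + V >= 1 || 2 * V >= 1) next
      expect_equal(hky_distance(mk_counts(S, V)),
                   k2p_distance(mk_counts(S, V)), tolerance = 1e-10)
    }
  }
})

test_that("HKY matches JC when rates are JC-like and d is small", {
  # under JC, transitions are 1/3 of differences (S = V/2)
  for (p in c(0.01, 0.03, 0.05)) {
    cc <- mk_counts(p / 3, 2 * p / 3)
    expect_equal(hky_distance(cc), jc_distance(cc), tolerance = 1e-3)
  }
})

test_that("all three distances are monotone in S at fixed V", {
  for (fn in list(jc_distance, k2p_distance, hky_distance)) {
    d <- vapply(seq(0.02, 0.3, by = 0.02), function(S) {
      fn(mk_counts(S, 0.1))
    }, numeric(1))
    expect_true(all(diff(d) > 0))
  }
})

test_that("HKY weighs unequal base frequencies differently from K2P", {
  pi <- c(A = 0.4, C = 0.15, G = 0.25, T = 0.2)
  cc <- mk_counts(0.12, 0.06, pi)
  expect_gt(abs(hky_distance(cc) - k2p_distance(cc)), 1e-4)
})

test_that("xi classification is exact: xi > 1 iff Kn > Ks", {
  pairs <- tibble::tibble(name = "nc",
                          seq1 = strrep("ACGT", 250),
                          seq2 = strrep("ACGT", 250))
  # Kn = 0 with any positive Ks -> xi = 0
  r0 <- knks(pairs, model = "HKY", ks = 0.5)
  expect_equal(r0$kn, 0)
  expect_equal(r0$kn_ks, 0)
  sim <- sim_nuc(model = "HKY", length = 5000, t = 0.4, kappa = 4,
                 base_freqs = c(0.3, 0.2, 0.2, 0.3), seed = 8)
  r <- knks(sim, model = "HKY", ks = 0.3)
  expect_identical(r$kn_ks > 1, r$kn > r$ks)
  r2 <- knks(sim, model = "HKY", ks = 10)
  expect_identical(r2$kn_ks > 1, r2$kn > r2$ks)
  # undefined neutral rate
  expect_true(is.na(knks(sim, model = "HKY", ks = 0)$kn_ks))
})

test_that("Ks can come from an adjacent coding pair, one row each", {
  nc <- sim_nuc(model = "K2P", length = 2000, t = 0.3, kappa = 2, seed = 4)
  cds <- dplyr::bind_rows(
    sim_codon(model = "HKY", length = 500, t = 0.6, omega = 0.2, kappa = 2,
              seed = 14),
    sim_codon(model = "HKY", length = 500, t = 0.9, omega = 0.2, kappa = 2,
              seed = 15)
  )
  cds$name <- c("geneA", "geneB")
  r <- knks(nc, model = "K2P", cds = cds, cds_method = "MYN")
  expect_equal(nrow(r), 2L) # one xi per adjacent coding pair
  expect_match(r$ks_source, "^MYN:gene[AB]$")
  expect_false(r$ks[1] == r$ks[2])
  expect_equal(r$kn[1], r$kn[2]) # same non-coding distance
  # user value and cds are mutually exclusive; some source is required
  expect_error(knks(nc, ks = 1, cds = cds), "not both")
  expect_error(knks(nc, model = "HKY"), "Ks source")
})
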