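# The matrix-exponential pair simulator

test_that("sim_spec validates its inputs", {
  expect_error(sim_spec("nucleotide", model = "JC", length = 10, t = 0.1),
               "seed")
  expect_error(sim_spec("codon", model = "BOGUS", length = 10, t = 0.1,
                        seed = 1))
  expect_error(sim_spec("nucleotide", model = "JC", length = 10, t = -1,
                        seed = 1))
})

test_that("t = 0 yields identical pairs; seeds make runs reproducible", {
  for (kind_model in list(c("nucleotide", "HKY"), c("codon", "HKY"))) {
    p <- simulate_pair(sim_spec(kind_model[1], model = kind_model[2],
                                length = 200, t = 0, kappa = 2, seed = 2))
    expect_equal(p$seq1, p$seq2)
  }
  a <- sim_nuc(model = "K2P", length = 500, t = 0.2, kappa = 2, seed = 6)
  b <- sim_nuc(model = "K2P", length = 500, t = 0.2, kappa = 2, seed = 6)
  c <- sim_nuc(model = "K2P", length = 500, t = 0.2, kappa = 2, seed = 7)
  expect_identical(a, b)
  expect_false(identical(b$seq1, c$seq1))
  expect_match(a$name, "seed6") # seed echoed into the fixture name
})

test_that("JC divergence matches the closed-form expectation", {
  n <- 40000; t <- 0.2
  p_exp <- 0.75 * (1 - exp(-4 * t / 3))
  sim <- sim_nuc(model = "JC", length = n, t = t, seed = 12)
  cp <- count_pair(sim$seq1, sim$seq2)
  sigma <- sqrt(p_exp * (1 - p_exp) / n)
  expect_lt(abs(cp$S + cp$V - p_exp), 3 * sigma)
  # under JC, transitions are one third of differences
  expect_lt(abs(cp$S / (cp$S + cp$V) - 1 / 3), 0.03)
})

test_that("omega = 0 forbids amino-acid differences", {
  sim <- sim_codon(model = "HKY", length = 1000, t = 0.8, omega = 0,
                   kappa = 2, seed = 9)
  chk <- empirical_check(sim, "codon")
  expect_equal(chk$aa_diff, 0L)
  expect_gt(chk$sd, 0)
})

test_that("long-run composition matches the stationary frequencies", {
  pi <- c(0.4, 0.1, 0.2, 0.3)
  sim <- sim_nuc(model = "HKY", length = 50000, t = 0.3, kappa = 3,
                 base_freqs = pi, seed = 23)
  obs <- pair_base_freqs <- table(strsplit(sim$seq1, "")[[1]])[
    c("A", "C", "G", "T")] / 50000
  for (i in 1:4) {
    sigma <- sqrt(pi[i] * (1 - pi[i]) / 50000)
    expect_lt(abs(obs[[i]] - pi[i]), 4 * sigma)
  }
})

test_that("transition enrichment follows kappa", {
  # at kappa = 4 transitions should exceed the JC share 1/3 in most
  # replicates; a sign test over seeds
  wins <- 0L
  for (sd in rep_seeds(300, 12)) {
    sim <- sim_nuc(model = "HKY", length = 3000, t = 0.2, kappa = 4,
                   seed = sd)
    cp <- count_pair(sim$seq1, sim$seq2)
    if (cp$S / (cp$S + cp$V) > 0.5) wins <- wins + 1L
  }
  expect_gte(wins, 11L)
})

test_that("descendant statistics are exchangeable", {
  sim <- sim_codon(model = "HKY", length = 800, t = 0.4, omega = 0.5,
                   kappa = 2, seed = 33)
  swapped <- sim
  swapped$seq1 <- sim$seq2
  swapped$seq2 <- sim$seq1
  expect_equal(empirical_check(sim, "codon")[, -1],
               empirical_check(swapped, "codon")[, -1])
})

test_that("empirical_check reports all-zero summaries on identity", {
  p <- tibble::tibble(name = "x", seq1 = strrep("ATGGCT", 10),
                      seq2 = strrep("ATGGCT", 10))
  chk <- empirical_check(p, "codon")
  expect_equal(chk$S + chk$V + chk$sd + chk$nd + chk$aa_diff, 0)
})
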