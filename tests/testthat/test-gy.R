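# Goldman-Yang codon model: rate matrix, likelihood, fitting, model
# selection and averaging

test_that("rate matrix structure and scaling invariants hold", {
  m <- build_rate_matrix("JC", omega = 1)
  Q <- m$Q
  expect_equal(max(abs(rowSums(Q))), 0, tolerance = 1e-12)
  expect_equal(-sum(m$pi * diag(Q)), 1, tolerance = 1e-12)
  # all single-step off-diagonals equal under JC / equal freqs / omega 1
  off <- Q[row(Q) != col(Q)]
  expect_length(unique(round(off[off > 0], 12)), 1L)
  # omega 0 kills every nonsynonymous rate
  m0 <- build_rate_matrix("JC", omega = 0)
  gc1 <- genetic_code()
  aa <- gc1$codon_to_aa[rownames(m0$Q)]
  nonsyn <- outer(aa, aa, "!=")
  expect_true(all(m0$Q[nonsyn & row(m0$Q) != col(m0$Q)] == 0))
  # detailed balance for an HKY structure with skewed frequencies
  set.seed(1)
  f <- rexp(61); f <- f / sum(f)
  mh <- build_rate_matrix("HKY", omega = 0.4, kappa = 3, codon_freqs = f)
  flux <- mh$pi * mh$Q
  expect_lt(max(abs(flux - t(flux))), 1e-12)
  expect_error(build_rate_matrix("HKY", omega = -1), "non-negative")
})

test_that("HKY transition/transversion off-diagonal ratio equals kappa", {
  m <- build_rate_matrix("HKY", omega = 1, kappa = 4)
  # TTT -> TTC is a transition, TTT -> TTA a transversion, and with equal
  # codon frequencies the target frequencies match
  expect_equal(m$Q["TTT", "TTC"] / m$Q["TTT", "TTA"], 4, tolerance = 1e-10)
})

test_that("transition probabilities agree with series-summation expm", {
  m <- build_rate_matrix("GTR", omega = 0.5,
                         params = c(1.5, 4, 0.7, 1.2, 2.5))
  for (t in c(0.05, 0.4, 1.5)) {
    P1 <- kaksr:::cpp_gy_pmatrix(t, m$rates, m$omega, m$pi, m$steps)
    P2 <- oracle_expm_series(m$Q * t, nterms = 80)
    expect_lt(max(abs(P1 - P2)), 1e-8)
    expect_equal(rowSums(P1), rep(1, 61), tolerance = 1e-10)
    expect_true(all(P1 > -1e-12))
  }
})

test_that("log-likelihood behaves at t = 0 and is orientation-invariant", {
  m <- build_rate_matrix("HKY", omega = 0.5, kappa = 2)
  s <- "ATGGCTAAAGGGTTTCCC"
  ll0 <- pair_log_likelihood(s, s, m, t = 0)
  idx <- match(substring(s, seq(1, 18, 3), seq(3, 18, 3)),
               rownames(m$Q))
  expect_equal(ll0, sum(log(m$pi[idx])), tolerance = 1e-6)
  # non-identical pair at t = 0 collapses far below the identical pair
  expect_lt(pair_log_likelihood(s, sub("ATG", "ACG", s), m, t = 0),
            ll0 - 20)
  sim <- sim_codon(model = "HKY", length = 200, t = 0.4, omega = 0.5,
                   kappa = 2, seed = 13)
  expect_equal(pair_log_likelihood(sim$seq1, sim$seq2, m, 0.4),
               pair_log_likelihood(sim$seq2, sim$seq1, m, 0.4),
               tolerance = 1e-8)
})

test_that("fit_gy matches a grid-search oracle on a small fixture", {
  sim <- sim_codon(model = "HKY", length = 500, t = 0.5, omega = 0.3,
                   kappa = 2, seed = 77)
  fit <- suppressWarnings(fit_gy(sim$seq1, sim$seq2, model = "HKY"))
  # coarse-to-fine grid over (t, omega) at the fitted kappa
  kap <- fit$rates[2]
  grid_ll <- function(tt, om) {
    m <- build_rate_matrix("HKY", omega = om, kappa = kap,
                           codon_freqs = fit$pi)
    pair_log_likelihood(sim$seq1, sim$seq2, m, tt)
  }
  ts <- seq(0.2, 0.9, by = 0.02)
  oms <- seq(0.05, 1, by = 0.02)
  ll <- outer(ts, oms, Vectorize(grid_ll))
  best <- which(ll == max(ll), arr.ind = TRUE)
  expect_lt(abs(ts[best[1]] - fit$t), 0.025)
  expect_lt(abs(oms[best[2]] - fit$omega), 0.025)
  expect_gte(fit$lnL, max(ll) - 1e-3)
})

test_that("optimum dominates every multi-start initial point", {
  sim <- sim_codon(model = "K2P", length = 300, t = 0.3, omega = 0.8,
                   kappa = 2, seed = 19)
  fit <- fit_gy(sim$seq1, sim$seq2, model = "K2P")
  for (s in list(c(0.1, 0.5, 2), c(1, 1, 2), c(0.5, 0.1, 5))) {
    m <- build_rate_matrix("K2P", omega = s[2], kappa = s[3])
    expect_gte(fit$lnL + 1e-6,
               pair_log_likelihood(sim$seq1, sim$seq2, m, s[1]))
  }
})

test_that("identical pairs drive t to the lower bound", {
  s <- paste(rep("ATGGCTCGTAAAGGGTTC", 20), collapse = "")
  fit <- fit_gy(s, s, model = "HKY")
  expect_lt(fit$t, 1e-5)
  expect_lt(fit$ka, 1e-4)
  expect_lt(fit$ks, 1e-4)
})

test_that("omega recovery on a matched simulation", {
  sim <- sim_codon(model = "HKY", length = 5000, t = 0.5, omega = 0.2,
                   kappa = 2, seed = 99)
  fit <- fit_gy(sim$seq1, sim$seq2, model = "HKY")
  expect_lt(abs(fit$omega - 0.2), 0.05)
  expect_lt(abs(fit$t - 0.5), 0.05)
})

test_that("model selection ranks, tie-breaks and weights correctly", {
  sim <- sim_codon(model = "JC", length = 400, t = 0.3, omega = 0.5,
                   seed = 55)
  ms <- model_select(sim$seq1, sim$seq2, models = c("JC", "GTR"))
  expect_equal(ms$table$model[1], "JC") # AICc penalty on 5 extra params
  expect_equal(sum(ms$table$weight), 1, tolerance = 1e-12)
  # single candidate returned as best trivially
  ms1 <- model_select(sim$seq1, sim$seq2, models = "HKY")
  expect_equal(ms1$best$model, "HKY")
  expect_equal(ms1$table$weight, 1)
})

test_that("model averaging stays within the per-model hull", {
  sim <- sim_codon(model = "HKY", length = 600, t = 0.4, omega = 0.5,
                   kappa = 3, seed = 42)
  ms <- model_select(sim$seq1, sim$seq2,
                     models = c("JC", "K2P", "HKY", "TN"))
  ma <- model_average(ms)
  expect_equal(sum(ms$table$weight), 1, tolerance = 1e-12)
  expect_gte(ma$ka, min(ms$table$ka) - 1e-12)
  expect_lte(ma$ka, max(ms$table$ka) + 1e-12)
  expect_gte(ma$ks, min(ms$table$ks) - 1e-12)
  expect_lte(ma$ks, max(ms$table$ks) + 1e-12)
})

test_that("tidy and glance expose the fit in tabular form", {
  sim <- sim_codon(model = "HKY", length = 200, t = 0.3, omega = 0.5,
                   kappa = 2, seed = 3)
  fit <- fit_gy(sim$seq1, sim$seq2, model = "HKY")
  td <- tidy(fit)
  expect_true(all(c("t", "omega", "ka", "ks") %in% td$term))
  gl <- glance(fit)
  expect_equal(gl$model, "HKY")
  expect_equal(gl$lnL, fit$lnL)
  ms <- model_select(sim$seq1, sim$seq2, models = c("JC", "HKY"))
  expect_equal(nrow(tidy(ms)), 2)
  expect_s3_class(autoplot(ms), "ggplot")
})
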