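# Counting-based estimators: NG, LWL, LPB, MLWL, MLPB

test_that("NG site counting matches mutation enumeration", {
  expect_equal(unname(ng_site_counts("TTT")), c(1 / 3, 8 / 3))
  expect_equal(unname(ng_site_counts("ATG")), c(0, 3))
  expect_gte(ng_site_counts("GGG")[["s_sites"]], 1)
  # concatenation is additive
  expect_equal(unname(ng_site_counts("TTTATGGGG")),
               unname(ng_site_counts("TTT") + ng_site_counts("ATG") +
                        ng_site_counts("GGG")))
  expect_error(ng_site_counts("TAA"), "stop")
})

test_that("pathway-averaged differences match hand-derived cases", {
  expect_equal(unname(ng_difference_counts("TTT", "TTC")), c(1, 0))
  expect_equal(unname(ng_difference_counts("TTT", "GTA")), c(0.5, 1.5))
  expect_equal(unname(ng_difference_counts("AAA", "AAA")), c(0, 0))
})

test_that("jc correction has the right closed form and saturation guard", {
  expect_equal(jc_correct(0), 0)
  expect_equal(jc_correct(0.3), 0.383119, tolerance = 1e-6)
  expect_true(is.na(jc_correct(0.75)))
  expect_true(is.na(jc_correct(0.9)))
})

test_that("all approximate methods are symmetric and zero on identity", {
  fns <- list(ng86, lwl85, lpb93, mlwl, mlpb, yn00, myn)
  sim <- sim_codon(model = "HKY", length = 500, t = 0.5, omega = 0.4,
                   kappa = 3, seed = 11)
  ident <- paste(rep("ATGGCTCGTAAA", 20), collapse = "")
  for (fn in fns) {
    r0 <- fn(ident, ident)
    expect_equal(r0$ka, 0)
    expect_equal(r0$ks, 0)
    expect_true(is.na(r0$ka_ks))
    a <- fn(sim$seq1, sim$seq2)
    b <- fn(sim$seq2, sim$seq1)
    expect_equal(a$ka, b$ka, tolerance = 1e-10)
    expect_equal(a$ks, b$ks, tolerance = 1e-10)
  }
})

test_that("synonymous transitions only at 4-fold sites give Ks = A4", {
  # glycine repeats differing by third-position A<->G transitions
  n <- 120; nmut <- 30
  s1 <- paste(rep("GGA", n), collapse = "")
  s2 <- paste(rep(c("GGG", "GGA"), c(nmut, n - nmut)), collapse = "")
  r <- lwl85(s1, s2)
  p <- nmut / n
  a4 <- -0.5 * log(1 - 2 * p) # K2P transition distance, Q = 0
  expect_equal(r$ks, a4, tolerance = 1e-10)
  expect_equal(r$ka, 0)
  expect_equal(r$ka_ks, 0)
})

test_that("LPB and LWL Ks agree in the small-distance equal-rate limit", {
  # one transition and two transversions at 4-fold sites out of many codons:
  # kappa ~ 1 and d small, where the two combinations coincide
  n <- 3000
  s1 <- paste(rep("GGA", n), collapse = "")
  muts <- c("GGG", "GGC", "GGT")
  s2 <- paste(c(muts, rep("GGA", n - 3)), collapse = "")
  expect_equal(lpb93(s1, s2)$ks, lwl85(s1, s2)$ks, tolerance = 1e-3)
})

test_that("modified LWL reduces to LWL at kappa = 1 without special codons", {
  # pair built from codon families with no synonymous 2-fold transversions
  # (no arginine/isoleucine cases): identical counting at kappa = 1
  cod1 <- rep(c("GCT", "TTT", "AAA", "GAT", "GGA"), 30)
  cod2 <- cod1
  cod2[seq(1, 50, 5)] <- "GCC"   # syn transition, 4-fold
  cod2[seq(2, 50, 5)] <- "TTC"   # syn transition, 2-fold
  cod2[seq(53, 150, 10)] <- "AAG" # syn transition, 2-fold
  cod2[seq(54, 150, 10)] <- "GAC" # syn transition, 2-fold
  cod2[seq(55, 150, 10)] <- "GGC" # syn transversion, 4-fold
  cod2[seq(56, 150, 15)] <- "ACT" # nonsyn transition, 0-fold site
  cod2[seq(60, 150, 15)] <- "GAA" # nonsyn transition
  s1 <- paste(cod1, collapse = "")
  s2 <- paste(cod2, collapse = "")
  a <- mlwl(s1, s2, kappa = 1)
  b <- lwl85(s1, s2)
  expect_equal(a$ka, b$ka, tolerance = 1e-12)
  expect_equal(a$ks, b$ks, tolerance = 1e-12)
  expect_equal(a$s_sites, b$s_sites, tolerance = 1e-12)
  ap <- mlpb(s1, s2, kappa = 1)
  bp <- lpb93(s1, s2)
  expect_equal(ap$ka, bp$ka, tolerance = 1e-12)
  expect_equal(ap$ks, bp$ks, tolerance = 1e-12)
})

test_that("modified LWL counts synonymous arginine transversions as synonymous", {
  # CGA <-> AGA: first-position synonymous transversion (arginine family)
  n <- 60
  s1 <- paste(rep(c("CGA", "GGG"), n), collapse = "")
  cod2 <- rep(c("CGA", "GGG"), n)
  cod2[seq(1, 2 * n, 12)] <- "AGA" # 10 synonymous first-position tv
  s2 <- paste(cod2, collapse = "")
  raw <- lwl85(s1, s2)
  mod <- mlwl(s1, s2, kappa = 1)
  expect_gt(mod$ks, raw$ks) # reassigned to the synonymous pool
  expect_lt(mod$ka, raw$ka)
})

test_that("fisher test matches hypergeometric enumeration", {
  expect_equal(fisher_test_kaks(0, 0, 10, 10), 1)
  expect_equal(fisher_test_kaks(5, 5, 10, 10), 1)
  # 2x2 table [[10,0],[0,10]]: two-sided p = 2 / C(20,10)
  expect_equal(fisher_test_kaks(10, 0, 10, 10), 2 / choose(20, 10),
               tolerance = 1e-12)
  expect_true(is.na(fisher_test_kaks(NA, 1, 2, 3)))
})

test_that("monotonicity: Ka and Ks medians rise with divergence", {
  ts <- c(0.1, 0.3, 0.6)
  med <- sapply(ts, function(tt) {
    reps <- sapply(rep_seeds(500, 8), function(sd) {
      sim <- sim_codon(model = "HKY", length = 400, t = tt, omega = 0.5,
                       kappa = 2, seed = sd)
      r <- ng86(sim$seq1, sim$seq2)
      c(r$ka, r$ks)
    })
    apply(reps, 1, stats::median)
  })
  expect_true(all(diff(med[1, ]) >= 0))
  expect_true(all(diff(med[2, ]) >= 0))
})
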