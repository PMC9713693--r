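# Pearson matrix, circular shuffles, empirical p-values, KS comparison,
# BH fractions, ROI ranking.

makeToyPair <- function(n_roi = 2, n_el = 1, nf = 200, fill = NULL) {
  # build a TraceSet and a BandPowerSet sharing a frame axis, bands
  # theta/beta only, with caller-provided content
  ft <- (seq_len(nf) - 1) / 15
  bd <- canonicalBands()[1:2, ]
  pw <- array(abs(fill$power), c(n_el, 2, nf))
  bp <- BandPowerSet(pw, ft, bd)
  ts <- TraceSet(fill$dff, ft)
  list(ts = ts, bp = bp)
}

test_that("pearsonMatrix reproduces hand-computed and exact correlations", {
  nf <- 200
  set.seed(1)
  base <- abs(rnorm(nf)) + 1
  toy <- makeToyPair(fill = list(
    power = array(rep(base, each = 2), c(1, 2, nf)),
    dff = rbind(base, -base)))
  r <- pearsonMatrix(toy$ts, toy$bp)
  expect_equal(r[1, 1, "theta"], 1.0)
  expect_equal(r[2, 1, "theta"], -1.0)
  # 3-point worked example against the closed-form Pearson definition
  x <- c(1, 2, 3); y <- c(1, 2, 4)
  expect_equal(pearsonOracle(x, y), 0.9819805, tolerance = 1e-7)
  expect_equal(cor(x, y), pearsonOracle(x, y))
  # constant trace: NA flagged, never 0
  toy2 <- makeToyPair(fill = list(
    power = array(rep(base, each = 2), c(1, 2, nf)),
    dff = rbind(base, rep(1, nf))))
  r2 <- pearsonMatrix(toy2$ts, toy2$bp)
  expect_true(is.na(r2[2, 1, "theta"]))
  # mismatched frame axes
  ts3 <- TraceSet(matrix(rnorm(2 * 100), 2), (seq_len(100) - 1) / 15)
  expect_error(pearsonMatrix(ts3, toy$bp), "frame axes")
})

test_that("circular shuffles respect the shift bounds and preserve values", {
  set.seed(3)
  x <- rnorm(100)
  sh <- circularShuffle(x, n_shuffles = 50, seed = 7)
  expect_equal(dim(sh), c(50, 100))
  for (i in seq_len(50)) {
    expect_equal(sort(sh[i, ]), sort(x))
    # recover the realized shift and check 10 <= s <= 90
    s <- (which(sh[i, ] == x[1]) - 1) %% 100
    expect_true(any(s >= 10 & s <= 90))
  }
  # shuffles break alignment: |cor| with the original drops below 1
  ac <- as.numeric(filter(rnorm(300), 0.95, method = "recursive"))
  shc <- circularShuffle(ac, n_shuffles = 20, seed = 1)
  expect_lt(mean(abs(cor(ac, t(shc)))), 0.9)
  expect_error(circularShuffle(rnorm(5)), "at least 10")
})

test_that("empirical p-values follow the permutation formula", {
  expect_equal(empiricalP(0.9, rnorm(100) * 0.1), 1 / 101)
  nulls <- c(-0.5, -0.2, 0.2, 0.5)
  expect_equal(empiricalP(0, nulls), 1)
  expect_equal(empiricalP(0.35, nulls), 3 / 5)
  # array form agrees with scalar form elementwise
  obs <- array(rnorm(8), c(2, 2, 2))
  nll <- array(rnorm(8 * 30), c(2, 2, 2, 30))
  p <- empiricalP(obs, nll)
  for (i in 1:2) for (j in 1:2) for (k in 1:2)
    expect_equal(p[i, j, k], empiricalP(obs[i, j, k], nll[i, j, k, ]))
  # invariance under shuffle relabeling
  perm <- sample(30)
  expect_equal(empiricalP(obs, nll[, , , perm]), p)
  expect_error(empiricalP(0.5, numeric(0)), "null draw")
})

test_that("the 1-D KS statistic matches the brute-force CDF-gap oracle", {
  set.seed(9)
  for (rep in 1:20) {
    a <- rnorm(sample(5:50, 1))
    b <- rnorm(sample(5:50, 1), mean = runif(1, -1, 1))
    ks <- ksOriginalVsShuffled(a, b)
    expect_equal(ks$ks_stat, ks1dOracle(a, b), tolerance = 1e-12)
  }
  expect_equal(ksOriginalVsShuffled(1:10, 1:10)$ks_stat, 0)
  set.seed(10)
  s1 <- rnorm(1000)
  ks2 <- ksOriginalVsShuffled(s1, s1 + 0.5)
  expect_lt(ks2$ks_p, 0.001)
  expect_error(ksOriginalVsShuffled(numeric(0), 1:3), "non-empty")
})

test_that("BH step-up matches the hand-applied thresholds", {
  p <- array(NA_real_, c(4, 1, 1))
  p[, 1, 1] <- c(0.01, 0.02, 0.30, 0.04)
  # hand step-up: sorted p (0.01, 0.02, 0.04, 0.30) vs i/m * q
  # (0.0125, 0.025, 0.0375, 0.05): p_(3) = 0.04 > 0.0375, so exactly the
  # two smallest are significant
  f <- fdrFractions(p, fdr_q = 0.05)
  expect_equal(sum(f$significant), 2)
  expect_false(f$significant[3, 1, 1])
  expect_false(f$significant[4, 1, 1])
  expect_equal(unname(f$fraction_significant), 0.5)
  # degenerate corners
  p1 <- array(1, c(3, 2, 1))
  expect_equal(unname(fdrFractions(p1)$fraction_significant), 0)
  p0 <- array(0.001, c(3, 2, 1))
  expect_equal(unname(fdrFractions(p0)$fraction_significant), 1)
})

test_that("full analysis detects the coupled ROIs in the small session", {
  s <- smallSession()
  bp <- smallBandPower()
  res <- correlationAnalysis(s$traces, bp, n_shuffles = 100, seed = 5)
  # coupled half correlates with theta, uncoupled half does not
  expect_gt(mean(rho(res)[1:5, , "theta"]), 0.1)
  expect_lt(mean(abs(rho(res)[6:10, , "theta"])), 0.1)
  expect_gt(significantFraction(res)["theta"], 0.2)
  expect_lt(significantFraction(res, shuffled = TRUE)["theta"], 0.1)
  expect_lt(res@ks_p["theta"], 0.001)
  # determinism in the seed
  res2 <- correlationAnalysis(s$traces, bp, n_shuffles = 100, seed = 5)
  expect_identical(rho(res2), rho(res))
  expect_identical(empiricalPValues(res2), empiricalPValues(res))
})

test_that("ROI ranking by band correlation behaves at the edges", {
  s <- smallSession()
  bp <- smallBandPower()
  res <- correlationAnalysis(s$traces, bp, n_shuffles = 50, seed = 6)
  top <- topCorrelatedRois(res, "theta", k = 4)
  expect_equal(nrow(top), 4)
  expect_true(all(top$roi_id %in% sprintf("roi_%03d", 0:4)))
  expect_true(all(diff(top$mean_rho) <= 0))
  expect_equal(nrow(topCorrelatedRois(res, "theta", k = 0)), 0)
  expect_warning(big <- topCorrelatedRois(res, "theta", k = 99),
                 "truncating")
  expect_equal(nrow(big), 10)
  expect_error(topCorrelatedRois(res, "delta"), "unknown band")
})
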