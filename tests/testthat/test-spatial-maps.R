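# Head velocity, transient positions, occupancy-normalized maps, 2-D KS.

lineTrack <- function(n = 300, rate = 30, step = 30) {
  BehaviorTrack((seq_len(n) - 1) / rate,
                cbind(seq_len(n) * step, rep(100, n)), rate_hz = rate)
}

test_that("head velocity matches constant, zero and circular motion", {
  # straight line at 30 px/frame, 30 fps -> 900 px/s
  v <- headVelocity(lineTrack(), smooth_window_s = 0)
  expect_true(all(abs(v - 900) / 900 < 0.01))
  # stationary -> 0
  still <- BehaviorTrack((0:99) / 30, cbind(rep(5, 100), rep(5, 100)))
  expect_equal(headVelocity(still), rep(0, 100))
  # circle radius R, period T -> speed 2 pi R / T within 2%
  R <- 200; T <- 10; rate <- 30
  tt <- (0:(T * rate - 1)) / rate
  circ <- BehaviorTrack(tt, cbind(300 + R * cos(2 * pi * tt / T),
                                  300 + R * sin(2 * pi * tt / T)))
  vc <- headVelocity(circ, smooth_window_s = 0.2)
  interior <- seq(10, length(tt) - 10)
  expect_true(all(abs(vc[interior] - 2 * pi * R / T) / (2 * pi * R / T)
                  < 0.02))
  dup <- BehaviorTrack(c(0, 1, 2) / 30, cbind(1:3, 1:3))
  dup@times_s[2] <- 0
  expect_error(headVelocity(dup), "strictly increasing|duplicate")
})

test_that("transient onsets are localized in time and space", {
  nf <- 450
  ft <- (seq_len(nf) - 1) / 15
  set.seed(4)
  trace <- rnorm(nf, sd = 0.001)
  trace[150:160] <- 2                       # one square pulse
  track <- lineTrack(n = 900)
  pos <- transientPositions(trace, ft, track, threshold_sd = 5)
  expect_equal(nrow(pos), 1)
  expect_equal(pos$frame, 150)
  # nearest track sample: frame 150 at t=9.933 s -> track x = 30 * round(t*30)
  expect_lt(abs(pos$x_px - 30 * (round(ft[150] * 30) + 1)), 31)
  # threshold above the trace max -> empty, not an error
  none <- transientPositions(trace, ft, track, threshold_sd = 1e6)
  expect_equal(nrow(none), 0)
})

test_that("place-cell transients cluster around the field center", {
  # arena sized so the walk mixes over the field within the session
  ctr <- matrix(c(150, 150), 1)
  cfg <- sessionConfig(n_rois = 1, n_electrodes = 4, duration_s = 300,
                       ephys_rate_hz = 250, arena_px = c(300, 300),
                       place_field_centers = ctr,
                       place_field_sigma_px = 60, baseline_rate_hz = 6,
                       noise_sd = 0.05, seed = 17)
  s <- generateSession(cfg)
  pos <- transientPositions(dff(s$traces)[1, ], frameTimes(s$traces),
                            s$track, threshold_sd = 3)
  expect_gt(nrow(pos), 10)
  d <- sqrt((pos$x_px - 150)^2 + (pos$y_px - 150)^2)
  expect_gte(mean(d <= 2 * 60), 0.7)
})

test_that("spatial maps normalize by occupancy and respect the mask", {
  # uniform occupancy and activity -> flat normalized map
  nx <- 12
  n <- nx * nx * 20
  cells <- expand.grid(x = seq_len(nx), y = seq_len(nx))
  ord <- rep(seq_len(nrow(cells)), 20)
  track <- BehaviorTrack((seq_len(n) - 1) / 30,
                         cbind((cells$x[ord] - 0.5) * 25,
                               (cells$y[ord] - 0.5) * 25))
  ft <- (seq_len(n) - 1) / 30            # imaging at the video rate here
  m <- buildSpatialMap(rep(1, n), ft, track, arena_px = c(300, 300))
  inner <- m@normalized[3:10, 3:10]
  expect_lt(max(inner) / min(inner), 1.05)
  # doubling occupancy with the same activity halves the map
  track2 <- BehaviorTrack((seq_len(2 * n) - 1) / 30,
                          cbind((cells$x[rep(ord, 2)] - 0.5) * 25,
                                (cells$y[rep(ord, 2)] - 0.5) * 25))
  m2 <- buildSpatialMap(rep(1, n), ft, track2, arena_px = c(300, 300))
  expect_equal(m2@normalized, m@normalized / 2, tolerance = 1e-9)
  # all activity in one bin, sigma = 0 -> single nonzero bin
  tr0 <- rep(0, n); tr0[1] <- 5
  m0 <- buildSpatialMap(tr0, ft, track, arena_px = c(300, 300),
                        sigma_px = 0)
  expect_equal(sum(m0@normalized > 0, na.rm = TRUE), 1)
  expect_error(buildSpatialMap(tr0, ft, track, bin_px = 0), "bin_px")
  # occupancy conservation: total time within one frame duration
  expect_equal(sum(m@occupancy_s), n / 30, tolerance = 1 / 30)
  # unvisited bins are NA, not zero
  sparse <- BehaviorTrack((0:99) / 30, cbind(rep(30, 100), rep(30, 100)))
  msp <- buildSpatialMap(rep(1, 100), (0:99) / 30, sparse,
                         arena_px = c(300, 300))
  expect_true(any(is.na(msp@normalized)))
  expect_false(any(msp@normalized == 0, na.rm = TRUE))
})

test_that("smoothing preserves mass over the visited support", {
  set.seed(12)
  n <- 3000
  track <- BehaviorTrack((seq_len(n) - 1) / 30,
                         cbind(runif(n, 0, 300), runif(n, 0, 300)))
  tr <- abs(rnorm(n))
  ft <- (seq_len(n) - 1) / 30
  m_a <- buildSpatialMap(tr, ft, track, arena_px = c(300, 300),
                         sigma_px = 62.5)
  m_b <- buildSpatialMap(tr, ft, track, arena_px = c(300, 300),
                         sigma_px = 30)
  sum_a <- sum(m_a@normalized, na.rm = TRUE)
  sum_b <- sum(m_b@normalized, na.rm = TRUE)
  expect_lt(abs(sum_a - sum_b) / sum_b, 0.01)
})

test_that("the 2-D KS statistic matches the brute-force quadrant oracle", {
  set.seed(21)
  for (rep in 1:12) {
    n1 <- sample(5:30, 1); n2 <- sample(5:30, 1)
    x1 <- runif(n1); y1 <- runif(n1)
    x2 <- runif(n2, 0.2); y2 <- runif(n2, 0.2)
    expect_equal(caephys:::ff2dStat(x1, y1, x2, y2),
                 ks2dOracle(x1, y1, x2, y2), tolerance = 1e-12)
  }
  # D is within [0, 1] and invariant under a shared affine transform
  x1 <- rnorm(40); y1 <- rnorm(40); x2 <- rnorm(40, 1); y2 <- rnorm(40, 1)
  d0 <- caephys:::ff2dStat(x1, y1, x2, y2)
  expect_true(d0 >= 0 && d0 <= 1)
  d1 <- caephys:::ff2dStat(3 * x1 + 7, 0.5 * y1 - 2,
                           3 * x2 + 7, 0.5 * y2 - 2)
  expect_equal(d1, d0, tolerance = 1e-12)
})

test_that("map comparisons separate distinct maps and not identical ones", {
  mkmap <- function(cx, cy, seed) {
    set.seed(seed)
    n <- 4000
    track <- BehaviorTrack((seq_len(n) - 1) / 30,
                           cbind(runif(n, 0, 300), runif(n, 0, 300)))
    xy <- trackXY(track)
    tr <- exp(-((xy[, 1] - cx)^2 + (xy[, 2] - cy)^2) / (2 * 20^2))
    buildSpatialMap(tr, (seq_len(n) - 1) / 30, track,
                    arena_px = c(300, 300))
  }
  mA <- mkmap(70, 70, 1)
  mB <- mkmap(230, 230, 2)     # centers ~10 sigma apart
  same <- ks2dCompare(mA, mA, n_resample = 200, seed = 5, n_perm = 49)
  expect_equal(same$D, 0)
  diff2 <- ks2dCompare(mA, mB, n_resample = 500, seed = 5, n_perm = 199)
  expect_lt(diff2$p, 0.01)
  # determinism per seed
  diff3 <- ks2dCompare(mA, mB, n_resample = 500, seed = 5, n_perm = 199)
  expect_identical(diff2, diff3)
})

test_that("pairwise map tests count pairs and flag separated fields", {
  mkmap <- function(cx, cy, seed) {
    set.seed(seed)
    n <- 3000
    track <- BehaviorTrack((seq_len(n) - 1) / 30,
                           cbind(runif(n, 0, 300), runif(n, 0, 300)))
    xy <- trackXY(track)
    tr <- exp(-((xy[, 1] - cx)^2 + (xy[, 2] - cy)^2) / (2 * 18^2))
    buildSpatialMap(tr, (seq_len(n) - 1) / 30, track,
                    arena_px = c(300, 300))
  }
  maps <- list(mkmap(60, 60, 1), mkmap(240, 60, 2),
               mkmap(60, 240, 3), mkmap(240, 240, 4))
  res <- pairwiseMapTests(maps, n_resample = 400, seed = 9, n_perm = 199)
  expect_equal(nrow(res), 6)
  expect_true(all(res$significant))
  two <- pairwiseMapTests(maps[1:2], n_resample = 200, seed = 9,
                          n_perm = 49)
  expect_equal(nrow(two), 1)
  # identical maps (same underlying draws): no significant pairs
  m1 <- mkmap(150, 150, 7)
  res0 <- pairwiseMapTests(list(m1, m1, m1), n_resample = 200, seed = 11,
                           n_perm = 49)
  expect_equal(sum(res0$significant), 0)
  expect_error(pairwiseMapTests(list(m1)), "at least 2")
})
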