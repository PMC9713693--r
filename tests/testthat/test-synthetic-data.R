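# Synthetic session and calibration-image generators.

test_that("identical config and seed reproduce the session bit for bit", {
  cfg <- sessionConfig(n_rois = 3, n_electrodes = 4, duration_s = 20,
                       ephys_rate_hz = 250, seed = 11)
  a <- generateSession(cfg)
  b <- generateSession(cfg)
  expect_identical(dff(a$traces), dff(b$traces))
  expect_identical(voltageUV(a$ephys), voltageUV(b$ephys))
  expect_identical(a$spikes@spikes, b$spikes@spikes)
  expect_identical(trackXY(a$track), trackXY(b$track))
  c <- generateSession(sessionConfig(n_rois = 3, n_electrodes = 4,
                                     duration_s = 20, ephys_rate_hz = 250,
                                     seed = 12))
  expect_false(identical(dff(a$traces), dff(c$traces)))
})

test_that("session shapes follow the configured geometry", {
  s <- smallSession()
  expect_equal(dim(dff(s$traces)), c(10, 120 * 15))
  expect_equal(dim(voltageUV(s$ephys)), c(16, 120 * 250))
  expect_equal(length(unique(tetrodeOf(s$ephys))), 4)
  expect_equal(nrow(trackXY(s$track)), 120 * 30)
  # full-scale geometry without generating 10 minutes of data: the frame
  # counts derive from rates alone
  cfg <- sessionConfig(n_rois = 100, n_electrodes = 16, duration_s = 600)
  expect_equal(round(cfg$duration_s * cfg$imaging_rate_hz), 9000)
  expect_equal(nrow(cfg$coupling_matrix), 100)
})

test_that("constant-rate spiking matches Poisson expectations", {
  cfg <- sessionConfig(n_rois = 8, n_electrodes = 4, duration_s = 100,
                       ephys_rate_hz = 250, baseline_rate_hz = 2, seed = 5)
  s <- generateSession(cfg)
  for (st in s$truth$spike_times) {
    expect_true(all(diff(st) > 0))
    expect_lt(abs(length(st) - 2 * 100), 4 * sqrt(2 * 100))
  }
})

test_that("latent drives carry their configured carrier frequencies", {
  cfg <- sessionConfig(n_rois = 2, n_electrodes = 4, duration_s = 60,
                       ephys_rate_hz = 250, seed = 9)
  s <- generateSession(cfg)
  lat <- s$truth$latent_drives
  for (b in seq_along(cfg$latent_freqs_hz)) {
    sp <- Mod(fft(lat[, b]))^2
    n <- nrow(lat)
    fgrid <- (seq_len(n) - 1) * cfg$ephys_rate_hz / n
    half <- fgrid <= cfg$ephys_rate_hz / 2
    fpk <- fgrid[half][which.max(sp[half])]
    expect_lt(abs(fpk - cfg$latent_freqs_hz[b]), 1)
  }
})

test_that("dF/F-band coupling shows up in, and only in, the coupled band", {
  # one ROI coupled to theta only, no dF/F noise: its correlation with
  # theta power must beat every other band
  cm <- matrix(0, 1, 4); cm[1, 1] <- 1
  cfg <- sessionConfig(n_rois = 1, n_electrodes = 4, duration_s = 120,
                       ephys_rate_hz = 250, coupling_matrix = cm,
                       noise_sd = 0, seed = 21)
  s <- generateSession(cfg)
  bp <- bandPowerTraces(s$ephys, frameTimes(s$traces))
  r <- pearsonMatrix(s$traces, bp)
  mean_by_band <- apply(r, 3, mean)
  expect_equal(which.max(mean_by_band), c(theta = 1L))
  expect_true(all(mean_by_band["theta"] > mean_by_band[-1]))
})

test_that("zero coupling leaves ROI x band correlations centered on zero", {
  cfg <- sessionConfig(n_rois = 13, n_electrodes = 16, duration_s = 120,
                       ephys_rate_hz = 250, seed = 31)
  s <- generateSession(cfg)
  bp <- bandPowerTraces(s$ephys, frameTimes(s$traces))
  r <- pearsonMatrix(s$traces, bp)
  n_frames <- sum(validFrames(bp))
  expect_gt(length(r), 200)
  expect_lt(mean(abs(r)), 3 / sqrt(n_frames))
})

test_that("invalid session configs are rejected with a message", {
  expect_error(sessionConfig(duration_s = -1), "duration")
  expect_error(sessionConfig(imaging_rate_hz = 0), "rates")
  expect_error(sessionConfig(noise_sd = NaN), "non-finite")
  expect_error(sessionConfig(n_rois = 5,
                             coupling_matrix = matrix(0, 2, 4)),
               "coupling_matrix")
})

test_that("place fields concentrate spiking near the field center", {
  ctr <- matrix(c(150, 150), 1)
  cfg <- sessionConfig(n_rois = 1, n_electrodes = 4, duration_s = 240,
                       ephys_rate_hz = 250, arena_px = c(600, 600),
                       place_field_centers = ctr, baseline_rate_hz = 5,
                       seed = 8)
  s <- generateSession(cfg)
  st <- s$truth$spike_times[[1]]
  tt <- trackTimes(s$track)
  xy <- trackXY(s$track)
  idx <- vapply(st, function(t0) which.min(abs(tt - t0)), integer(1))
  d <- sqrt((xy[idx, 1] - 150)^2 + (xy[idx, 2] - 150)^2)
  # spikes should sit well inside the bump compared to the overall track
  d_all <- sqrt((xy[, 1] - 150)^2 + (xy[, 2] - 150)^2)
  expect_lt(median(d), 0.6 * median(d_all))
})

test_that("grid images have the requested period and reject sub-pixel grids", {
  img <- generateGridImage(50, 2, n_lines = 4, noise_sd = 0)
  expect_equal(ncol(img), 4 * 100)
  profile <- colMeans(img)
  pk <- which(diff(sign(diff(profile))) == -2) + 1
  expect_equal(diff(pk), rep(100, 3), tolerance = 1e-6)
  expect_error(generateGridImage(50, 0.03, n_lines = 2), "unresolvable")
  one <- generateGridImage(50, 2, n_lines = 1, noise_sd = 0)
  expect_equal(which.max(colMeans(one)), 50)
})

test_that("bead stacks place the requested beads without overlap", {
  st <- generateBeadStack(2, 10, n_beads = 6, px_per_um = 4, z_step_um = 2,
                          seed = 3)
  ctr <- attr(st, "bead_centers")
  expect_equal(nrow(ctr), 6)
  dmat <- as.matrix(dist(ctr[, 1:2]))
  diag(dmat) <- Inf
  sxy <- 2 / 2.3548 * 4
  expect_true(all(dmat >= 6 * sxy))
  # single noiseless bead: voxel max at the placed center within a pixel
  one <- generateBeadStack(2, 10, n_beads = 1, px_per_um = 4, z_step_um = 2,
                           seed = 4)
  c1 <- attr(one, "bead_centers")
  pk <- which(one == max(one), arr.ind = TRUE)[1, ]
  expect_lt(abs(pk[2] - c1[1, 1]), 1)   # x = column
  expect_lt(abs(pk[1] - c1[1, 2]), 1)   # y = row
  expect_lt(abs(pk[3] - c1[1, 3]), 1)
  expect_error(generateBeadStack(30, 10, n_beads = 50, px_per_um = 4,
                                 dim_xy = 64),
               "too small|overlap")
})

test_that("calibration images round-trip through TIFF", {
  img <- generateGridImage(50, 2, n_lines = 3, noise_sd = 0)
  f <- withr::local_tempfile(fileext = ".tif")
  writeImageTiff(img, f)
  back <- readImageTiff(f)
  expect_equal(dim(back), dim(img))
  # intensities are rescaled to [0, 1]; structure is preserved
  expect_gt(cor(as.vector(back), as.vector(img)), 0.999)
  st <- generateBeadStack(2, 8, n_beads = 2, px_per_um = 3, z_step_um = 2,
                          seed = 6, dim_xy = 64)
  f2 <- withr::local_tempfile(fileext = ".tif")
  writeImageTiff(st, f2)
  back2 <- readImageTiff(f2)
  expect_equal(dim(back2), dim(st))
})
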