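# Magnification, FOV, and FWHM recovery from synthetic calibration images.

test_that("magnification is recovered from grid image pairs within 1%", {
  ref_scale <- 2                       # px per um without the lens system
  # identical image as its own reference -> M = 1
  ref <- generateGridImage(50, ref_scale, n_lines = 8, noise_sd = 0.02,
                           seed = 1)
  expect_equal(magnificationFromGrid(ref, ref_scale), 1, tolerance = 0.01)
  # the two systems' magnifications used as recovery fixtures
  for (M_true in c(1.07, 1.89)) {
    img <- generateGridImage(50, ref_scale * M_true, n_lines = 6,
                             noise_sd = 0.02, seed = 2)
    M <- magnificationFromGrid(img, ref_scale)
    expect_equal(M, M_true, tolerance = 0.01)
  }
  # featureless image: rejected
  set.seed(3)
  flat <- matrix(rnorm(128 * 400, sd = 0.05), 128, 400)
  expect_error(magnificationFromGrid(flat, ref_scale),
               "no periodic structure")
})

test_that("FOV by 10%-peak counting reproduces count x spacing", {
  for (spec in list(c(8, 400), c(7, 350), c(1, 50))) {
    img <- generateGridImage(50, 2, n_lines = spec[1], noise_sd = 0.02,
                             seed = 4)
    if (spec[1] == 1) {
      # a single line carries no period; count the one peak directly
      expect_equal(fovFromGrid(img), 50)
    } else {
      expect_equal(fovFromGrid(img), spec[2])
    }
    # intensity scaling leaves the count unchanged
    expect_equal(fovFromGrid(img * 1000), fovFromGrid(img))
  }
})

test_that("lateral FWHM is recovered within 5% and corrected by 1/M", {
  # System B fixture: true 0.62 um, M = 1.89, so the image shows
  # 0.62 * 1.89 um at the reference scale
  scale <- 6
  img <- generateBeadStack(0.62 * 1.89, 10, n_beads = 8, px_per_um = scale,
                           z_step_um = 2, n_z = 1, seed = 5,
                           noise_sd = 0.01)
  lat <- lateralFwhm(img, n_beads = 5, magnification = 1.89,
                     px_per_um = scale, seed = 6)
  expect_equal(lat$fwhm_um, 0.62, tolerance = 0.05)
  expect_equal(nrow(lat$per_bead), 5)
  # System A fixture: 1.63 um at M = 1.07
  imgA <- generateBeadStack(1.63 * 1.07, 10, n_beads = 8, px_per_um = scale,
                            z_step_um = 2, n_z = 1, seed = 7,
                            noise_sd = 0.01)
  latA <- lateralFwhm(imgA, n_beads = 5, magnification = 1.07,
                      px_per_um = scale, seed = 8)
  expect_equal(latA$fwhm_um, 1.63, tolerance = 0.05 * 1.63)
  # noiseless single bead: near-exact recovery, M = 1 is the identity
  one <- generateBeadStack(2, 10, n_beads = 1, px_per_um = 4, n_z = 1,
                           seed = 9, noise_sd = 0)
  l1 <- lateralFwhm(one, n_beads = 1, magnification = 1, px_per_um = 4)
  expect_equal(l1$fwhm_um, 2, tolerance = 1e-3)
  ctr <- attr(one, "bead_centers")
  expect_lt(abs(l1$per_bead$center_px - ctr[1, 1]), 0.1)
  expect_error(lateralFwhm(one, n_beads = 5), "only 1 beads")
})

test_that("axial FWHM is recovered within 5% and corrected by 1/M^2", {
  # System A fixture: true 32.56 um, M = 1.07 -> apparent 32.56 * 1.07^2
  st <- generateBeadStack(1.63 * 1.07, 32.56 * 1.07^2, n_beads = 6,
                          px_per_um = 6, z_step_um = 2, seed = 10,
                          noise_sd = 0.01)
  ax <- axialFwhm(st, n_beads = 5, magnification = 1.07, z_step_um = 2,
                  seed = 11)
  expect_equal(ax$fwhm_um, 32.56, tolerance = 0.05 * 32.56)
  # System B fixture: 17.74 um at M = 1.89
  stB <- generateBeadStack(0.62 * 1.89, 17.74 * 1.89^2, n_beads = 6,
                           px_per_um = 6, z_step_um = 2, seed = 12,
                           noise_sd = 0.01)
  axB <- axialFwhm(stB, n_beads = 5, magnification = 1.89, z_step_um = 2,
                   seed = 13)
  expect_equal(axB$fwhm_um, 17.74, tolerance = 0.05 * 17.74)
  # 1/M^2 arithmetic: M = 2 quarters the reported value
  one <- generateBeadStack(2, 20, n_beads = 1, px_per_um = 4,
                           z_step_um = 2, seed = 14, noise_sd = 0)
  a1 <- axialFwhm(one, n_beads = 1, magnification = 1, z_step_um = 2)
  a2 <- axialFwhm(one, n_beads = 1, magnification = 2, z_step_um = 2)
  expect_equal(a2$fwhm_um, a1$fwhm_um / 4, tolerance = 1e-12)
  expect_equal(a1$fwhm_um, 20, tolerance = 0.02 * 20)
})

test_that("beads truncated by the stack boundary are skipped with warning", {
  # stack trimmed so every bead's z profile clips the boundary
  st <- generateBeadStack(2, 30, n_beads = 3, px_per_um = 4, z_step_um = 2,
                          seed = 15, noise_sd = 0)
  nz <- dim(st)[3]
  ctr <- attr(st, "bead_centers")
  clipped <- st[, , seq(ceiling(median(ctr[, 3])), nz)]
  w <- capture_warnings(
    expect_error(axialFwhm(clipped, n_beads = 3, z_step_um = 2),
                 "no untruncated beads"))
  expect_true(all(grepl("truncated|fit failed", w)) && length(w) >= 1)
})

test_that("the assembled optics report recovers a full system profile", {
  ref_scale <- 6
  M_true <- 1.07
  grid <- generateGridImage(50, ref_scale * M_true, n_lines = 8,
                            noise_sd = 0.02, seed = 16)
  beads <- generateBeadStack(1.63 * M_true, 32.56 * M_true^2, n_beads = 7,
                             px_per_um = ref_scale, z_step_um = 2,
                             seed = 17, noise_sd = 0.01)
  rep <- opticsReport(grid, beads, reference_px_per_um = ref_scale,
                      z_step_um = 2, seed = 18)
  expect_equal(rep@magnification, M_true, tolerance = 0.01)
  expect_equal(rep@fov_um, 400)
  expect_equal(rep@lateral_fwhm_um, 1.63, tolerance = 0.05 * 1.63)
  expect_equal(rep@axial_fwhm_um, 32.56, tolerance = 0.05 * 32.56)
  expect_output(show(rep), "OpticsReport")
})
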