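# Optical characterization of a GRIN-lens imaging system from calibration
# images: magnification from a grid slide, field of view by peak counting,
# and lateral/axial resolution from Gaussian fits to bead profiles with
# 1/M and 1/M^2 magnification corrections.

FWHM_PER_SIGMA <- 2.3548200450309493   # 2 sqrt(2 ln 2)

# Mean column profile of a grid image and its period in pixels, from the
# first off-zero autocorrelation peak refined by parabolic interpolation.
gridPeriodPx <- function(image) {
  profile <- colMeans(image)
  x <- profile - mean(profile)
  n <- length(x)
  ac <- as.numeric(stats::acf(x, lag.max = floor(n / 2), plot = FALSE,
                              demean = FALSE)$acf)
  peaks <- localMaxima(ac[-1], min_sep = 2L)
  noise_floor <- mad(ac[-1])
  peaks <- peaks[ac[peaks + 1] > 3 * noise_floor]
  if (!length(peaks))
    stop("no periodic structure detected in grid image", call. = FALSE)
  lag0 <- min(peaks)                       # first repeat distance
  refinePeak(ac, lag0 + 1L) - 1            # acf index 1 is lag 0
}

#' Magnification from a grid-slide image pair
#'
#' The grid slide is imaged once without the lens system to calibrate the
#' reference pixels-per-micrometer, then through the system; magnification
#' is the factor by which pixels-per-micrometer increased. The grid period
#' is measured from the autocorrelation peak of the mean line profile.
#'
#' @param image grid image taken through the imaging system (matrix).
#' @param reference_px_per_um calibrated scale without the system.
#' @param grid_spacing_um physical grid spacing (50 for the standard slide).
#' @return magnification M (dimensionless).
#' @export
magnificationFromGrid <- function(image, reference_px_per_um,
                                  grid_spacing_um = 50) {
  period_px <- gridPeriodPx(image)
  (period_px / grid_spacing_um) / reference_px_per_um
}

#' Field of view from a grid-slide image
#'
#' Subtracts a rolling-minimum baseline from the mean fluorescence profile
#' and counts the grid-line peaks exceeding `threshold_frac` of the profile
#' maximum; FOV = peak count x grid spacing. The count is invariant to
#' global intensity scaling. `method = "span"` instead reports the distance
#' between the extreme qualifying peaks converted to micrometers.
#'
#' @param image grid image (matrix).
#' @param grid_spacing_um physical grid spacing.
#' @param threshold_frac peak qualification threshold, fraction of max.
#' @param method `"count"` (default) or `"span"`.
#' @return field of view in micrometers.
#' @export
fovFromGrid <- function(image, grid_spacing_um = 50, threshold_frac = 0.10,
                        method = c("count", "span")) {
  method <- match.arg(method)
  profile <- colMeans(image)
  period <- tryCatch(gridPeriodPx(image), error = function(e) NA_real_)
  win <- if (is.na(period)) max(3, length(profile) / 4) else period
  base <- rollingMin(profile, win)
  p <- pmax(0, profile - base)
  sep <- if (is.na(period)) 2L else max(2L, floor(period / 2))
  pk <- localMaxima(p, min_sep = sep)
  pk <- pk[p[pk] > threshold_frac * max(p)]
  if (!length(pk))
    stop("no qualifying peaks in grid profile", call. = FALSE)
  if (method == "count") length(pk) * grid_spacing_um
  else diff(range(pk)) / period * grid_spacing_um
}

# Detect bead candidates in a 2-D image: 8-neighborhood local maxima above
# background + 5 * robust SD, deduplicated by a minimum separation (the
# brightest candidate wins) and re-centered on the local peak. Fitting is
# insensitive to small off-center detections because a 2-D Gaussian's row
# profile keeps its sigma at any vertical offset.
detectBeads <- function(image, min_sep = 12) {
  bg <- median(image)
  s <- mad(image)
  if (s == 0) s <- max(sd(image) / 5, 1e-12)
  thr <- bg + 5 * s
  n <- nrow(image); m <- ncol(image)
  ctr <- image[2:(n - 1), 2:(m - 1)]
  lm <- ctr > thr
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    lm <- lm & (ctr >= image[2:(n - 1) + dr, 2:(m - 1) + dc])
  }
  cand <- which(lm, arr.ind = TRUE)
  if (!nrow(cand)) return(cand)
  cand <- cand + 1L
  cand <- cand[order(image[cand], decreasing = TRUE), , drop = FALSE]
  keep <- matrix(NA_integer_, 0, 2)
  for (i in seq_len(nrow(cand))) {
    p <- cand[i, ]
    if (!nrow(keep) ||
        all((keep[, 1] - p[1])^2 + (keep[, 2] - p[2])^2 >= min_sep^2))
      keep <- rbind(keep, p, deparse.level = 0)
  }
  unname(keep)
}

# 1-D Gaussian fit amp * exp(-(x - c)^2 / (2 s^2)) + b; returns sigma.
fitGaussian1d <- function(y, x = seq_along(y)) {
  b0 <- min(y)
  a0 <- max(y) - b0
  c0 <- x[which.max(y)]
  above <- which(y - b0 >= a0 / 2)
  s0 <- max(1, diff(range(x[above]))) / FWHM_PER_SIGMA
  fit <- minpack.lm::nlsLM(
    y ~ a * exp(-(x - c)^2 / (2 * s^2)) + b,
    start = list(a = a0, c = c0, s = s0, b = b0),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  co <- stats::coef(fit)
  list(sigma = abs(co[["s"]]), center = co[["c"]], amp = co[["a"]],
       offset = co[["b"]])
}

#' Lateral resolution from a bead image
#'
#' Fits a 1-D Gaussian to the horizontal line profile through the center
#' of each of `n_beads` randomly sampled detected beads (local maxima
#' above 5 robust SDs of background), reports the mean FWHM
#' (`2 sqrt(2 ln 2) sigma`) corrected for magnification by 1/M.
#'
#' @param bead_image 2-D bead-field matrix, or the 3-D stack from
#'   [generateBeadStack()] (each bead is measured in its brightest slice).
#' @param n_beads beads to sample (without replacement, seeded).
#' @param magnification system magnification M for the 1/M correction.
#' @param px_per_um reference lateral scale in pixels per micrometer.
#' @param seed integer seed for the bead sampling.
#' @param profile_halfwidth_px half-length of the fitted line profile;
#'   default adapts to the detected spot size.
#' @return list with `fwhm_um` (corrected mean), `per_bead` data.frame.
#' @export
lateralFwhm <- function(bead_image, n_beads = 5, magnification = 1,
                        px_per_um = 1, seed = 1L,
                        profile_halfwidth_px = NULL) {
  # for stacks, detect and fit on the z-mean projection: a separable
  # Gaussian keeps its lateral sigma under z-averaging, and noise shrinks
  img2d <- if (length(dim(bead_image)) == 3)
    apply(bead_image, c(1, 2), mean) else as.matrix(bead_image)
  beads <- detectBeads(img2d)
  if (nrow(beads) < n_beads)
    stop(sprintf("only %d beads detected, need %d", nrow(beads), n_beads),
         call. = FALSE)
  pick <- withSeed(seed, sample.int(nrow(beads), n_beads))
  fits <- lapply(pick, function(i) {
    r <- beads[i, 1]; c0 <- beads[i, 2]
    half <- profile_halfwidth_px
    if (is.null(half)) {
      # adapt: walk out until the profile falls below half max
      row <- img2d[r, ]
      bg <- median(img2d)
      hm <- bg + (row[c0] - bg) / 2
      right <- which(row[c0:length(row)] < hm)[1]
      half <- max(6L, 4L * (if (is.na(right)) 6L else right))
    }
    cols <- max(1, c0 - half):min(ncol(img2d), c0 + half)
    f <- fitGaussian1d(img2d[r, cols], cols)
    data.frame(row = r, col = c0, sigma_px = f$sigma, center_px = f$center)
  })
  per_bead <- do.call(rbind, fits)
  fwhm_px <- FWHM_PER_SIGMA * mean(per_bead$sigma_px)
  list(fwhm_um = fwhm_px / px_per_um / magnification, per_bead = per_bead)
}

#' Axial resolution from a bead z-stack
#'
#' Fits a 1-D Gaussian to the z profile through each sampled bead's
#' brightest voxel and reports the mean FWHM corrected for magnification
#' by 1/M^2. Beads truncated by the stack boundary (profile peak on the
#' first/last slice or fitted extent leaving the stack) are skipped with a
#' warning.
#'
#' @param bead_stack 3-D array (y, x, z), e.g. from [generateBeadStack()].
#' @param n_beads beads to sample.
#' @param magnification system magnification M.
#' @param z_step_um axial step between slices, micrometers.
#' @param seed integer seed for the sampling.
#' @return list with `fwhm_um` (corrected mean), `per_bead` data.frame.
#' @export
axialFwhm <- function(bead_stack, n_beads = 5, magnification = 1,
                      z_step_um = 1, seed = 1L) {
  stopifnot(length(dim(bead_stack)) == 3)
  proj <- apply(bead_stack, c(1, 2), mean)
  beads <- detectBeads(proj)
  if (nrow(beads) < n_beads)
    stop(sprintf("only %d beads detected, need %d", nrow(beads), n_beads),
         call. = FALSE)
  pick <- withSeed(seed, sample.int(nrow(beads), n_beads))
  nz <- dim(bead_stack)[3]
  fits <- list()
  for (i in pick) {
    zprof <- bead_stack[beads[i, 1], beads[i, 2], ]
    zmax <- which.max(zprof)
    if (zmax == 1 || zmax == nz) {
      warning(sprintf("bead at (%d, %d) truncated by stack boundary; skipped",
                      beads[i, 1], beads[i, 2]), call. = FALSE)
      next
    }
    f <- tryCatch(fitGaussian1d(zprof), error = function(e) NULL)
    if (is.null(f)) {
      warning(sprintf("Gaussian fit failed for bead at (%d, %d); skipped",
                      beads[i, 1], beads[i, 2]), call. = FALSE)
      next
    }
    if (f$center - FWHM_PER_SIGMA * f$sigma < 1 ||
        f$center + FWHM_PER_SIGMA * f$sigma > nz) {
      warning(sprintf("bead at (%d, %d) extends beyond the stack; skipped",
                      beads[i, 1], beads[i, 2]), call. = FALSE)
      next
    }
    fits[[length(fits) + 1]] <-
      data.frame(row = beads[i, 1], col = beads[i, 2], sigma_sl = f$sigma)
  }
  if (!length(fits))
    stop("no untruncated beads available for the axial fit", call. = FALSE)
  per_bead <- do.call(rbind, fits)
  fwhm_sl <- FWHM_PER_SIGMA * mean(per_bead$sigma_sl)
  list(fwhm_um = fwhm_sl * z_step_um / magnification^2, per_bead = per_bead)
}

#' Assemble a full optics report
#'
#' Runs the four characterization procedures on a grid image and a bead
#' stack and returns an [OpticsReport-class].
#'
#' @param grid_image grid-slide image through the system.
#' @param bead_stack bead z-stack through the system.
#' @param reference_px_per_um calibrated scale without the system.
#' @param grid_spacing_um grid spacing in micrometers.
#' @param z_step_um axial step of the stack.
#' @param n_beads beads per FWHM estimate.
#' @param seed sampling seed.
#' @return an [OpticsReport-class].
#' @export
opticsReport <- function(grid_image, bead_stack, reference_px_per_um,
                         grid_spacing_um = 50, z_step_um = 1, n_beads = 5,
                         seed = 1L) {
  M <- magnificationFromGrid(grid_image, reference_px_per_um,
                             grid_spacing_um)
  fov <- fovFromGrid(grid_image, grid_spacing_um)
  lat <- lateralFwhm(bead_stack, n_beads, magnification = M,
                     px_per_um = reference_px_per_um, seed = seed)
  ax <- axialFwhm(bead_stack, n_beads, magnification = M,
                  z_step_um = z_step_um, seed = seed)
  methods::new("OpticsReport", magnification = M, fov_um = fov,
               lateral_fwhm_um = lat$fwhm_um, axial_fwhm_um = ax$fwhm_um,
               n_beads_used = as.integer(n_beads),
               bead_fits = merge(lat$per_bead, ax$per_bead,
                                 by = c("row", "col"), all = TRUE))
}
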