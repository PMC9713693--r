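# Synthetic calibration images: grid-slide targets and fluorescent bead
# fields, used as recovery fixtures for the optics QC operations.

#' Generate a synthetic grid-slide calibration image
#'
#' Renders a 2-D image of a grid calibration target: bright vertical lines
#' with Gaussian cross-profile every `spacing_um * px_per_um` pixels, plus
#' additive Gaussian noise. The frame width is sized so exactly `n_lines`
#' lines fall inside it.
#'
#' @param spacing_um grid line spacing in micrometers (50 for the standard
#'   grid slide).
#' @param px_per_um image scale in pixels per micrometer.
#' @param n_lines number of grid lines inside the frame.
#' @param noise_sd additive Gaussian noise sd (line peak is 1).
#' @param seed integer seed; the image is deterministic per seed.
#' @param height_px image height in pixels.
#' @param line_sigma_px Gaussian cross-profile sigma of each line.
#'
#' @return a numeric matrix (rows = y, columns = x).
#' @export
generateGridImage <- function(spacing_um, px_per_um, n_lines = 8,
                              noise_sd = 0.02, seed = 1L, height_px = 128,
                              line_sigma_px = 1.2) {
  stopifnot(spacing_um > 0, px_per_um > 0, n_lines >= 1)
  period <- spacing_um * px_per_um
  if (period < 2)
    stop("grid spacing finer than 2 px is unresolvable", call. = FALSE)
  width <- round(n_lines * period)
  centers <- (seq_len(n_lines) - 0.5) * period
  xs <- seq_len(width)
  profile <- rep(0, width)
  for (c0 in centers)
    profile <- profile + exp(-0.5 * ((xs - c0) / line_sigma_px)^2)
  img <- matrix(profile, height_px, width, byrow = TRUE)
  if (noise_sd > 0)
    img <- img + withSeed(seed,
      matrix(rnorm(height_px * width, sd = noise_sd), height_px, width))
  img
}

#' Generate a synthetic fluorescent bead stack
#'
#' Places `n_beads` 3-D Gaussian spots with the requested lateral and axial
#' FWHMs at random non-overlapping positions (minimum separation 6 lateral
#' sigmas, margins keeping every bead clear of the x/y borders and untruncated
#' in z). With `n_z = 1` the result is a single bead-field image usable for
#' lateral measurements alone.
#'
#' @param fwhm_xy_um true lateral FWHM of each bead image, micrometers.
#' @param fwhm_z_um true axial FWHM, micrometers.
#' @param n_beads number of beads.
#' @param px_per_um lateral scale, pixels per micrometer.
#' @param z_step_um axial step between slices, micrometers.
#' @param seed integer seed.
#' @param dim_xy lateral image size in pixels (square).
#' @param n_z number of z slices; default spans 10 axial sigmas.
#' @param noise_sd additive Gaussian noise sd (bead peak is 1).
#'
#' @return a 3-D array (y, x, z) with attributes `bead_centers` (n x 3,
#'   pixel/slice units), `px_per_um` and `z_step_um`.
#' @export
generateBeadStack <- function(fwhm_xy_um, fwhm_z_um, n_beads = 10,
                              px_per_um = 4, z_step_um = 2, seed = 1L,
                              dim_xy = 256, n_z = NULL, noise_sd = 0) {
  stopifnot(fwhm_xy_um > 0, fwhm_z_um > 0, n_beads >= 1)
  sxy <- fwhm_xy_um / 2.3548200450309493 * px_per_um   # px
  sz <- fwhm_z_um / 2.3548200450309493 / z_step_um     # slices
  if (is.null(n_z)) n_z <- max(1L, ceiling(10 * sz) + 1L)
  margin_xy <- 4 * sxy + 2
  margin_z <- if (n_z > 1) 3.5 * sz else 0
  if (2 * margin_xy >= dim_xy)
    stop("image too small for the requested bead size", call. = FALSE)
  if (n_z > 1 && 2 * margin_z >= n_z)
    stop("stack too shallow to hold untruncated beads", call. = FALSE)
  centers <- withSeed(seed, {
    out <- matrix(NA_real_, 0, 3)
    tries <- 0
    while (nrow(out) < n_beads) {
      tries <- tries + 1
      if (tries > 2000 * n_beads)
        stop("could not place beads without overlap", call. = FALSE)
      p <- c(runif(1, margin_xy, dim_xy - margin_xy),
             runif(1, margin_xy, dim_xy - margin_xy),
             if (n_z > 1) runif(1, 1 + margin_z, n_z - margin_z) else 1)
      if (nrow(out) == 0 ||
          all(sqrt((out[, 1] - p[1])^2 + (out[, 2] - p[2])^2) >= 6 * sxy + 4))
        out <- rbind(out, p)
    }
    out
  })
  stack <- array(0, c(dim_xy, dim_xy, n_z))
  ys <- seq_len(dim_xy)
  for (i in seq_len(n_beads)) {
    gx <- exp(-0.5 * ((ys - centers[i, 1]) / sxy)^2)
    gy <- exp(-0.5 * ((ys - centers[i, 2]) / sxy)^2)
    gz <- if (n_z > 1)
      exp(-0.5 * ((seq_len(n_z) - centers[i, 3]) / sz)^2) else 1
    spot <- outer(gy, gx)                 # rows = y, cols = x
    for (k in seq_len(n_z))
      stack[, , k] <- stack[, , k] + spot * gz[k]
  }
  if (noise_sd > 0)
    stack <- stack + withSeed(splitSeed(seed, 99),
      array(rnorm(length(stack), sd = noise_sd), dim(stack)))
  attr(stack, "bead_centers") <- centers
  attr(stack, "px_per_um") <- px_per_um
  attr(stack, "z_step_um") <- z_step_um
  stack
}

#' Read or write calibration images as TIFF
#'
#' Thin wrappers over the `tiff` package for moving grid/bead images in
#' and out of the optics QC functions. Multi-page TIFFs map to the third
#' array dimension (z).
#'
#' @param path file path.
#' @param image matrix or 3-D array; intensities are rescaled to the
#'   TIFF unit range on write.
#' @return `readImageTiff()` returns a matrix (single page) or a 3-D
#'   array (y, x, z); `writeImageTiff()` returns `path` invisibly.
#' @export
readImageTiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("package 'tiff' is required for TIFF input", call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) == 1) return(pages[[1]])
  array(unlist(pages), c(dim(pages[[1]]), length(pages)))
}

#' @rdname readImageTiff
#' @export
writeImageTiff <- function(image, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("package 'tiff' is required for TIFF output", call. = FALSE)
  lo <- min(image); hi <- max(image)
  scaled <- if (hi > lo) (image - lo) / (hi - lo) else image * 0
  if (length(dim(scaled)) == 3) {
    pages <- lapply(seq_len(dim(scaled)[3]), function(k) scaled[, , k])
    tiff::writeTIFF(pages, path)
  } else {
    tiff::writeTIFF(as.matrix(scaled), path)
  }
  invisible(path)
}
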