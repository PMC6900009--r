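#' Synthetic short-axis ring phantom
#'
#' Builds a 2-D image of a left-ventricular short-axis slice: a circular
#' blood pool surrounded by a myocardial annulus, with optional Gaussian
#' pixel noise. Pixel membership is decided at pixel centres: the pool is
#' `r < r_endo`, the annulus `r_endo <= r < r_epi`.
#'
#' @param n Image size in pixels (n x n grid).
#' @param center Numeric length-2, annulus centre in pixel coordinates
#'   (x, y); defaults to the grid centre.
#' @param r_endo,r_epi Endocardial / epicardial radii in pixels
#'   (`0 < r_endo < r_epi`, annulus fully inside the grid).
#' @param myo_signal,blood_signal Noise-free signal values (a.u.).
#' @param noise_sd SD of additive Gaussian pixel noise.
#' @param seed Integer seed; required when `noise_sd > 0`.
#' @param septal_angle Direction of the septal reference (degrees,
#'   counter-clockwise from the +x axis); sector ROIs are measured relative
#'   to it.
#' @return A `phantom_image`: `pixels` matrix (row = y, column = x), logical
#'   `myo_mask` and `blood_mask` (disjoint), and the geometry fields.
#' @examples
#' ph <- make_phantom(r_endo = 20, r_epi = 30, myo_signal = 1, blood_signal = 2)
#' @export
make_phantom <- function(n = 96, center = NULL, r_endo = 20, r_epi = 30,
                         myo_signal = 1, blood_signal = 2,
                         noise_sd = 0, seed = NULL, septal_angle = 0) {
  if (is.null(center)) center <- c((n + 1) / 2, (n + 1) / 2)
  if (r_endo <= 0 || r_epi <= r_endo) {
    stop("radii must satisfy 0 < r_endo < r_epi")
  }
  if (center[1] - r_epi < 0.5 || center[1] + r_epi > n + 0.5 ||
      center[2] - r_epi < 0.5 || center[2] + r_epi > n + 0.5) {
    stop(sprintf("annulus of radius %.1f px around (%.1f, %.1f) falls outside the %d px grid",
                 r_epi, center[1], center[2], n))
  }
  if (noise_sd > 0 && is.null(seed)) stop("a `seed` is required when `noise_sd` > 0")
  grid <- matrix(0, n, n)
  x <- col(grid)   # pixel-centre x
  y <- row(grid)   # pixel-centre y
  r <- sqrt((x - center[1])^2 + (y - center[2])^2)
  blood_mask <- r < r_endo
  myo_mask <- r >= r_endo & r < r_epi
  pixels <- matrix(0, n, n)
  pixels[blood_mask] <- blood_signal
  pixels[myo_mask] <- myo_signal
  if (noise_sd > 0) {
    pixels <- pixels + withr::with_seed(seed, matrix(stats::rnorm(n * n, 0, noise_sd), n, n))
  }
  structure(list(pixels = pixels, n = n, center = center,
                 r_endo = r_endo, r_epi = r_epi,
                 septal_angle = septal_angle,
                 myo_mask = myo_mask, blood_mask = blood_mask,
                 noise_sd = noise_sd, seed = seed),
            class = "phantom_image")
}

#' @export
print.phantom_image <- function(x, ...) {
  cat(sprintf("<phantom_image> %dx%d px, annulus %.1f-%.1f px around (%.1f, %.1f)\n",
              x$n, x$n, x$r_endo, x$r_epi, x$center[1], x$center[2]))
  invisible(x)
}

#' Write a phantom image to NIfTI
#'
#' @param image A `phantom_image`.
#' @param path Output file (`.nii` / `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_phantom_nifti <- function(image, path) {
  stopifnot(inherits(image, "phantom_image"))
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("writing NIfTI requires the RNifti package")
  }
  RNifti::writeNifti(RNifti::asNifti(image$pixels), path)
  invisible(path)
}

#' Write a phantom image to PNG for visual inspection
#'
#' Signals are linearly rescaled to [0, 1].
#'
#' @param image A `phantom_image`.
#' @param path Output `.png` file.
#' @return `path`, invisibly.
#' @export
write_phantom_png <- function(image, path) {
  stopifnot(inherits(image, "phantom_image"))
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("writing PNG requires the png package")
  }
  px <- image$pixels
  rng <- range(px)
  scaled <- if (diff(rng) > 0) (px - rng[1]) / diff(rng) else px * 0
  png::writePNG(scaled, path)
  invisible(path)
}
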