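## Grayscale micrograph quantification and a synthetic micrograph generator.
##
## Experimentally, bead counts are not directly observable; the chamber image
## is thresholded at the mean background gray level G and quantified by pixel
## counts (coverage) and by the summed excess intensity I = sum(G_ij - G)
## over suprathreshold chamber pixels (bead amount).  Rates follow as ratios
## of I between frames.  The synthetic generator renders bead spots on an
## uneven background with known ground truth so the whole pipeline is
## testable without laboratory data.

#' Circular region-of-interest mask
#'
#' @param nrow,ncol image size (pixels)
#' @param center (row, col) center, pixels; defaults to the image center
#' @param radius radius in pixels
#' @return logical matrix
#' @export
circle_mask <- function(nrow, ncol, center = c((nrow + 1) / 2, (ncol + 1) / 2),
                        radius = min(nrow, ncol) / 2 - 1) {
  outer(seq_len(nrow), seq_len(ncol),
        function(r, c) (r - center[1])^2 + (c - center[2])^2 <= radius^2)
}

#' Mean background gray level
#'
#' @param image numeric matrix of gray values
#' @param background_mask logical matrix, TRUE on background pixels
#' @return arithmetic mean gray level G
#' @export
background_level <- function(image, background_mask) {
  if (!any(background_mask)) stop("background mask is empty")
  mean(image[background_mask])
}

#' Coverage rate from an image
#'
#' COR = 100 P_p / P with P_p the chamber (ROI) pixels strictly brighter
#' than the background level G and P the ROI pixel count.  The threshold is
#' strict (> G) so exact-background pixels never count as beads.
#'
#' @param image numeric matrix
#' @param roi logical ROI (chamber) mask
#' @param G background gray level, from [background_level()]
#' @return COR in percent
#' @export
coverage_from_image <- function(image, roi, G) {
  if (!any(roi)) stop("ROI mask is empty")
  100 * sum(image[roi] > G) / sum(roi)
}

## summed excess intensity over suprathreshold ROI pixels
intensity_index <- function(image, roi, G) {
  v <- image[roi]
  sum(v[v > G] - G)
}

#' Capture rate from image intensity
#'
#' CPR = 100 I_t / I_1 where I = sum(G_ij - G) over suprathreshold ROI
#' pixels and I_1 is the same index of the reference (initial, lowest-flow)
#' frame.
#'
#' @param image image at the measured condition
#' @param reference_image reference frame defining I_1
#' @param roi logical ROI mask shared by both images
#' @param background_mask logical background mask shared by both images
#' @return CPR in percent
#' @export
intensity_capture_rate <- function(image, reference_image, roi,
                                   background_mask) {
  if (!identical(dim(image), dim(reference_image)))
    stop("image and reference differ in size")
  I1 <- intensity_index(reference_image, roi,
                        background_level(reference_image, background_mask))
  if (I1 <= 0) stop("reference intensity index is not positive")
  It <- intensity_index(image, roi, background_level(image, background_mask))
  100 * It / I1
}

#' Release rate from an image series
#'
#' RER(t) = 100 (1 - I_t / I_0), clamped to [0, 100], with I_0 the intensity
#' index of the initial frame.
#'
#' @param images list of frames, time-ordered
#' @param initial_image frame defining I_0
#' @param roi logical ROI mask
#' @param background_mask logical background mask
#' @return numeric vector of RER (percent), one per frame
#' @export
release_rate_from_images <- function(images, initial_image, roi,
                                     background_mask) {
  I0 <- intensity_index(initial_image, roi,
                        background_level(initial_image, background_mask))
  if (I0 <= 0) stop("initial intensity index is not positive")
  vapply(images, function(im) {
    It <- intensity_index(im, roi, background_level(im, background_mask))
    min(max(100 * (1 - It / I0), 0), 100)
  }, numeric(1))
}

#' Synthesize a chamber micrograph
#'
#' Renders beads as Gaussian spots on an uneven background (tilted plane
#' plus a low-frequency bump) with additive Gaussian noise, quantized to the
#' requested bit depth.  Ground truth (bead pixel mask, true background
#' plane, per-bead centers) is returned for pipeline tests.  An optional
#' amplitude decay emulates beads drifting out of focus during release.
#'
#' @param layout n x 2 matrix of bead centers (pixels, row/col); `NULL` for
#'   a bead-free frame
#' @param size image size in pixels (square)
#' @param amplitude peak spot amplitude (gray levels)
#' @param sigma spot Gaussian sigma (pixels)
#' @param background mean background level (gray levels)
#' @param tilt background plane tilt, gray levels edge-to-edge
#' @param bump_amp low-frequency background bump amplitude
#' @param noise_sd additive Gaussian noise sd (gray levels)
#' @param bit_depth 8 or 16
#' @param amplitude_decay multiplies `amplitude` (defocus emulation)
#' @param seed RNG seed for the noise
#' @return object of class `micrograph`: `image` matrix, `roi`,
#'   `background_mask`, and `truth` (bead mask, true mean background,
#'   covered pixel count)
#' @export
synth_micrograph <- function(layout, size = 256, amplitude = 120, sigma = 1.2,
                             background = 40, tilt = 10, bump_amp = 6,
                             noise_sd = 2, bit_depth = 8,
                             amplitude_decay = 1, seed = 1) {
  stopifnot(bit_depth %in% c(8, 16))
  gmax <- 2^bit_depth - 1
  amp <- amplitude * amplitude_decay
  if (amp > gmax - background)
    warning("spot amplitude exceeds bit depth headroom; highlights will clip")
  rc <- seq_len(size)
  bg <- background + tilt * (outer(rc, rc, function(r, c) (r + c)) /
                               (2 * size) - 0.5) +
    bump_amp * outer(sin(2 * pi * rc / size), cos(2 * pi * rc / size))
  img <- bg
  bead_mask <- matrix(FALSE, size, size)
  if (!is.null(layout) && nrow(layout) > 0) {
    ext <- ceiling(4 * sigma)
    for (b in seq_len(nrow(layout))) {
      r0 <- layout[b, 1]; c0 <- layout[b, 2]
      rr <- max(1, round(r0) - ext):min(size, round(r0) + ext)
      cc <- max(1, round(c0) - ext):min(size, round(c0) + ext)
      spot <- amp * exp(-(outer((rr - r0)^2, (cc - c0)^2, "+")) /
                          (2 * sigma^2))
      img[rr, cc] <- img[rr, cc] + spot
      ## ground-truth footprint: contributes at least half a gray level
      ## (the quantization detectability limit)
      bead_mask[rr, cc] <- bead_mask[rr, cc] | (spot >= 0.5)
    }
  }
  set.seed(seed)
  if (noise_sd > 0) img <- img + stats::rnorm(size^2, sd = noise_sd)
  img <- matrix(pmin(pmax(round(img), 0), gmax), size, size)
  roi <- circle_mask(size, size, radius = size * 0.42)
  bgm <- !circle_mask(size, size, radius = size * 0.46)
  structure(list(image = img, roi = roi, background_mask = bgm,
                 bit_depth = bit_depth,
                 truth = list(bead_mask = bead_mask,
                              covered_pixels = sum(bead_mask & roi),
                              mean_background = mean(bg[bgm]),
                              layout = layout)),
            class = "micrograph")
}

#' Map simulated capture positions to image pixels
#'
#' @param positions n x 2 (x, y) capture positions (m)
#' @param chamber_diameter chamber diameter (m)
#' @param size image size (pixels)
#' @param roi_radius chamber radius in pixels (matches [synth_micrograph()])
#' @return n x 2 matrix of (row, col) pixel centers
#' @export
layout_from_positions <- function(positions, chamber_diameter = 6e-3,
                                  size = 256, roi_radius = size * 0.42) {
  p <- as.matrix(positions)
  scale <- roi_radius / (chamber_diameter / 2)
  cbind((size + 1) / 2 + p[, 2] * scale,
        (size + 1) / 2 + p[, 1] * scale)
}

#' Read/write grayscale images
#'
#' Thin wrappers over TIFF/PNG I/O operating on integer gray matrices
#' (bit-exact round trips).
#'
#' @param image integer-valued matrix of gray levels
#' @param path file path (`.tif`/`.tiff` or `.png`)
#' @param bit_depth 8 or 16
#' @return `read_gray()` returns the gray matrix on the original level scale
#' @export
write_gray <- function(image, path, bit_depth = 8) {
  gmax <- 2^bit_depth - 1
  norm <- image / gmax
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::writeTIFF(norm, path, bits.per.sample = bit_depth)
  } else {
    png::writePNG(norm, path, dpi = NULL)
  }
  invisible(path)
}

#' @rdname write_gray
#' @export
read_gray <- function(path, bit_depth = 8) {
  gmax <- 2^bit_depth - 1
  im <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(im)) == 3) im <- im[, , 1]
  round(im * gmax)
}
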