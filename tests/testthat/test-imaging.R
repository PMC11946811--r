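test_that("background level is the masked mean", {
  img <- matrix(37, 40, 40)
  msk <- matrix(TRUE, 40, 40)
  expect_equal(background_level(img, msk), 37)
  ## checkerboard of two levels
  img2 <- matrix(c(10, 30), 40, 40)
  expect_equal(background_level(img2, msk), 20)
  expect_error(background_level(img, matrix(FALSE, 40, 40)), "empty")
})

test_that("synthetic micrograph background is recovered within one gray level", {
  m <- synth_micrograph(NULL, size = 128, noise_sd = 1.5, seed = 4)
  G <- background_level(m$image, m$background_mask)
  expect_lt(abs(G - m$truth$mean_background), 1)
  expect_equal(coverage_from_image(m$image, m$roi, max(m$image)), 0)
})

test_that("image coverage matches the rendered bead fraction", {
  set.seed(7)
  n <- 40
  ## non-overlapping bead centers on a coarse lattice inside the ROI
  gr <- expand.grid(r = seq(50, 206, by = 12), c = seq(50, 206, by = 12))
  gr <- gr[(gr$r - 128.5)^2 + (gr$c - 128.5)^2 < (0.38 * 256)^2, ]
  lay <- as.matrix(gr[sample(nrow(gr), n), ])
  ## high-contrast, flat-background regime: the mean-background threshold
  ## only recovers the bead fraction when background variation is below the
  ## quantization step
  m <- synth_micrograph(lay, size = 256, amplitude = 150, sigma = 1.1,
                        tilt = 0.2, bump_amp = 0.1, noise_sd = 0.1, seed = 8)
  G <- background_level(m$image, m$background_mask)
  cor_img <- coverage_from_image(m$image, m$roi, G)
  f_true <- 100 * m$truth$covered_pixels / sum(m$roi)
  expect_lt(abs(cor_img - f_true), 2)
  ## doubling the bead count doubles the ground-truth covered pixels
  m2 <- synth_micrograph(as.matrix(gr[sample(nrow(gr), 2 * n), ]),
                         size = 256, amplitude = 150, sigma = 1.1,
                         tilt = 0.2, bump_amp = 0.1, noise_sd = 0.1, seed = 8)
  expect_equal(m2$truth$covered_pixels / m$truth$covered_pixels, 2,
               tolerance = 0.1)
})

test_that("intensity capture rate is the intensity-index ratio", {
  gr <- expand.grid(r = seq(60, 200, by = 14), c = seq(60, 200, by = 14))
  gr <- gr[(gr$r - 128.5)^2 + (gr$c - 128.5)^2 < (0.38 * 256)^2, ]
  lay1 <- as.matrix(gr[seq_len(30), ])
  lay2 <- as.matrix(gr[seq_len(60), ])
  m1 <- synth_micrograph(lay1, tilt = 0.4, bump_amp = 0.3, noise_sd = 0,
                         seed = 1)
  m2 <- synth_micrograph(lay2, tilt = 0.4, bump_amp = 0.3, noise_sd = 0,
                         seed = 1)
  ## identical image -> 100%
  expect_equal(intensity_capture_rate(m1$image, m1$image, m1$roi,
                                      m1$background_mask), 100,
               tolerance = 1e-6)
  ## twice the beads -> ~200%
  expect_equal(intensity_capture_rate(m2$image, m1$image, m1$roi,
                                      m1$background_mask), 200,
               tolerance = 10)
  ## bead-free frame -> ~0%
  m0 <- synth_micrograph(NULL, tilt = 0.4, bump_amp = 0.3, noise_sd = 0,
                         seed = 1)
  expect_lt(intensity_capture_rate(m0$image, m1$image, m1$roi,
                                   m1$background_mask), 5)
})

test_that("release series from images tracks the removed fraction", {
  gr <- expand.grid(r = seq(60, 200, by = 12), c = seq(60, 200, by = 12))
  gr <- gr[(gr$r - 128.5)^2 + (gr$c - 128.5)^2 < (0.38 * 256)^2, ]
  lay <- as.matrix(gr[seq_len(80), ])
  keep <- list(80, 60, 40, 20, 0)    # beads remaining per frame
  frames <- lapply(keep, function(k) {
    synth_micrograph(if (k > 0) lay[seq_len(k), , drop = FALSE] else NULL,
                     tilt = 0.4, bump_amp = 0.3, noise_sd = 0.2,
                     seed = 2)$image
  })
  m0 <- synth_micrograph(lay, tilt = 0.4, bump_amp = 0.3, noise_sd = 0.2,
                         seed = 2)
  rer <- release_rate_from_images(frames, m0$image, m0$roi,
                                  m0$background_mask)
  truth <- 100 * (1 - unlist(keep) / 80)
  expect_true(all(abs(rer - truth) < 5))
  ## copies of the initial frame -> 0 throughout
  rer0 <- release_rate_from_images(list(m0$image, m0$image), m0$image,
                                   m0$roi, m0$background_mask)
  expect_equal(rer0, c(0, 0))
  ## pure background final frame -> 100
  expect_equal(rer[5], 100, tolerance = 1)
})

test_that("image IO round trips are bit-exact (pipeline idempotence)", {
  m <- synth_micrograph(cbind(c(25, 40), c(35, 28)), size = 64,
                        noise_sd = 2, seed = 3)
  for (ext in c(".tif", ".png")) {
    f <- tempfile(fileext = ext)
    write_gray(m$image, f, bit_depth = 8)
    back <- read_gray(f, bit_depth = 8)
    expect_identical(as.integer(back), as.integer(m$image))
  }
  ## quantification of a re-read image is identical
  f <- tempfile(fileext = ".png")
  write_gray(m$image, f)
  img2 <- read_gray(f)
  G <- background_level(m$image, m$background_mask)
  expect_identical(coverage_from_image(img2, m$roi, G),
                   coverage_from_image(m$image, m$roi, G))
})

test_that("amplitude decay emulates defocus and clipping warns", {
  gr <- cbind(c(110, 130, 150), c(110, 150, 120))
  bright <- synth_micrograph(gr, amplitude = 100, tilt = 0.4,
                             bump_amp = 0.3, noise_sd = 0, seed = 1)
  dim_ <- synth_micrograph(gr, amplitude = 100, amplitude_decay = 0.4,
                           tilt = 0.4, bump_amp = 0.3, noise_sd = 0,
                           seed = 1)
  Ib <- beadflow:::intensity_index(bright$image, bright$roi,
                                   background_level(bright$image,
                                                    bright$background_mask))
  Id <- beadflow:::intensity_index(dim_$image, dim_$roi,
                                   background_level(dim_$image,
                                                    dim_$background_mask))
  expect_lt(Id, 0.6 * Ib)
  expect_warning(synth_micrograph(gr, amplitude = 300, bit_depth = 8),
                 "clip")
})

test_that("simulated capture layouts map into the image frame", {
  pos <- cbind(c(-2e-3, 0, 2e-3), c(0, 1e-3, -1e-3))
  px <- layout_from_positions(pos, size = 256)
  ## center maps near the image center; all inside the ROI circle
  expect_equal(px[2, 1], (256 + 1) / 2 + 1e-3 / 3e-3 * 0.42 * 256,
               tolerance = 1e-6)
  expect_true(all((px[, 1] - 128.5)^2 + (px[, 2] - 128.5)^2 <
                    (0.42 * 256)^2))
})
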