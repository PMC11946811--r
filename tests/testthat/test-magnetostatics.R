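magnet <- magnet_spec(gap = 1.5e-3, side = "below")
particle <- particle_spec()

test_that("quadrature field matches the on-axis closed form to 1e-6", {
  z <- c(0, 0.3e-3, 1e-3, 2.9e-3)       # chamber coords above the magnet
  B <- magnet_flux_density(magnet, cbind(0, 0, z))
  expect_equal(B[, 3], magnet_axis_field(magnet, z + magnet$gap),
               tolerance = 1e-6)
  expect_true(all(abs(B[, 1:2]) < 1e-12))   # radial component vanishes on axis
})

test_that("far field approaches the point dipole within 1% at 20 diameters", {
  m_dip <- magnet$remanence / MU0 * pi * (magnet$diameter / 2)^2 *
    magnet$height
  z_c <- -magnet$gap - magnet$height / 2          # magnet center
  d <- 20 * magnet$diameter
  B <- magnet_flux_density(magnet, c(0, 0, z_c + d))
  expect_equal(B[3], MU0 * 2 * m_dip / (4 * pi * d^3), tolerance = 0.01)
})

test_that("exterior field is divergence- and curl-free", {
  set.seed(42)
  pts <- cbind(runif(8, -2e-3, 2e-3), runif(8, -2e-3, 2e-3),
               runif(8, 0.2e-3, 2.5e-3))
  h <- 1e-6
  for (k in seq_len(nrow(pts))) {
    J <- matrix(0, 3, 3)     # J[a, b] = dB_a / dx_b
    for (b in 1:3) {
      e <- c(0, 0, 0); e[b] <- h
      J[, b] <- (magnet_flux_density(magnet, pts[k, ] + e) -
                   magnet_flux_density(magnet, pts[k, ] - e)) / (2 * h)
    }
    scale <- max(abs(J))
    expect_lt(abs(J[1, 1] + J[2, 2] + J[3, 3]), 1e-4 * scale)
    expect_lt(max(abs(J - t(J))), 1e-4 * scale)
  }
})

test_that("points inside the magnet body are rejected", {
  expect_error(magnet_flux_density(magnet, c(0, 0, -2e-3)), "inside")
  expect_error(force_map(magnet, particle, z_plane = -2e-3), "intersects")
})

test_that("bead force follows the dipole-force law", {
  ## uniform synthetic field -> zero force
  F0 <- bead_force(magnet, particle, c(1e-3, 0, 1e-3),
                   field_fn = function(p) cbind(0.2, 0, 0.1)[rep(1, nrow(p)), , drop = FALSE])
  expect_equal(max(abs(F0)), 0)
  ## chi = 0 -> zero force anywhere
  p0 <- particle_spec(effective_susceptibility = 1e-12)
  expect_lt(max(abs(bead_force(magnet, p0, c(1e-3, 0.5e-3, 0.2e-3)))),
            1e-20)
  ## on-axis force equals the analytic 1-D derivative of the closed form
  z <- 0.5e-3
  h <- 1e-7
  dB2dz <- (magnet_axis_field(magnet, z + magnet$gap + h)^2 -
              magnet_axis_field(magnet, z + magnet$gap - h)^2) / (2 * h)
  F_ana <- particle$volume * particle$effective_susceptibility /
    (2 * MU0) * dB2dz
  F <- bead_force(magnet, particle, c(0, 0, z))
  expect_equal(F[3], F_ana, tolerance = 1e-4)
})

test_that("forces scale quadratically in remanence; ratios are invariant", {
  m2 <- magnet_spec(gap = 1.5e-3, side = "below",
                    remanence = 2 * magnet$remanence)
  pts <- cbind(c(0, 1e-3, 2e-3), 0.3e-3, 0.1e-3)
  expect_equal(bead_force(m2, particle, pts),
               4 * bead_force(magnet, particle, pts), tolerance = 1e-9)
  ## percentage reductions identical under doubled remanence
  st1 <- force_map_stats(
    force_map(magnet_spec(gap = 1.5e-3), particle, resolution = 41),
    force_map(magnet_spec(gap = 1.2e-3), particle, resolution = 41))
  st2 <- force_map_stats(
    force_map(magnet_spec(gap = 1.5e-3, remanence = 2.34), particle,
              resolution = 41),
    force_map(magnet_spec(gap = 1.2e-3, remanence = 2.34), particle,
              resolution = 41))
  expect_equal(st1$reduction_peak_vertical, st2$reduction_peak_vertical,
               tolerance = 1e-9)
  expect_equal(st1$reduction_peak_horizontal, st2$reduction_peak_horizontal,
               tolerance = 1e-9)
})

test_that("force maps are axisymmetric and peak off-axis at close gap", {
  map <- force_map(magnet_spec(gap = 1.2e-3), particle, resolution = 61)
  ## 90-degree rotation leaves the sampled magnitudes unchanged
  expect_equal(map$Fz, t(map$Fz)[, ], tolerance = 1e-6 * max(abs(map$Fz)))
  st <- force_map_stats(map)
  expect_gt(st$peak_vertical, st$center_vertical)
  ## peak sits above the magnet rim region, not at the center
  idx <- which(abs(map$Fz) == max(abs(map$Fz)), arr.ind = TRUE)[1, ]
  r_peak <- sqrt(map$x[idx[1]]^2 + map$y[idx[2]]^2)
  expect_gt(r_peak, 1e-3)
  expect_lt(r_peak, magnet_spec()$diameter / 2 + 0.5e-3)
})

test_that("bottom-plane force decreases monotonically with gap everywhere", {
  maps <- lapply(c(1.2e-3, 1.5e-3, 1.8e-3), function(hc)
    force_map(magnet_spec(gap = hc), particle, resolution = 31))
  expect_true(all(abs(maps[[1]]$Fz) > abs(maps[[2]]$Fz)))
  expect_true(all(abs(maps[[2]]$Fz) > abs(maps[[3]]$Fz)))
})

test_that("a map referenced to itself reports zero reductions", {
  map <- force_map(magnet, particle, resolution = 21)
  st <- force_map_stats(map, map)
  expect_equal(st$reduction_peak_vertical, 0)
  expect_equal(st$reduction_center_vertical, 0)
  expect_equal(st$reduction_peak_horizontal, 0)
  other <- force_map(magnet, particle, resolution = 31)
  expect_error(force_map_stats(map, other), "grid")
})
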