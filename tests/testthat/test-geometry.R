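test_that("constructors enforce their invariants", {
  expect_error(chamber_geometry(channel_height = 4e-3),
               "channel_height")
  expect_error(magnet_spec(remanence = -1), "positive")
  expect_error(particle_spec(diameter = 0), "diameter")
  expect_error(fluid_spec(dynamic_viscosity = 0), "positive")
  expect_error(simulation_config(inlet_velocity = -0.1), "inlet_velocity")
  ## derived bead quantities
  p <- particle_spec()
  expect_equal(p$radius, 2e-6)
  expect_equal(p$volume, 4 / 3 * pi * (2e-6)^3)
  expect_equal(p$effective_susceptibility, 0.38)
  p_cm <- particle_spec(effective_susceptibility = NULL)
  expect_equal(p_cm$effective_susceptibility, 3 * 999 / 1002,
               tolerance = 1e-12)
})

test_that("reference device configuration validates; bad configs are named", {
  prof <- device_profile(inlet_velocity = 0.02)
  expect_silent(validate_config(prof$config, prof$geometry, prof$magnet,
                                prof$fluid, prof$particle))
  prof$config$grid_spacing <- 0.1e-3
  expect_error(validate_config(prof$config, prof$geometry, prof$magnet,
                               prof$fluid, prof$particle), "channel_height")
  rel <- device_profile(mode = "release")
  expect_identical(rel$geometry$inlet_level, "upper")
  cap_cfg <- simulation_config(mode = "capture")
  expect_warning(
    expect_warning(validate_config(cap_cfg, rel$geometry, rel$magnet,
                                   fluid_spec(), particle_spec()),
                   "upper inlet"),
    "magnet below")
})

test_that("voxelized interior volume exceeds 80 uL and matches the closed form", {
  geom <- chamber_geometry()
  dom <- suppressWarnings(build_domain(geom, 50e-6))
  vol <- domain_volume(dom)
  expect_gt(vol * 1e9, 80)                      # design requirement
  expect_equal(vol, analytic_volume(geom), tolerance = 0.02)
})

test_that("voxel volume estimate improves under refinement", {
  ## cylinder-only comparison on a scaled-down chamber to keep it fast
  geom <- chamber_geometry(chamber_diameter = 2e-3, chamber_height = 1e-3,
                           channel_width = 0.4e-3, channel_height = 0.2e-3,
                           channel_length = 0.6e-3)
  v_true <- analytic_volume(geom)
  err <- vapply(c(50e-6, 25e-6), function(dx) {
    abs(domain_volume(suppressWarnings(build_domain(geom, dx))) - v_true)
  }, numeric(1))
  expect_lt(err[2], err[1])
  ## voxel count scales ~8x when dx halves
  n1 <- sum(suppressWarnings(build_domain(geom, 50e-6))$mask > 0)
  n2 <- sum(suppressWarnings(build_domain(geom, 25e-6))$mask > 0)
  expect_equal(n2 / n1, 8, tolerance = 0.15)
})

test_that("domain labels partition boundary faces", {
  dom <- suppressWarnings(build_domain(chamber_geometry(), 50e-6))
  expect_setequal(unique(as.vector(dom$mask)), c(0L, 1L, 2L, 3L))
  ## inlet and outlet faces are planar sets at the channel ends
  iin <- which(dom$mask == 2L, arr.ind = TRUE)
  iout <- which(dom$mask == 3L, arr.ind = TRUE)
  expect_length(unique(iin[, 1]), 1)
  expect_length(unique(iout[, 1]), 1)
  ## both faces have the channel cross-section cell count
  expect_equal(nrow(iin), round(1e-3 / 50e-6) * round(0.2e-3 / 50e-6))
  expect_equal(nrow(iin), nrow(iout))
  ## coarse grid is rejected
  expect_error(build_domain(chamber_geometry(), 80e-6), "too coarse")
})

test_that("upper-inlet domain places the inlet flush with the chamber top", {
  geom <- chamber_geometry(inlet_level = "upper")
  dom <- suppressWarnings(build_domain(geom, 50e-6))
  iin <- which(dom$mask == 2L, arr.ind = TRUE)
  z <- dom$origin[3] + (iin[, 3] - 1) * dom$dx
  expect_true(all(z > geom$chamber_height - geom$channel_height))
  expect_true(all(z < geom$chamber_height))
  ## outlet stays at the bottom
  iout <- which(dom$mask == 3L, arr.ind = TRUE)
  zo <- dom$origin[3] + (iout[, 3] - 1) * dom$dx
  expect_true(all(zo < geom$channel_height))
})

test_that("the bundled device profile parses to the reference values", {
  f <- system.file("extdata", "device.yaml", package = "beadflow")
  cfg <- read_run_config(f)
  expect_equal(cfg$geometry$chamber_diameter, 6e-3)
  expect_equal(cfg$magnet$diameter, 5e-3)
  expect_equal(cfg$particle$effective_susceptibility, 0.38)
  expect_equal(cfg$config$inlet_velocity, 0.02)
})

test_that("YAML round trip reproduces a configuration", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("geometry:", "  chamber_diameter: 6.0e-3",
               "  inlet_level: lower",
               "magnet:", "  gap: 1.2e-3",
               "config:", "  inlet_velocity: 0.08", "  rng_seed: 7"), f)
  cfg <- read_run_config(f)
  expect_equal(cfg$geometry$chamber_diameter, 6e-3)
  expect_equal(cfg$magnet$gap, 1.2e-3)
  expect_equal(cfg$config$inlet_velocity, 0.08)
  expect_equal(cfg$config$rng_seed, 7L)
  expect_equal(cfg$particle$density, 1.4e3)  # defaults fill missing blocks
})
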