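particle <- particle_spec()
fluid <- fluid_spec()

test_that("a bead in quiescent fluid without a magnet stays put", {
  fl <- uniform_flow(u = c(0, 0, 0))
  seeds <- cbind(5e-4, 5e-4, 5e-4)
  tr <- track_beads(fl, NULL, particle, fluid, seeds, mode = "capture",
                    max_time = 0.5)
  expect_equal(unname(c(tr$x, tr$y, tr$z)), c(5e-4, 5e-4, 5e-4))
})

test_that("drag equilibrium: bead velocity equals the fluid velocity", {
  u <- 0.012
  fl <- uniform_flow(u = c(u, 0, 0), n = c(60, 10, 10))
  seeds <- cbind(3e-4, 2.5e-4, 2.5e-4)
  tmax <- 0.05
  tr <- track_beads(fl, NULL, particle, fluid, seeds, mode = "capture",
                    max_time = tmax)
  expect_equal(tr$x[1], 3e-4 + u * tmax, tolerance = 1e-6)
  expect_equal(tr$y[1], 2.5e-4, tolerance = 1e-12)
})

test_that("magnetic settling matches an independent 1-D ODE integration", {
  magnet <- magnet_spec(gap = 1.5e-3, side = "below")
  gamma <- 6 * pi * fluid$dynamic_viscosity * particle$radius
  ## independent oracle: adaptive high-accuracy ODE in z only, using the
  ## closed-form on-axis field (no force table, no tracker)
  vz <- function(z) {
    h <- 1e-7
    b2p <- magnet_axis_field(magnet, z + magnet$gap + h)^2
    b2m <- magnet_axis_field(magnet, z + magnet$gap - h)^2
    particle$volume * particle$effective_susceptibility / (2 * MU0) *
      (b2p - b2m) / (2 * h) / gamma
  }
  z0 <- 1.5e-3; z_stop <- particle$radius
  sol <- deSolve::ode(y = c(z = z0), times = seq(0, 60, by = 1e-3),
                      func = function(t, y, p) list(vz(y)),
                      rtol = 1e-10, atol = 1e-12)
  t_arr_oracle <- unname(sol[which(sol[, "z"] <= z_stop)[1], "time"])
  ## tracker: quiescent fluid, bead on the axis
  fl <- uniform_flow(u = c(0, 0, 0), n = c(20, 20, 62), dx = 50e-6)
  fl$origin <- c(-0.5e-3, -0.5e-3, -25e-6)
  tr <- track_beads(fl, magnet, particle, fluid, cbind(1e-9, 1e-9, z0),
                    mode = "capture", max_time = 60, dt_max = 1e-3,
                    ftab = force_table(magnet, particle,
                                       dr = 10e-6, dz = 10e-6))
  expect_equal(tr$status[1], 1L)
  expect_equal(tr$t_end[1], t_arr_oracle, tolerance = 1e-3)
})

test_that("gravity-buoyancy force matches the closed form and hierarchy flag", {
  p_g <- particle_spec(include_gravity_buoyancy = TRUE)
  expect_equal(abs(beadflow:::net_body_force(p_g, fluid)),
               400 * 4 / 3 * pi * (2e-6)^3 * 9.80665, tolerance = 1e-9)
  expect_equal(abs(beadflow:::net_body_force(p_g, fluid)), 1.31e-13,
               tolerance = 0.01)
  ## neutral buoyancy: exactly zero
  p_n <- particle_spec(density = 1000, include_gravity_buoyancy = TRUE)
  expect_identical(beadflow:::net_body_force(p_n, fluid), 0)
  ## flag off: no body force enters the dynamics
  expect_identical(beadflow:::net_body_force(particle, fluid), 0)
})

test_that("capture bookkeeping: statuses partition and runs are reproducible", {
  ## synthetic uniform flow through the real device mask, magnet below
  g <- chamber_geometry(inlet_level = "lower")
  dom <- suppressWarnings(build_domain(g, 50e-6))
  dims <- dim(dom$mask)
  mk <- function(v) array(v, dims) * (dom$mask > 0)
  fl <- structure(list(ux = mk(0.03), uy = mk(0), uz = mk(0), rho = mk(1),
                       domain = dom, u0 = 0.03, dx = dom$dx,
                       origin = dom$origin,
                       ghost = list(ux = mk(0.03), uy = mk(0), uz = mk(0)),
                       meta = list(converged = TRUE, steps = 0L,
                                   residuals = numeric(0))),
                  class = "flow_field")
  magnet <- magnet_spec(gap = 1.5e-3, side = "below")
  cfg <- simulation_config(inlet_velocity = 0.03, particle_count = 120,
                           rng_seed = 5, max_sim_time = 5)
  r1 <- suppressWarnings(simulate_capture(fl, magnet, cfg))
  r2 <- suppressWarnings(simulate_capture(fl, magnet, cfg))
  expect_identical(r1$status, r2$status)          # bit-reproducible
  expect_identical(r1$positions, r2$positions)
  expect_equal(r1$N_c + r1$n_escaped + r1$n_active, r1$N)
  expect_equal(r1$cpr_pct, 100 * r1$N_c / r1$N)
  ## remanence -> 0 limit: no magnetic trapping, advection carries beads out
  m0 <- magnet_spec(gap = 1.5e-3, side = "below", remanence = 1e-6)
  r0 <- simulate_capture(fl, m0, cfg)
  expect_lt(r0$cpr_pct, 15)
  expect_gt(r0$n_escaped, 0.85 * r0$N)
})

test_that("release bookkeeping: RER series is monotone and complete", {
  g <- chamber_geometry(inlet_level = "upper")
  dom <- suppressWarnings(build_domain(g, 50e-6))
  dims <- dim(dom$mask)
  mk <- function(v) array(v, dims) * (dom$mask > 0)
  ## synthetic upward + outward flow that flushes beads to the outlet
  fl <- structure(list(ux = mk(0.02), uy = mk(0), uz = mk(0.002),
                       rho = mk(1), domain = dom, u0 = 0.02, dx = dom$dx,
                       origin = dom$origin,
                       ghost = list(ux = mk(0.02), uy = mk(0),
                                    uz = mk(0.002)),
                       meta = list(converged = TRUE, steps = 0L,
                                   residuals = numeric(0))),
                  class = "flow_field")
  set.seed(2)
  layout <- cbind(runif(60, -2e-3, 2e-3), runif(60, -1.5e-3, 1.5e-3))
  cfg <- simulation_config(inlet_velocity = 0.02, particle_count = 60,
                           rng_seed = 2, mode = "release", max_sim_time = 3)
  rel <- simulate_release(fl, NULL, layout, cfg)
  expect_true(all(diff(rel$series$rer_pct) >= 0))
  expect_equal(rel$series$rer_pct[1], 0)
  expect_equal(rel$n_released, sum(rel$status == 2L))
  expect_false(is.unsorted(rel$release_times))
  ## layout outside the disc is rejected
  expect_error(simulate_release(fl, NULL, cbind(5e-3, 0), cfg), "outside")
})

test_that("time-step refinement leaves capture counts stable", {
  g <- chamber_geometry(inlet_level = "lower")
  dom <- suppressWarnings(build_domain(g, 50e-6))
  dims <- dim(dom$mask)
  mk <- function(v) array(v, dims) * (dom$mask > 0)
  fl <- structure(list(ux = mk(0.03), uy = mk(0), uz = mk(0), rho = mk(1),
                       domain = dom, u0 = 0.03, dx = dom$dx,
                       origin = dom$origin,
                       ghost = list(ux = mk(0.03), uy = mk(0), uz = mk(0)),
                       meta = list(converged = TRUE, steps = 0L,
                                   residuals = numeric(0))),
                  class = "flow_field")
  magnet <- magnet_spec(gap = 1.5e-3, side = "below")
  cfg <- simulation_config(inlet_velocity = 0.03, particle_count = 150,
                           rng_seed = 9, max_sim_time = 5)
  c1 <- suppressWarnings(simulate_capture(fl, magnet, cfg, step_frac = 0.25))
  c2 <- suppressWarnings(simulate_capture(fl, magnet, cfg,
                                          step_frac = 0.125))
  expect_lt(abs(c1$cpr_pct - c2$cpr_pct), 2)
})
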