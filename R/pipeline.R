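## Orchestration of the three studies: capture sweeps over (u0, h_c), force
## maps and their gap/diameter statistics, and the release study (effective
## inlet length + release curves).  All runs are deterministic given seeds;
## each result row carries its full parameter provenance.

#' Device flow solve at desk scale
#'
#' Convenience wrapper: voxelizes the device and solves at the shared
#' desk-scale settings.  The lattice velocity scales as sqrt(u0) so the
#' channel pressure drop stays small in lattice units across the sweep
#' (at fixed lattice velocity the lattice density drop grows as 1/u0 and
#' the weakly compressible model breaks down at low inlet velocities).
#'
#' @param geometry [chamber_geometry()]
#' @param u0 inlet velocity (m/s)
#' @param dx grid spacing (m)
#' @param fluid [fluid_spec()]
#' @param max_steps,tol,init,... passed to [solve_steady_flow()]
#' @param recharge maximum cavity-pressure recharge iterations
#' @return a `flow_field`
#' @export
chamber_flow <- function(geometry, u0, dx = 50e-6, fluid = fluid_spec(),
                         max_steps = 30000L, tol = 2e-5, init = NULL,
                         recharge = 5L, ...) {
  dom <- suppressWarnings(build_domain(geometry, dx))
  u_lat <- min(max(0.05 * sqrt(u0 / 0.16), 0.01), 0.12)
  if (is.null(init) && u0 > 0) {
    ## prime the cavity pressure: it otherwise charges through the channel
    ## resistance on a slow RC timescale.  Linear drop along each channel
    ## (analytic rectangular-duct resistance), flat across the chamber.
    g <- geometry
    R <- g$chamber_diameter / 2; L <- g$channel_length
    h <- g$channel_height; w <- g$channel_width
    dp <- u0 * 12 * fluid$dynamic_viscosity * L /
      (h^2 * (1 - 0.63 * h / w))                      # Pa, per channel
    delta <- 3 * dp / (fluid$density * (u0 / u_lat)^2)  # lattice rho units
    dims <- dim(dom$mask)
    xs <- dom$origin[1] + (seq_len(dims[1]) - 1) * dx
    rho_x <- 1 + delta * ifelse(xs < -R, 1 + pmin((-R - xs) / L, 1),
                                ifelse(xs > R, pmax(1 - (xs - R) / L, 0), 1))
    zero <- array(0, dims)
    init <- list(ux = zero, uy = zero, uz = zero,
                 rho = array(rho_x, dims))
  }
  fl <- solve_steady_flow(dom, u0, fluid, u_lattice = u_lat, tol = tol,
                          max_steps = max_steps, check_every = 500L,
                          symmetric = TRUE, init = init, ...)
  ## cavity-pressure recharge: the chamber pressure that drives the outlet
  ## flux otherwise approaches its steady value on a slow RC (channel
  ## resistance x cavity compliance) timescale.  Rescale the density
  ## deviation by the outlet-flux deficit and re-equilibrate briefly.
  q0 <- u0 * g_area(geometry)
  if (u0 > 0) {
    for (i in seq_len(recharge)) {
      q_out <- flux_balance(fl)$flux_out
      gain <- q0 / q_out
      if (!is.finite(gain) || abs(gain - 1) < 0.01) break
      fl$rho <- 1 + (fl$rho - 1) * min(max(gain, 0.7), 1.3)
      fl <- solve_steady_flow(dom, u0, fluid, u_lattice = u_lat, tol = tol,
                              max_steps = 2500L, check_every = 500L,
                              symmetric = TRUE, init = fl, ramp_steps = 0L)
    }
  }
  fl
}

## inlet cross-section area
g_area <- function(geometry) geometry$channel_width * geometry$channel_height

#' Run the capture sweep
#'
#' One capture simulation per (u0, h_c) pair: solve the lower-inlet flow,
#' track `n_particles` beads, report CPR/COR.  Flow fields are reused across
#' h_c values at the same u0 (the magnet does not act back on the fluid) and
#' warm-started along the u0 ladder.
#'
#' @param u0 inlet velocities (m/s)
#' @param h_c capture-magnet gaps (m)
#' @param n_particles beads per run
#' @param seed RNG seed (bead seeding)
#' @param dx grid spacing (m)
#' @param max_sim_time per-bead tracking cap (s)
#' @param coverage_grid occupancy cells per side
#' @param geometry device geometry (lower inlet)
#' @param flow_max_steps lattice-step cap per flow solve
#' @param out_dir optional directory: writes `capture_sweep.csv`
#' @param verbose log progress to stderr
#' @return data.frame, one row per (u0, h_c) with CPR, COR and provenance
#' @export
run_capture_sweep <- function(u0 = seq(0.02, 0.16, by = 0.02),
                              h_c = c(1.2e-3, 1.5e-3, 1.8e-3),
                              n_particles = 1000, seed = 1, dx = 50e-6,
                              max_sim_time = 60, coverage_grid = 36,
                              geometry = chamber_geometry(inlet_level = "lower"),
                              flow_max_steps = 30000L,
                              out_dir = NULL, verbose = TRUE) {
  particle <- particle_spec(); fluid <- fluid_spec()
  rows <- list(); fl <- NULL
  for (u in sort(u0)) {
    if (verbose) message(sprintf("[capture-sweep] flow solve u0 = %.2f m/s", u))
    fl <- chamber_flow(geometry, u, dx, fluid, init = fl,
                       max_steps = flow_max_steps)
    for (hc in h_c) {
      magnet <- magnet_spec(gap = hc, side = "below")
      cfg <- simulation_config(inlet_velocity = u, grid_spacing = dx,
                               particle_count = n_particles, rng_seed = seed,
                               mode = "capture", max_sim_time = max_sim_time)
      res <- simulate_capture(fl, magnet, cfg, particle, fluid,
                              coverage_grid = coverage_grid)
      rows[[length(rows) + 1]] <- data.frame(
        u0_m_per_s = u, h_c_mm = hc * 1e3, N = res$N, N_c = res$N_c,
        CPR_pct = res$cpr_pct, COR_pct = res$cor_pct,
        grid_cells = coverage_grid, dx_um = dx * 1e6, seed = seed,
        flow_steps = fl$meta$steps)
      if (verbose)
        message(sprintf("  h_c = %.1f mm: CPR %.1f%%, COR %.1f%%",
                        hc * 1e3, res$cpr_pct, res$cor_pct))
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(out, file.path(out_dir, "capture_sweep.csv"),
                     row.names = FALSE)
  }
  out
}

#' Run the force-map analysis
#'
#' Bottom-plane force maps for the capture magnet at each gap (with
#' percentage reductions relative to the smallest gap) and, optionally, the
#' release-magnet diameter sweep with the two quantities that set the
#' optimal diameter: the bottom-edge force (release authority) and the
#' force along the chamber axis at mid-height (over-attraction risk in the
#' main flow field).
#'
#' @param h_c capture-magnet gaps (m)
#' @param diameters release-magnet diameter sweep (m); `NULL` to skip
#' @param release_gap release-magnet gap (m)
#' @param resolution force-map grid points per side
#' @param out_dir optional directory: writes CSV tables (+ map CSVs)
#' @return list with `gap_stats` (data.frame incl. reductions) and
#'   `diameter_stats`
#' @export
run_force_analysis <- function(h_c = c(1.2e-3, 1.5e-3, 1.8e-3),
                               diameters = seq(4e-3, 10e-3, by = 1e-3),
                               release_gap = 0.8e-3, resolution = 121,
                               out_dir = NULL) {
  particle <- particle_spec()
  maps <- lapply(h_c, function(hc) {
    force_map(magnet_spec(gap = hc, side = "below"), particle,
              z_plane = particle$radius, resolution = resolution)
  })
  ref <- maps[[which.min(h_c)]]
  gap_stats <- do.call(rbind, lapply(seq_along(h_c), function(i) {
    s <- force_map_stats(maps[[i]], ref)
    data.frame(h_c_mm = h_c[i] * 1e3,
               peak_vertical_N = s$peak_vertical,
               center_vertical_N = s$center_vertical,
               peak_horizontal_N = s$peak_horizontal,
               red_peak_vertical_pct = s$reduction_peak_vertical,
               red_center_vertical_pct = s$reduction_center_vertical,
               red_peak_horizontal_pct = s$reduction_peak_horizontal)
  }))
  diameter_stats <- NULL
  if (!is.null(diameters)) {
    H <- 3e-3
    diameter_stats <- do.call(rbind, lapply(diameters, function(d) {
      mag <- magnet_spec(diameter = d, gap = release_gap, side = "above")
      ## bottom center + edge (release authority on settled beads)
      Fb <- bead_force(mag, particle,
                       rbind(c(0, 0, particle$radius),
                             c(2.9e-3, 0, particle$radius)))
      ## axis force at mid-height (risk of trapping beads crossing the top)
      Fc <- bead_force(mag, particle, c(0, 0, H / 2))
      data.frame(diameter_mm = d * 1e3,
                 F_bottom_center_N = Fb[1, 3],
                 F_bottom_edge_N = Fb[2, 3],
                 F_axis_mid_N = Fc[3])
    }))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(gap_stats, file.path(out_dir, "force_gap_stats.csv"),
                     row.names = FALSE)
    if (!is.null(diameter_stats))
      utils::write.csv(diameter_stats,
                       file.path(out_dir, "force_diameter_stats.csv"),
                       row.names = FALSE)
    for (i in seq_along(h_c))
      write_force_map_csv(maps[[i]],
                          file.path(out_dir, sprintf("force_map_hc%.1fmm.csv",
                                                     h_c[i] * 1e3)))
  }
  list(gap_stats = gap_stats, diameter_stats = diameter_stats, maps = maps)
}

#' Run the release study
#'
#' Upper-inlet flow at each u0: effective inlet length, then the release
#' simulation (8 mm magnet, 0.8 mm above the chamber) from a capture layout,
#' plus a no-magnet control at `control_u0`.
#'
#' @param u0 inlet velocities for the effective-length curve (m/s)
#' @param release_u0 velocities for release simulations (subset of `u0`)
#' @param layout n x 2 bottom layout or a `capture_result`; `NULL` seeds a
#'   uniform in-disc layout of `n_particles`
#' @param n_particles layout size when `layout` is `NULL`
#' @param seed RNG seed for the fallback layout
#' @param dx grid spacing (m)
#' @param magnet_diameter release-magnet diameter (m)
#' @param magnet_gap release-magnet gap (m)
#' @param max_sim_time release window (s)
#' @param control_u0 velocity of the no-magnet control; `NULL` to skip
#' @param geometry device geometry (upper inlet)
#' @param flow_max_steps lattice-step cap per flow solve
#' @param out_dir optional directory for CSV outputs
#' @return list: `effective_length` (data.frame), `releases` (named list of
#'   `release_result`), `control` (`release_result` or `NULL`)
#' @export
run_release_study <- function(u0 = seq(0.02, 0.24, by = 0.02),
                              release_u0 = c(0.16),
                              layout = NULL, n_particles = 1000, seed = 1,
                              dx = 50e-6, magnet_diameter = 8e-3,
                              magnet_gap = 0.8e-3, max_sim_time = 40,
                              control_u0 = 0.16,
                              geometry = chamber_geometry(inlet_level = "upper"),
                              flow_max_steps = 30000L, out_dir = NULL) {
  particle <- particle_spec(); fluid <- fluid_spec()
  if (is.null(layout)) {
    set.seed(seed)
    R <- geometry$chamber_diameter / 2
    r <- R * 0.95 * sqrt(stats::runif(n_particles))
    th <- stats::runif(n_particles, 0, 2 * pi)
    layout <- cbind(r * cos(th), r * sin(th))
  }
  if (inherits(layout, "capture_result")) layout <- layout$positions
  magnet <- magnet_spec(diameter = magnet_diameter, height = 1.5e-3,
                        gap = magnet_gap, side = "above")
  eff <- list(); flows <- list(); fl <- NULL
  for (u in sort(unique(c(u0, release_u0, control_u0)))) {
    message(sprintf("[release-study] flow solve u0 = %.2f m/s (upper inlet)", u))
    fl <- chamber_flow(geometry, u, dx, fluid, init = fl,
                       max_steps = flow_max_steps)
    flows[[sprintf("%.3f", u)]] <- fl
    if (u %in% u0) {
      e <- effective_inlet_length(fl)
      eff[[length(eff) + 1]] <- data.frame(u0_m_per_s = u,
                                           effective_pct = e$effective_pct)
      message(sprintf("  effective inlet length: %.1f%%", e$effective_pct))
    }
  }
  cfg <- function(u) simulation_config(inlet_velocity = u, grid_spacing = dx,
                                       particle_count = nrow(layout),
                                       rng_seed = seed, mode = "release",
                                       max_sim_time = max_sim_time)
  releases <- lapply(release_u0, function(u) {
    message(sprintf("[release-study] release run u0 = %.2f m/s", u))
    simulate_release(flows[[sprintf("%.3f", u)]], magnet, layout, cfg(u),
                     particle, fluid)
  })
  names(releases) <- sprintf("%.2f", release_u0)
  control <- NULL
  if (!is.null(control_u0)) {
    message("[release-study] no-magnet control")
    control <- simulate_release(flows[[sprintf("%.3f", control_u0)]], NULL,
                                layout, cfg(control_u0), particle, fluid)
  }
  eff <- do.call(rbind, eff)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(eff, file.path(out_dir, "effective_inlet_length.csv"),
                     row.names = FALSE)
    for (nm in names(releases))
      utils::write.csv(releases[[nm]]$series,
                       file.path(out_dir, sprintf("release_u0_%s.csv", nm)),
                       row.names = FALSE)
  }
  list(effective_length = eff, releases = releases, control = control)
}
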