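## Lagrangian bead tracking under Stokes drag + dipole magnetic force.
##
## The beads are tracked in the overdamped (zero-inertia) limit: the
## particle response time rho_p d_p^2 / (18 eta) is ~1.2 us for a 4 um bead
## in water, orders of magnitude below any flow timescale, so the momentum
## balance m_p du_p/dt = F_d + F_m (+ F_g + F_f) collapses to the
## quasi-static drift u_p = u(x) + (F_m + F_g + F_f) / (6 pi eta R_p).
## Positions advance by 4th-order integration of that drift field.

STANDARD_GRAVITY <- 9.80665

## net gravity - buoyancy force on the bead (signed z-component, N)
net_body_force <- function(particle, fluid) {
  if (!particle$include_gravity_buoyancy) return(0)
  -(particle$density - fluid$density) * particle$volume * STANDARD_GRAVITY
}

#' Seed beads over the inlet cross-section
#'
#' Uniform grid plus in-cell jitter over the inlet face, one bead radius
#' clear of the walls.  Uses the current RNG state; call `set.seed()` (or go
#' through [simulate_capture()]) for reproducibility.
#'
#' @param geometry [chamber_geometry()]
#' @param n bead count
#' @param dx grid spacing of the flow solve (m), used to inset the seed
#'   plane from the inlet face
#' @param radius bead radius (m)
#' @return n x 3 matrix of positions
#' @export
seed_inlet <- function(geometry, n, dx, radius = 2e-6) {
  g <- geometry
  R <- g$chamber_diameter / 2
  x0 <- -(R + g$channel_length) + 2 * dx
  z_lo <- if (g$inlet_level == "upper") g$chamber_height - g$channel_height else 0
  w_eff <- g$channel_width - 2 * radius
  h_eff <- g$channel_height - 2 * radius
  ny <- max(1L, round(sqrt(n * w_eff / h_eff)))
  nz <- ceiling(n / ny)
  gy <- rep(seq_len(ny), nz)[seq_len(n)] - 1L
  gz <- rep(seq_len(nz), each = ny)[seq_len(n)] - 1L
  y <- -w_eff / 2 + (gy + stats::runif(n)) * w_eff / ny
  z <- z_lo + radius + (gz + stats::runif(n)) * h_eff / nz
  cbind(x = rep(x0, n), y = y, z = z)
}

## geometry parameters handed to the C++ tracker
tracker_geom <- function(geometry) {
  list(R = geometry$chamber_diameter / 2, H = geometry$chamber_height,
       w = geometry$channel_width, h = geometry$channel_height,
       L = geometry$channel_length,
       upper_inlet = as.integer(geometry$inlet_level == "upper"))
}

#' Track beads through a flow field
#'
#' Low-level driver: advances every seed until it is captured on the bottom
#' (capture mode), escapes into the outlet channel, stalls (drift speed
#' below `v_stop`), or `max_time` elapses.  The magnetic force is bilinearly
#' interpolated from a precomputed axisymmetric [force_table()]; pass
#' `magnet = NULL` for a field-free control.
#'
#' @param flow [solve_steady_flow()] result
#' @param magnet [magnet_spec()] or `NULL`
#' @param particle [particle_spec()]
#' @param fluid [fluid_spec()]
#' @param seeds n x 3 position matrix
#' @param mode `"capture"` or `"release"`
#' @param max_time tracking-time cap per bead (s)
#' @param dt_max time-step cap (s)
#' @param step_frac displacement per step as a fraction of dx
#' @param freeze immobilize beads on first bottom contact (the standard
#'   particle-tracing wall condition; touchdown footprints are what the
#'   coverage metric measures).  `FALSE` gives the frictionless sliding
#'   limit, where settled beads keep creeping under wall-shear drag and the
#'   horizontal magnetic force until they reach the in-plane force
#'   attractor
#' @param v_stop drift speed below which a bead is declared immobile (m/s)
#' @param n_traj number of beads whose trajectories are recorded
#' @param traj_dt trajectory sampling interval (s)
#' @param ftab optional precomputed [force_table()]
#' @return list: integer `status` (0 active, 1 captured on the bottom,
#'   2 escaped through the outlet), end times/positions, `stuck_top` flags,
#'   optional `traj` array
#' @export
track_beads <- function(flow, magnet, particle, fluid, seeds,
                        mode = c("capture", "release"),
                        max_time = 60, dt_max = 2e-3, step_frac = 0.25,
                        freeze = TRUE, v_stop = 1e-6,
                        n_traj = 0, traj_dt = 0.05, ftab = NULL) {
  mode <- match.arg(mode)
  g <- flow$domain$geometry
  if (is.null(ftab)) {
    ftab <- if (is.null(magnet)) NULL else {
      force_table(magnet, particle, chamber_height = g$chamber_height)
    }
  }
  if (is.null(ftab)) {
    Fr <- matrix(0, 2, 2); Fz <- matrix(0, 2, 2)
    ft_dims <- c(2L, 2L); ft_dr <- 1; ft_dz <- 1; ft_z0 <- 0; active <- FALSE
  } else {
    Fr <- ftab$Fr; Fz <- ftab$Fz
    ft_dims <- c(length(ftab$r), length(ftab$z))
    ft_dr <- ftab$r[2] - ftab$r[1]; ft_dz <- ftab$z[2] - ftab$z[1]
    ft_z0 <- ftab$z[1]; active <- TRUE
  }
  gamma <- 6 * pi * fluid$dynamic_viscosity * particle$radius
  res <- .track_particles_cpp(flow$ghost$ux, flow$ghost$uy, flow$ghost$uz,
                              as.integer(dim(flow$ux)), flow$origin, flow$dx,
                              Fr, Fz, as.integer(ft_dims), ft_dr, ft_dz,
                              ft_z0, active,
                              as.matrix(seeds),
                              if (mode == "capture") 0L else 1L, freeze,
                              tracker_geom(g), particle$radius, gamma,
                              net_body_force(particle, fluid),
                              max_time, dt_max, step_frac, v_stop,
                              as.integer(n_traj), traj_dt)
  if (n_traj > 0)
    res$traj_t <- seq(0, by = traj_dt, length.out = dim(res$traj)[2])
  res
}

#' Simulate bead capture
#'
#' Seeds `config$particle_count` beads over the inlet face (seeded RNG) and
#' tracks each until it is captured (touches the bottom; frozen there),
#' escapes into the outlet channel, or the window ends; see [track_beads()].
#' Capture and coverage rates are computed from the final ensemble.
#'
#' @param flow lower-inlet [solve_steady_flow()] result
#' @param magnet capture [magnet_spec()] (side `"below"`)
#' @param config [simulation_config()]
#' @param particle [particle_spec()]
#' @param fluid [fluid_spec()]
#' @param coverage_grid occupancy cells per side for the coverage rate
#' @param ... passed to [track_beads()]
#' @return object of class `capture_result`: `N`, `N_c`, `cpr_pct`,
#'   `cor_pct`, capture `positions`, `status` vector, `seed`
#' @export
simulate_capture <- function(flow, magnet, config, particle = particle_spec(),
                             fluid = fluid_spec(), coverage_grid = 36, ...) {
  if (!flow$meta$converged && flow$u0 > 0)
    warning("flow field did not meet its convergence tolerance")
  g <- flow$domain$geometry
  set.seed(config$rng_seed)
  seeds <- seed_inlet(g, config$particle_count, flow$dx, particle$radius)
  tr <- track_beads(flow, magnet, particle, fluid, seeds, mode = "capture",
                    max_time = config$max_sim_time, ...)
  cap <- tr$status == 1L
  pos <- cbind(x = tr$x[cap], y = tr$y[cap])
  N <- nrow(seeds); Nc <- sum(cap)
  structure(list(N = N, N_c = Nc, n_escaped = sum(tr$status == 2L),
                 n_active = sum(tr$status == 0L),
                 cpr_pct = capture_rate(Nc, N),
                 cor_pct = coverage_rate(pos, g$chamber_diameter,
                                         grid_n = coverage_grid),
                 coverage_grid = coverage_grid,
                 positions = pos, status = tr$status,
                 t_end = tr$t_end, seed = config$rng_seed,
                 u0 = flow$u0, h_c = magnet$gap),
            class = "capture_result")
}

#' Simulate bead release
#'
#' Beads start at rest on the chamber bottom (a prior capture layout or any
#' supplied bottom-disc layout) with the upper-inlet flow running and the
#' release magnet above the chamber; each bead is tracked until it enters
#' the outlet channel.  Beads pressed against the chamber top by a dominant
#' upward attraction are flagged (`stuck_top`), the over-attraction failure
#' mode of oversized release magnets.
#'
#' @param flow upper-inlet [solve_steady_flow()] result
#' @param magnet release [magnet_spec()] (side `"above"`) or `NULL` for the
#'   no-magnet control
#' @param layout n x 2 (x, y) bottom positions (m) or a `capture_result`
#' @param config [simulation_config()]
#' @param particle [particle_spec()]
#' @param fluid [fluid_spec()]
#' @param record_dt release-curve sampling interval (s)
#' @param ... passed to [track_beads()]
#' @return object of class `release_result`: data.frame `series` (time,
#'   `n_in_chamber`, `rer_pct`), `release_times`, `t_complete` (first time
#'   the chamber count reaches zero, NA if it never does), `n_stuck_top`
#' @export
simulate_release <- function(flow, magnet, layout, config,
                             particle = particle_spec(), fluid = fluid_spec(),
                             record_dt = 0.1, ...) {
  g <- flow$domain$geometry
  if (inherits(layout, "capture_result")) {
    ## only beads settled on the chamber bottom take part in the release
    pos <- layout$positions
    keep <- sqrt(pos[, 1]^2 + pos[, 2]^2) <= g$chamber_diameter / 2
    layout <- pos[keep, , drop = FALSE]
  }
  layout <- as.matrix(layout)
  r <- sqrt(layout[, 1]^2 + layout[, 2]^2)
  if (any(r > g$chamber_diameter / 2))
    stop("release layout contains points outside the bottom disc")
  seeds <- cbind(layout[, 1], layout[, 2], particle$radius)
  tr <- track_beads(flow, magnet, particle, fluid, seeds, mode = "release",
                    max_time = config$max_sim_time, ...)
  N <- nrow(seeds)
  rel_t <- tr$t_end[tr$status == 2L]
  tgrid <- seq(0, config$max_sim_time, by = record_dt)
  n_in <- N - vapply(tgrid, function(t) sum(rel_t <= t), integer(1))
  series <- release_rate_series(tgrid, n_in, N)
  structure(list(series = series, release_times = sort(rel_t),
                 t_complete = if (length(rel_t) == N) max(rel_t) else NA_real_,
                 N = N, n_released = length(rel_t),
                 n_stuck_top = sum(tr$stuck_top),
                 status = tr$status, u0 = flow$u0,
                 traj = tr$traj, traj_t = tr$traj_t),
            class = "release_result")
}

#' Gravity/buoyancy force-hierarchy check
#'
#' Compares the net body force |F_g + F_f| = V_p |rho_p - rho_f| g against
#' the forces that transport beads, at sampled transport points (local
#' speed >= 0.1 u0).  The reported ratio uses the locally dominant
#' transport force max(|F_d|, |F_m|): gravity is negligible wherever it is
#' small against whichever force actually moves the bead there (a point
#' with weak magnetic force but strong drag is still gravity-dominated by
#' drag, not by gravity).
#'
#' @param particle [particle_spec()]
#' @param fluid [fluid_spec()]
#' @param magnet [magnet_spec()]
#' @param flow [solve_steady_flow()] result
#' @param n_sample sample size
#' @param rng_seed seed for point sampling
#' @return list: `body_force` (N), `max_ratio` =
#'   max |F_g+F_f| / max(|F_d|, |F_m|) over samples, and the sample table
#' @export
check_force_hierarchy <- function(particle, fluid, magnet, flow,
                                  n_sample = 200, rng_seed = 1) {
  fg <- (particle$density - fluid$density) * particle$volume * STANDARD_GRAVITY
  m <- flow$domain$mask
  speed <- sqrt(flow$ux^2 + flow$uy^2 + flow$uz^2)
  idx <- which(m > 0L & speed >= 0.1 * flow$u0)
  set.seed(rng_seed)
  idx <- sample(idx, min(n_sample, length(idx)))
  ij <- arrayInd(idx, dim(m))
  pts <- sweep((ij - 1) * flow$dx, 2, flow$origin, "+")
  Fm <- bead_force(magnet, particle, pts,
                   chamber_height = flow$domain$geometry$chamber_height)
  fmag <- sqrt(rowSums(Fm^2))
  fdrag <- 6 * pi * fluid$dynamic_viscosity * particle$radius * speed[idx]
  ratio <- abs(fg) / pmax(fdrag, fmag)
  list(body_force = abs(fg), max_ratio = max(ratio),
       samples = data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3],
                            F_drag = fdrag, F_mag = fmag, ratio = ratio))
}
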