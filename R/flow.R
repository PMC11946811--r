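## Steady incompressible flow in the voxelized device, streamline tracing,
## and the effective-inlet-length diagnostic.
##
## The solver is a D3Q19 lattice-Boltzmann scheme with two relaxation times
## (magic parameter 3/16, which places the bounce-back wall halfway along
## links), an equilibrium plug-velocity inlet, and a fixed-density outlet
## realizing the zero-static-pressure outflow condition.  Lattice viscosity
## is matched to the physical Reynolds number at a capped lattice velocity.

#' Solve steady flow in a voxelized domain
#'
#' @param domain [build_domain()] result
#' @param u0 mean inlet velocity (m/s)
#' @param fluid [fluid_spec()]
#' @param u_lattice inlet velocity in lattice units (Mach control; <= 0.15)
#' @param tol steady-state tolerance: relative L2 velocity change over one
#'   `check_every`-step window
#' @param max_steps lattice-step cap
#' @param check_every steps between convergence checks
#' @param ramp_steps inlet ramp-up (lattice steps), for an impulsive start
#' @param init optional initial condition: a prior `flow_field` (velocity
#'   and density carried over, with the density deviation rescaled to the
#'   new operating point) or a list `(ux, uy, uz, rho)` in lattice units
#' @param magic_lambda TRT magic parameter; 3/16 places bounce-back walls
#'   halfway along links, 1/4 maximizes stability
#' @param collision `"regularized"` (non-equilibrium projected onto its
#'   second-moment part before relaxation; stable at the low lattice
#'   viscosities the chamber Reynolds numbers require) or `"trt"`
#' @param symmetric exploit the device mirror symmetry about y = 0 (solves
#'   the half domain, reflects the result); only valid for y-symmetric masks
#' @param verbose print the residual at every convergence check
#' @param on_nonconvergence `"error"` or `"warn"` when the cap is hit
#' @return object of class `flow_field`: physical velocity arrays `ux`,
#'   `uy`, `uz` (m/s, zero in solids), ghost-filled copies for wall-aware
#'   interpolation, and solver metadata
#' @export
solve_steady_flow <- function(domain, u0, fluid = fluid_spec(),
                              u_lattice = 0.1, tol = 1e-6,
                              max_steps = 60000L, check_every = 1000L,
                              ramp_steps = 1000L, init = NULL,
                              magic_lambda = 3 / 16,
                              collision = c("regularized", "trt"),
                              symmetric = FALSE, verbose = FALSE,
                              on_nonconvergence = c("warn", "error")) {
  on_nonconvergence <- match.arg(on_nonconvergence)
  collision <- match.arg(collision)
  stopifnot(inherits(domain, "domain_mask"), u0 >= 0)
  dims <- dim(domain$mask)
  if (u0 == 0) {
    zero <- array(0, dims)
    return(structure(list(ux = zero, uy = zero, uz = zero, rho = array(1, dims),
                          domain = domain, u0 = 0, dx = domain$dx,
                          origin = domain$origin,
                          ghost = list(ux = zero, uy = zero, uz = zero),
                          meta = list(steps = 0L, residuals = numeric(0),
                                      converged = TRUE, tau = NA, u_lattice = 0,
                                      dt = NA)),
                     class = "flow_field"))
  }
  if (u_lattice > 0.15)
    stop("u_lattice > 0.15: compressibility error would be excessive")
  nu <- fluid$dynamic_viscosity / fluid$density
  dx <- domain$dx
  nu_lat <- nu * u_lattice / (u0 * dx)
  tau <- 3 * nu_lat + 0.5
  if (tau < 0.505)
    stop(sprintf(paste0("relaxation time tau = %.4f too close to 0.5 ",
                        "(under-resolved Reynolds number); refine dx or ",
                        "raise u_lattice"), tau))
  Cu <- u0 / u_lattice  # lattice -> physical velocity
  init_u <- list(NULL, NULL, NULL, NULL)
  if (!is.null(init)) {
    if (inherits(init, "flow_field")) {
      ## rescale the carried density deviation: lattice pressure scales as
      ## u0 / Cu^2 for a viscous (laminar) pressure drop
      s_rho <- if (is.null(init$meta$u_lattice) || init$u0 == 0) 0 else {
        (u0 / init$u0) * (init$u0 / init$meta$u_lattice)^2 / Cu^2
      }
      init_u <- list(init$ux / Cu, init$uy / Cu, init$uz / Cu,
                     1 + (init$rho - 1) * s_rho)
    } else {
      ## list(ux, uy, uz, rho) already in lattice units (priming profile)
      init_u <- list(init$ux, init$uy, init$uz, init$rho)
    }
  }
  ## developed duct profile over the inlet face, mean u_lattice: imposing the
  ## no-slip-compatible profile delivers the nominal flux (a plug loses a
  ## resolution-dependent fraction at the face perimeter)
  prof <- array(0, dims)
  iin <- which(domain$mask == 2L, arr.ind = TRUE)
  iy <- sort(unique(iin[, 2])); iz <- sort(unique(iin[, 3]))
  wf <- length(iy) * dx; hf <- length(iz) * dx
  pf <- duct_profile(((seq_along(iy)) - 0.5) * dx - wf / 2,
                     ((seq_along(iz)) - 0.5) * dx, wf, hf)
  prof[iin] <- u_lattice *
    pf[cbind(match(iin[, 2], iy), match(iin[, 3], iz))] / mean(pf)
  if (symmetric) {
    ## device is mirror-symmetric about y = 0: solve the y >= 0 half with a
    ## specular symmetry plane, then reflect
    nyp <- dims[2]
    if (nyp %% 2 != 0) stop("symmetric solve needs an even y cell count")
    jh <- (nyp / 2 + 1):nyp
    sl <- function(a) a[, jh, , drop = FALSE]
    hdims <- c(dims[1], length(jh), dims[3])
    res <- .lbm_solve_cpp(domain$mask[, jh, ], as.integer(hdims), u_lattice,
                          tau, as.integer(max_steps), tol,
                          as.integer(check_every), as.integer(ramp_steps),
                          magic_lambda, collision == "regularized", TRUE,
                          verbose, sl(prof),
                          if (is.null(init_u[[1]])) NULL else sl(init_u[[1]]),
                          if (is.null(init_u[[2]])) NULL else sl(init_u[[2]]),
                          if (is.null(init_u[[3]])) NULL else sl(init_u[[3]]),
                          if (is.null(init_u[[4]])) NULL else sl(init_u[[4]]))
    unfold <- function(h, flip = FALSE) {
      a <- array(0, dims)
      a[, jh, ] <- h
      a[, rev(seq_len(nyp / 2)), ] <- if (flip) -h else h
      a
    }
    res$ux <- unfold(res$ux); res$uy <- unfold(res$uy, flip = TRUE)
    res$uz <- unfold(res$uz); res$rho <- unfold(res$rho)
  } else {
    res <- .lbm_solve_cpp(domain$mask, as.integer(dims), u_lattice, tau,
                          as.integer(max_steps), tol, as.integer(check_every),
                          as.integer(ramp_steps), magic_lambda,
                          collision == "regularized", FALSE, verbose, prof,
                          init_u[[1]], init_u[[2]], init_u[[3]], init_u[[4]])
  }
  if (!res$converged) {
    msg <- sprintf(paste0("flow solve did not reach tol %.1e within %d steps ",
                          "(last residual %.2e)"), tol, max_steps,
                   utils::tail(res$residuals, 1))
    if (on_nonconvergence == "error") stop(msg) else warning(msg)
  }
  ux <- res$ux * Cu; uy <- res$uy * Cu; uz <- res$uz * Cu
  gh <- .fill_wall_ghosts_cpp(ux, uy, uz, domain$mask, as.integer(dims))
  structure(list(ux = ux, uy = uy, uz = uz, rho = res$rho,
                 domain = domain, u0 = u0, dx = dx, origin = domain$origin,
                 ghost = gh,
                 meta = list(steps = res$steps, residuals = res$residuals,
                             converged = res$converged, tau = tau,
                             u_lattice = u_lattice, dt = u_lattice * dx / u0)),
            class = "flow_field")
}

#' Inlet/outlet volumetric flux balance
#'
#' Fluxes are measured on the interior cross-sections adjacent to the inlet
#' and outlet faces (the delivered fluxes, free of the imposed-boundary
#' layers themselves).
#'
#' @param flow [solve_steady_flow()] result
#' @return list with `flux_in`, `flux_out` (m^3/s) and `imbalance` (relative)
#' @export
flux_balance <- function(flow) {
  m <- flow$domain$mask
  a <- flow$dx^2
  i_in <- unique(which(m == 2L, arr.ind = TRUE)[, 1]) + 1L
  i_out <- unique(which(m == 3L, arr.ind = TRUE)[, 1]) - 1L
  ch <- apply(m == 2L, c(2, 3), any)   # channel cross-section (y, z) extent
  qin <- sum(flow$ux[i_in, , ][ch]) * a
  ch_o <- apply(m == 3L, c(2, 3), any)
  qout <- sum(flow$ux[i_out, , ][ch_o]) * a
  list(flux_in = qin, flux_out = qout,
       imbalance = abs(qout - qin) / max(abs(qin), 1e-300))
}

#' Trace a streamline
#'
#' 4th-order integration of the interpolated velocity with a fixed spatial
#' step.  Terminates on reaching the outlet plane, exceeding `max_arc`
#' (classified recirculating), or when the local speed falls below
#' `1e-6 * u0` (stagnated).
#'
#' @param flow [solve_steady_flow()] result
#' @param seed 3-vector start position (m); must lie in fluid
#' @param step spatial step (m); default `0.25 * dx`
#' @param max_arc arc-length cap (m); default 20 chamber diameters
#' @return object of class `stream_path`: `points` (n x 3), `speed`,
#'   `arc_length`, `status` in `reached_outlet`/`recirculating`/`stagnated`
#' @export
trace_streamline <- function(flow, seed, step = NULL, max_arc = NULL) {
  g <- flow$domain$geometry
  if (is.null(step)) step <- 0.25 * flow$dx
  if (is.null(max_arc)) max_arc <- 20 * g$chamber_diameter
  m <- flow$domain$mask
  gi <- pmin(pmax(round((seed - flow$origin) / flow$dx) + 1, 1), dim(m))
  if (m[gi[1], gi[2], gi[3]] == 0L)
    stop("streamline seed lies in a wall voxel")
  outlet_x <- g$chamber_diameter / 2 + g$channel_length - 1.5 * flow$dx
  res <- .trace_path_cpp(flow$ghost$ux, flow$ghost$uy, flow$ghost$uz,
                         as.integer(dim(m)), flow$origin, flow$dx,
                         as.numeric(seed), step, max_arc, outlet_x,
                         1e-6 * max(flow$u0, 1e-12),
                         as.integer(ceiling(max_arc / step) + 10))
  status <- c("reached_outlet", "recirculating", "stagnated")[res$status + 1]
  structure(list(points = res$points, speed = res$speed,
                 arc_length = res$arc_length, status = status),
            class = "stream_path")
}

#' Magnetic force profile along a streamline
#'
#' Projects the bead force off the local path tangent; the perpendicular
#' component is the one that pulls beads across streamlines toward capture.
#'
#' @param path [trace_streamline()] result (>= 2 points)
#' @param magnet [magnet_spec()]
#' @param particle [particle_spec()]
#' @param chamber_height chamber height (m)
#' @return data.frame with arc length `s`, `F_perp` (magnitude of the
#'   off-tangent component), `F_z`, and `F_mag`
#' @export
streamline_force_profile <- function(path, magnet, particle,
                                     chamber_height = 3e-3) {
  p <- path$points
  if (nrow(p) < 2) stop("path must have at least 2 points")
  F <- bead_force(magnet, particle, p, chamber_height)
  n <- nrow(p)
  tang <- rbind(p[2, ] - p[1, ],
                (p[pmin(3:(n + 1), n), , drop = FALSE] -
                   p[1:(n - 1), , drop = FALSE]))[1:n, , drop = FALSE]
  len <- sqrt(rowSums(tang^2))
  ok <- len > 1e-15
  if (any(!ok)) warning("degenerate zero-length tangent segments skipped")
  tang[ok, ] <- tang[ok, ] / len[ok]
  ftan <- rowSums(F * tang)
  fperp2 <- pmax(rowSums(F^2) - ftan^2, 0)
  seglen <- c(0, sqrt(rowSums((p[-1, , drop = FALSE] -
                                 p[-n, , drop = FALSE])^2)))
  data.frame(s = cumsum(seglen),
             F_perp = ifelse(ok, sqrt(fperp2), NA_real_),
             F_z = F[, 3], F_mag = sqrt(rowSums(F^2)))[ok, ]
}

## classify one inlet-bottom-edge seed: TRUE if it reaches the outlet
classify_seed <- function(flow, y, x0, z0, step, max_arc) {
  trace_streamline(flow, c(x0, y, z0), step = step,
                   max_arc = max_arc)$status == "reached_outlet"
}

#' Effective inlet length
#'
#' Fraction of the inlet width whose bottom-edge streamlines reach the
#' outlet rather than recirculating: the separation of the left/right
#' boundary streamlines (refined by bisection) over the inlet width, in
#' percent.  Streamlines starting outside this band feed the vortex field.
#'
#' @param flow upper-inlet (release-configuration) [solve_steady_flow()]
#' @param geometry [chamber_geometry()]; defaults to the flow's own
#' @param n_scan initial seeds across the inlet width
#' @param y_tol bisection tolerance on the boundary-seed position (m)
#' @param max_arc streamline arc cap (m)
#' @return list with `effective_pct`, boundary positions `y_left`,
#'   `y_right` (m), and the scan classification
#' @export
effective_inlet_length <- function(flow, geometry = NULL, n_scan = 21,
                                   y_tol = 1e-6, max_arc = NULL) {
  g <- if (is.null(geometry)) flow$domain$geometry else geometry
  R <- g$chamber_diameter / 2
  x0 <- -(R + g$channel_length) + 2 * flow$dx
  z0 <- if (g$inlet_level == "upper") {
    g$chamber_height - g$channel_height + 0.5 * flow$dx
  } else {
    0.5 * flow$dx
  }
  step <- 0.25 * flow$dx
  if (is.null(max_arc)) max_arc <- 20 * g$chamber_diameter
  half <- g$channel_width / 2
  edge <- half - max(0.5 * flow$dx, y_tol)
  ys <- seq(-edge, edge, length.out = n_scan)
  exits <- vapply(ys, classify_seed, logical(1),
                  flow = flow, x0 = x0, z0 = z0, step = step,
                  max_arc = max_arc)
  if (!any(exits)) {
    warning("all inlet bottom-edge streamlines recirculate")
    return(list(effective_pct = 0, y_left = NA, y_right = NA,
                scan = data.frame(y = ys, exits = exits)))
  }
  bisect <- function(y_bad, y_good) {
    while (abs(y_good - y_bad) > y_tol) {
      mid <- (y_bad + y_good) / 2
      if (classify_seed(flow, mid, x0, z0, step, max_arc)) y_good <- mid
      else y_bad <- mid
    }
    (y_bad + y_good) / 2
  }
  i_exit <- which(exits)
  il <- min(i_exit); ir <- max(i_exit)
  y_left <- if (il == 1) -half else bisect(ys[il - 1], ys[il])
  y_right <- if (ir == n_scan) half else bisect(ys[ir + 1], ys[ir])
  list(effective_pct = 100 * (y_right - y_left) / g$channel_width,
       y_left = y_left, y_right = y_right,
       scan = data.frame(y = ys, exits = exits))
}

#' Analytic velocity profile of pressure-driven rectangular duct flow
#'
#' Fourier-series solution for fully developed laminar flow in a w x h duct,
#' normalized to unit mean velocity.  Used as the independent oracle for the
#' flow solver.
#'
#' @param y,z coordinates across the section, y in (-w/2, w/2), z in (0, h)
#' @param w,h duct width and height (m)
#' @param n_terms number of (odd) series terms
#' @return matrix of normalized velocities, `length(y)` x `length(z)`
#' @export
duct_profile <- function(y, z, w, h, n_terms = 101) {
  b <- w / 2; c <- h / 2
  zz <- z - c  # center the short dimension
  u <- matrix(0, length(y), length(zz))
  for (n in seq(1, 2 * n_terms - 1, by = 2)) {
    beta <- n * pi / (2 * c)
    ## cosh(beta y)/cosh(beta b) in overflow-safe exponential form
    ratio <- exp(beta * (abs(y) - b)) *
      (1 + exp(-2 * beta * abs(y))) / (1 + exp(-2 * beta * b))
    term <- outer(1 - ratio, cos(beta * zz)) * (-1)^((n - 1) / 2) / n^3
    u <- u + term
  }
  u / mean(u)
}

#' Export a flow field as legacy ASCII VTK (structured points)
#'
#' @param flow [solve_steady_flow()] result
#' @param path output `.vtk` path
#' @export
write_flow_vtk <- function(flow, path) {
  d <- dim(flow$ux)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "beadflow velocity field",
               "ASCII", "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", d[1], d[2], d[3]),
               sprintf("ORIGIN %g %g %g", flow$origin[1], flow$origin[2],
                       flow$origin[3]),
               sprintf("SPACING %g %g %g", flow$dx, flow$dx, flow$dx),
               sprintf("POINT_DATA %d", prod(d)),
               "VECTORS velocity double"), con)
  writeLines(paste(as.vector(flow$ux), as.vector(flow$uy),
                   as.vector(flow$uz)), con)
  invisible(path)
}
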