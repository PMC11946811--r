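## Field and force of an axially magnetized cylindrical magnet.
##
## The magnet is modelled as its equivalent solenoid: a uniform axial
## magnetization M = B_r / mu0 is a surface current sheet K = B_r / mu0 on
## the cylinder barrel.  The field is the integral over the magnet height of
## circular current-loop fields, each loop's radial/axial components given in
## closed form by complete elliptic integrals; the height integral uses
## fixed-order Gauss-Legendre quadrature (64 nodes by default, analytic-grade
## for these smooth integrands).

## Radial/axial flux density of a circular loop of radius a carrying current
## per unit length scaled out; inputs vectorized over (r, z) relative to the
## loop plane.  Returns list(Br, Bz) per unit (mu0 I / 2pi).
loop_field <- function(r, z, a) {
  rr <- pmax(r, 0)
  Q <- (a + rr)^2 + z^2
  m <- 4 * a * rr / Q                      # elliptic parameter m = k^2
  ke <- pracma::ellipke(pmin(m, 1 - 1e-15))
  K <- ke$k; E <- ke$e
  den <- (a - rr)^2 + z^2
  sq <- sqrt(Q)
  Bz <- (1 / sq) * (K + (a^2 - rr^2 - z^2) / den * E)
  Br <- ifelse(rr > 1e-12 * a,
               (z / (rr * sq)) * (-K + (a^2 + rr^2 + z^2) / den * E),
               0)
  list(Br = Br, Bz = Bz)
}

## z-interval occupied by a magnet, in chamber coordinates.
magnet_z_range <- function(magnet, chamber_height = 3e-3) {
  if (magnet$side == "below") {
    c(-magnet$gap - magnet$height, -magnet$gap)
  } else {
    c(chamber_height + magnet$gap, chamber_height + magnet$gap + magnet$height)
  }
}

#' Flux density of a cylindrical magnet
#'
#' Evaluates B at arbitrary points outside the magnet body.  The magnet axis
#' coincides with the chamber (z) axis; its z-extent follows from `side` and
#' `gap` (see [magnet_spec()]).
#'
#' @param magnet [magnet_spec()]
#' @param points numeric 3-vector or n x 3 matrix of positions (m), chamber
#'   coordinates
#' @param chamber_height chamber height used to place an `"above"` magnet (m)
#' @param n_quad Gauss-Legendre nodes over the magnet height
#' @return n x 3 matrix of B (T)
#' @export
magnet_flux_density <- function(magnet, points, chamber_height = 3e-3,
                                n_quad = 64) {
  p <- if (is.null(dim(points))) matrix(points, ncol = 3) else as.matrix(points)
  a <- magnet$diameter / 2
  zr <- magnet_z_range(magnet, chamber_height)
  r <- sqrt(p[, 1]^2 + p[, 2]^2)
  inside <- p[, 3] > zr[1] & p[, 3] < zr[2] & r < a
  if (any(inside))
    stop("field evaluation point inside the magnet body")
  gl <- pracma::gaussLegendre(n_quad, zr[1], zr[2])
  K_sheet <- magnet$remanence / MU0              # surface current density A/m
  pref <- MU0 * K_sheet / (2 * pi)               # per-loop prefactor
  Br <- numeric(nrow(p)); Bz <- numeric(nrow(p))
  for (q in seq_len(n_quad)) {
    lf <- loop_field(r, p[, 3] - gl$x[q], a)
    Br <- Br + gl$w[q] * lf$Br
    Bz <- Bz + gl$w[q] * lf$Bz
  }
  Br <- pref * Br; Bz <- pref * Bz
  ct <- ifelse(r > 0, p[, 1] / pmax(r, 1e-300), 0)
  st <- ifelse(r > 0, p[, 2] / pmax(r, 1e-300), 0)
  cbind(Bx = Br * ct, By = Br * st, Bz = Bz)
}

#' On-axis flux density, closed form
#'
#' Axial field of an axially magnetized cylinder on its axis:
#' `B_z = (B_r/2) [ (z + h_m)/sqrt((z + h_m)^2 + R^2) - z/sqrt(z^2 + R^2) ]`
#' with z measured from the top face and R the magnet radius.  Used as the
#' independent oracle for the quadrature model.
#'
#' @param magnet [magnet_spec()]
#' @param z_above distance above the magnet top face (m), vectorized
#' @return B_z (T)
#' @export
magnet_axis_field <- function(magnet, z_above) {
  R <- magnet$diameter / 2
  hm <- magnet$height
  z <- z_above
  magnet$remanence / 2 *
    ((z + hm) / sqrt((z + hm)^2 + R^2) - z / sqrt(z^2 + R^2))
}

#' Magnetic force on a linearly magnetizable bead
#'
#' Point-dipole force F = grad(m . B) with induced moment m = V_p chi_b H.
#' In the current-free region outside the magnet this reduces to
#' `F = V_p chi_b / (2 mu0) * grad|B|^2`, evaluated here by central finite
#' differences of |B|^2 (step 1 um by default, far below the mm field scale
#' and far above the floating-point noise floor).
#'
#' @param magnet [magnet_spec()]
#' @param particle [particle_spec()]
#' @param points 3-vector or n x 3 matrix (m)
#' @param chamber_height chamber height (m), placement of an above magnet
#' @param step finite-difference step (m)
#' @param field_fn optional override `function(points) -> n x 3 B matrix`
#'   (used for synthetic test fields)
#' @return n x 3 matrix of force (N)
#' @export
bead_force <- function(magnet, particle, points, chamber_height = 3e-3,
                       step = 1e-6, field_fn = NULL) {
  p <- if (is.null(dim(points))) matrix(points, ncol = 3) else as.matrix(points)
  fb <- if (is.null(field_fn)) {
    function(pts) magnet_flux_density(magnet, pts, chamber_height)
  } else {
    field_fn
  }
  n <- nrow(p)
  pref <- particle$volume * particle$effective_susceptibility / (2 * MU0)
  F <- matrix(0, n, 3)
  for (d in 1:3) {
    hp <- p; hp[, d] <- hp[, d] + step
    hm <- p; hm[, d] <- hm[, d] - step
    b2p <- rowSums(fb(hp)^2)
    b2m <- rowSums(fb(hm)^2)
    F[, d] <- pref * (b2p - b2m) / (2 * step)
  }
  if (any(!is.finite(F)))
    stop("non-finite magnetic force (field evaluation failed)")
  colnames(F) <- c("Fx", "Fy", "Fz")
  F
}

#' Magnetic force map on a horizontal plane
#'
#' Samples the bead force on an (x, y) grid at height `z_plane`, typically
#' the chamber bottom.  Reports the vertical component F_z, the signed
#' radial component F_r (negative toward the axis) and its magnitude.
#' Summary statistics are taken over the chamber disc (`in_disc`), the
#' physical bottom surface.
#'
#' @param magnet [magnet_spec()]
#' @param particle [particle_spec()]
#' @param z_plane plane height (m)
#' @param extent half-width of the square grid (m); default the chamber
#'   radius 3 mm
#' @param resolution points per side
#' @param chamber_height chamber height (m)
#' @return object of class `force_map`: `x`, `y` (axes), matrices `Fz`,
#'   `Fr`, `Fh` (horizontal magnitude), plus the specs used
#' @export
force_map <- function(magnet, particle, z_plane = 0, extent = 3e-3,
                      resolution = 121, chamber_height = 3e-3) {
  zr <- magnet_z_range(magnet, chamber_height)
  if (z_plane > zr[1] && z_plane < zr[2])
    stop("sampling plane intersects the magnet body")
  x <- seq(-extent, extent, length.out = resolution)
  y <- seq(-extent, extent, length.out = resolution)
  g <- expand.grid(x = x, y = y)
  pts <- cbind(g$x, g$y, z_plane)
  F <- bead_force(magnet, particle, pts, chamber_height)
  r <- sqrt(g$x^2 + g$y^2)
  Fr <- ifelse(r > 0, (F[, 1] * g$x + F[, 2] * g$y) / pmax(r, 1e-300), 0)
  Fh <- sqrt(F[, 1]^2 + F[, 2]^2)
  shape <- c(resolution, resolution)
  structure(list(x = x, y = y, z_plane = z_plane,
                 Fz = array(F[, 3], shape),
                 Fr = array(Fr, shape),
                 Fh = array(Fh, shape),
                 in_disc = array(r <= extent, shape),
                 magnet = magnet, particle = particle),
            class = "force_map")
}

#' Peak/center statistics of force maps
#'
#' Summarizes a force map and, when a reference map is given, the percentage
#' reductions `100 (1 - value / value_ref)` of the vertical peak, the
#' bottom-center vertical value, and the horizontal peak.  These ratios are
#' independent of the magnet remanence (forces scale with B_r^2).
#'
#' @param map [force_map()]
#' @param reference optional [force_map()] on the identical grid
#' @return list with `peak_vertical`, `center_vertical`,
#'   `peak_horizontal` (N) and, with a reference, `reduction_peak_vertical`,
#'   `reduction_center_vertical`, `reduction_peak_horizontal` (%)
#' @export
force_map_stats <- function(map, reference = NULL) {
  ctr <- ceiling(length(map$x) / 2)
  out <- list(peak_vertical = max(abs(map$Fz[map$in_disc])),
              center_vertical = abs(map$Fz[ctr, ctr]),
              peak_horizontal = max(map$Fh[map$in_disc]))
  if (!is.null(reference)) {
    if (!identical(length(map$x), length(reference$x)) ||
        max(abs(map$x - reference$x)) > 1e-12 ||
        abs(map$z_plane - reference$z_plane) > 1e-12)
      stop("force maps do not share a grid definition")
    ref <- force_map_stats(reference)
    out$reduction_peak_vertical <-
      100 * (1 - out$peak_vertical / ref$peak_vertical)
    out$reduction_center_vertical <-
      100 * (1 - out$center_vertical / ref$center_vertical)
    out$reduction_peak_horizontal <-
      100 * (1 - out$peak_horizontal / ref$peak_horizontal)
  }
  out
}

#' Axisymmetric force table for particle tracking
#'
#' Precomputes (F_r, F_z) on an (r, z) grid so the tracking kernel can
#' interpolate the dipole force instead of re-evaluating elliptic integrals
#' per step.
#'
#' @param magnet [magnet_spec()]
#' @param particle [particle_spec()]
#' @param r_max,z_min,z_max table extents (m)
#' @param dr,dz table spacings (m)
#' @param chamber_height chamber height (m)
#' @return list with axes and `Fr`, `Fz` matrices (nr x nz)
#' @export
force_table <- function(magnet, particle, r_max = 6.2e-3,
                        z_min = 0, z_max = 3.1e-3,
                        dr = 25e-6, dz = 25e-6, chamber_height = 3e-3) {
  r <- seq(0, r_max, by = dr)
  z <- seq(z_min, z_max, by = dz)
  g <- expand.grid(r = r, z = z)
  pts <- cbind(g$r, 0, g$z)
  F <- bead_force(magnet, particle, pts, chamber_height)
  list(r = r, z = z,
       Fr = matrix(F[, 1], nrow = length(r)),
       Fz = matrix(F[, 3], nrow = length(r)))
}

#' Export a force map as CSV
#'
#' @param map [force_map()]
#' @param path output CSV path (columns x, y, Fz, Fr, Fh)
#' @export
write_force_map_csv <- function(map, path) {
  g <- expand.grid(x = map$x, y = map$y)
  utils::write.csv(data.frame(x = g$x, y = g$y,
                              Fz = as.vector(map$Fz),
                              Fr = as.vector(map$Fr),
                              Fh = as.vector(map$Fh)),
                   path, row.names = FALSE)
  invisible(path)
}
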