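## Shared fixtures.  Flow solves are expensive, so tiny domains are built
## here and full-device fields are solved once per session and memoized.

fixture_env <- new.env(parent = emptyenv())

MU0 <- 4e-7 * pi

## the acceptance blocks compare against every published endpoint; do not
## stop the run early when several comparisons miss
options(testthat.progress.max_fails = 1000L)

## small straight rectangular duct domain (w x h section), for flow oracles
duct_domain <- function(w = 0.4e-3, h = 0.2e-3, len = 1.5e-3, dx = 25e-6) {
  nx <- round(len / dx); ny <- round(w / dx); nz <- round(h / dx)
  mask <- array(0L, c(nx + 2, ny + 2, nz + 2))
  mask[2:(nx + 1), 2:(ny + 1), 2:(nz + 1)] <- 1L
  sl <- mask[2, , ]; sl[sl == 1L] <- 2L; mask[2, , ] <- sl
  sl <- mask[nx + 1, , ]; sl[sl == 1L] <- 3L; mask[nx + 1, , ] <- sl
  structure(list(mask = mask, dx = dx,
                 origin = c(-dx / 2, -w / 2 - dx / 2, -dx / 2),
                 geometry = chamber_geometry()),
            class = "domain_mask")
}

## memoized full-device flow solve (desk-scale settings shared with the
## acceptance script)
device_flow <- function(u0, inlet = c("lower", "upper"), max_steps = 12000L) {
  inlet <- match.arg(inlet)
  key <- sprintf("%s_%0.2f_%d", inlet, u0, max_steps)
  if (!is.null(fixture_env[[key]])) return(fixture_env[[key]])
  fl <- suppressWarnings(
    chamber_flow(chamber_geometry(inlet_level = inlet), u0,
                 max_steps = max_steps, recharge = 3L))
  fixture_env[[key]] <- fl
  fl
}

## uniform synthetic flow field on a small box (tests of tracing/tracking)
uniform_flow <- function(u = c(0.01, 0, 0), n = c(40, 20, 20), dx = 50e-6) {
  mask <- array(0L, n + 2)
  mask[2:(n[1] + 1), 2:(n[2] + 1), 2:(n[3] + 1)] <- 1L
  mk <- function(v) array(v, n + 2) * (mask > 0)
  geom <- chamber_geometry()
  structure(list(ux = mk(u[1]), uy = mk(u[2]), uz = mk(u[3]),
                 rho = mk(1), domain = list(mask = mask, geometry = geom),
                 u0 = sqrt(sum(u^2)), dx = dx,
                 origin = -c(1, 1, 1) * dx / 2,
                 ghost = list(ux = mk(u[1]), uy = mk(u[2]), uz = mk(u[3])),
                 meta = list(converged = TRUE, steps = 0L,
                             residuals = numeric(0))),
            class = "flow_field")
}
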