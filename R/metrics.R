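## Simulation-side quantitative metrics: capture rate, coverage rate and
## release rate.

#' Capture rate
#'
#' CPR = 100 N_c / N: the percentage of released beads immobilized on the
#' chamber bottom.
#'
#' @param n_captured captured bead count N_c, or a `capture_result`
#' @param n_total total released count N
#' @return CPR in percent
#' @export
capture_rate <- function(n_captured, n_total) {
  if (inherits(n_captured, "capture_result")) {
    n_total <- n_captured$N
    n_captured <- n_captured$N_c
  }
  if (n_total < 1) stop("total bead count must be >= 1")
  if (n_captured > n_total) stop("captured count exceeds total")
  100 * n_captured / n_total
}

#' Coverage rate of captured beads
#'
#' COR = 100 S_p / S with S_p the occupied area and S the chamber bottom
#' area, both measured on a `grid_n` x `grid_n` occupancy grid over the
#' bounding square of the bottom disc.  Only cells whose centers lie inside
#' the disc count toward S; a cell is occupied when it contains at least one
#' captured bead.  The cell size (~167 um at the 36-cell default on a 6 mm
#' chamber) is the declared spatial scale of "coverage" for point-like
#' beads and is reported with every result.
#'
#' @param positions n x 2 matrix of (x, y) capture positions (m), chamber
#'   bottom coordinates
#' @param chamber_diameter bottom-disc diameter (m)
#' @param grid_n occupancy cells per side
#' @return COR in percent
#' @export
coverage_rate <- function(positions, chamber_diameter = 6e-3, grid_n = 36) {
  if (grid_n < 1) stop("coverage grid must have at least one cell")
  R <- chamber_diameter / 2
  cell <- chamber_diameter / grid_n
  ctr <- -R + (seq_len(grid_n) - 0.5) * cell
  in_disc <- outer(ctr^2, ctr^2, "+") < R^2
  S_cells <- sum(in_disc)
  pos <- as.matrix(positions)
  if (length(pos) == 0 || nrow(pos) == 0) return(0)
  r <- sqrt(pos[, 1]^2 + pos[, 2]^2)
  if (any(r > R)) {
    warning("dropping capture positions outside the bottom disc")
    pos <- pos[r <= R, , drop = FALSE]
    if (nrow(pos) == 0) return(0)
  }
  ix <- pmin(pmax(floor((pos[, 1] + R) / cell) + 1, 1), grid_n)
  iy <- pmin(pmax(floor((pos[, 2] + R) / cell) + 1, 1), grid_n)
  occ <- unique(cbind(ix, iy))
  occupied <- sum(in_disc[occ])
  100 * occupied / S_cells
}

#' Release-rate time series
#'
#' RER(t) = 100 (1 - N_p(t) / N) with N_p the bead count still inside the
#' chamber.
#'
#' @param time time grid (s)
#' @param n_in_chamber in-chamber counts N_p(t) on that grid
#' @param n_total total bead count N
#' @return data.frame with `time`, `n_in_chamber`, `rer_pct`
#' @export
release_rate_series <- function(time, n_in_chamber, n_total) {
  if (length(time) != length(n_in_chamber))
    stop("time grid and count series differ in length")
  if (any(n_in_chamber > n_total))
    stop("in-chamber count exceeds the total bead count")
  if (any(n_in_chamber < 0)) stop("negative in-chamber count")
  data.frame(time = time, n_in_chamber = n_in_chamber,
             rer_pct = 100 * (1 - n_in_chamber / n_total))
}
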