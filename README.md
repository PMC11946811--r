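# beadflow

Simulation of superparamagnetic bead capture and release in a cylindrical
microchamber used for nucleic-acid library preparation.

DNA cleanup on a chip binds the library to 4 µm superparamagnetic beads,
holds the beads with a permanent magnet while reagents are exchanged, and
must then resuspend and recover them.  `beadflow` models the device that
integrates both steps in one chamber: a 6 mm × 3 mm cylindrical
microchamber fed by 1 mm × 0.2 mm channels, with a 5 mm NdFeB magnet below
the chamber for capture and an 8 mm magnet above it for release.  The
package is aimed at microfluidic device designers who want to sweep
operating parameters (inlet velocity, magnet gap, magnet diameter) without
a commercial FEM license.

## What it computes

* **Magnetostatics** — the field of an axially magnetized cylinder as an
  equivalent solenoid (loop fields via complete elliptic integrals,
  Gauss–Legendre quadrature over the height), and the point-dipole force
  on a linearly magnetizable bead, F = V_p χ_b/(2µ0) ∇|B|².  Force maps on
  the chamber bottom and their gap statistics (peak, center, percentage
  reductions — remanence-independent).
* **Hydrodynamics** — steady incompressible flow in the voxelized chamber
  with a D3Q19 lattice-Boltzmann solver (incompressible equilibrium,
  regularized collision, developed-profile inlet, fixed-density outlet,
  optional mirror-symmetry half-domain), verified against the
  rectangular-duct series solution.  Streamline tracing and the
  *effective inlet length* — the fraction of the inlet width whose
  bottom-edge streamlines reach the outlet instead of feeding the vortex.
* **Bead dynamics** — overdamped Lagrangian tracking,
  u_p = u(x) + F_m/(6πηR_p), with wall-aware interpolation, freeze-on-touch
  capture, outlet-crossing escape, and release runs with the magnet above.
* **Metrics** — capture rate CPR = 100·N_c/N, coverage rate
  COR = 100·S_p/S on a declared occupancy grid, and the release-rate
  series RER(t) = 100·(1 − N_p(t)/N).
* **Image quantification** — the experimental counterpart: mean-background
  thresholding of grayscale micrographs, coverage from pixel counts,
  bead amount from the summed excess intensity I = Σ(G_ij − G), plus a
  synthetic micrograph generator with ground truth so the whole image
  pipeline is testable without laboratory data.

## A worked example

Force maps for the capture magnet at two gaps, and the gap statistics:

```r
library(beadflow)

bead <- particle_spec()                      # 4 um, chi_b = 0.38
m12 <- force_map(magnet_spec(gap = 1.2e-3), bead, z_plane = bead$radius)
m15 <- force_map(magnet_spec(gap = 1.5e-3), bead, z_plane = bead$radius)
force_map_stats(m15, reference = m12)
#> $peak_vertical
#> [1] 1.300762e-10
#> $center_vertical
#> [1] 1.292925e-10
#> $peak_horizontal
#> [1] 4.591514e-11
#> $reduction_peak_vertical
#> [1] 32.40615
#> $reduction_center_vertical
#> [1] 25.98275
#> $reduction_peak_horizontal
#> [1] 39.84937
```

Moving the magnet from 1.2 mm to 1.5 mm below the chamber cuts the peak
vertical force on the bottom by ~32 % but the center value by only ~26 %:
the map flattens, which disperses the captured beads at the cost of
holding force.  The percentages are independent of the assumed remanence.

A capture run at the lowest flow rate (a few minutes on one CPU):

```r
geom <- chamber_geometry(inlet_level = "lower")
flow <- chamber_flow(geom, u0 = 0.02, max_steps = 4000)
cfg  <- simulation_config(inlet_velocity = 0.02, particle_count = 1000,
                          rng_seed = 1, max_sim_time = 30)
cap  <- simulate_capture(flow, magnet_spec(gap = 1.5e-3), cfg)
round(c(CPR = cap$cpr_pct, COR = cap$cor_pct), 1)
#> CPR COR 
#> 100  11
```

Every bead is captured at 0.02 m/s; the captured beads occupy ~11 % of
the bottom disc on the default 36 × 36 occupancy grid, concentrated in
the inlet half — raising the flow rate disperses them at the cost of
capture.  `run_capture_sweep()`, `run_force_analysis()` and
`run_release_study()` orchestrate the full parameter sweeps and write
tidy CSV tables.

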