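# Reference device configuration (all lengths in meters, velocities in m/s)
geometry:
  chamber_diameter: 6.0e-03
  chamber_height: 3.0e-03
  channel_width: 1.0e-03
  channel_height: 2.0e-04
  channel_length: 3.0e-03
  inlet_level: lower
magnet:
  diameter: 5.0e-03
  height: 1.5e-03
  gap: 1.5e-03
  side: below
  remanence: 1.17
fluid:
  density: 1000
  dynamic_viscosity: 1.0e-03
particle:
  density: 1400
  diameter: 4.0e-06
  effective_susceptibility: 0.38
config:
  inlet_velocity: 0.02
  grid_spacing: 5.0e-05
  particle_count: 1000
  rng_seed: 1
  mode: capture
  max_sim_time: 30
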