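# Example pipeline configuration. Any omitted key keeps its package default.
seed: 1

landscape:
  nrow: 64
  ncol: 64
  cell_size: 1000       # m; sea cells are the 1x1-km planning units
  land_fraction: 0.3
  storm_rain_mm: 250    # cyclone-event rainfall at sea level
  n_towns: 6

musle:
  a: 11.8               # metric MUSLE calibration coefficients
  b: 0.56
  storm_duration_h: 24

dispersion:
  alpha: -2.3           # power-law decay of river-mouth sediment influence
  distance_metric: euclidean
  min_distance_km: 0.5

coral:
  k: 10                 # basis size of the log-TSS smooth
  method: REML
  n_draws: 1000         # posterior draws behind the exceedance surface
  threshold: 0.30       # good-condition hard-coral cover
  n_sites: 72
  transects: 3
  points_per_transect: 100

targets:                # fractions of total feature amount
  coral: 0.30
  mangrove: 0.30
  seagrass: 0.30
  turtle_grounds: 0.10

certainty: 0.90          # required P(coral target met), cyclone scenario

anneal:
  n_iterations: 100000
  cooling_factor: 0.999
  blm: 0
  n_solutions: 100
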