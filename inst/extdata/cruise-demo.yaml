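# Demo configuration for the picograze pipeline.
# Units: pp mg C m-3 d-1, rates d-1, abundances cells mL-1, depths m.
simulation:
  n_stations: 60
  depths_per_station: 3
  dilution_target: 0.33
  incubation_days: 1.0
  count_cv: 0.05
  d_jitter_sd: 0.02
  seed: 1
depth_rule: upper-half
regression:
  method: SMA
  n_perm: 999
  log_x: true
  log_y: true
projection:
  reference: HBAC
  low_max: 10
  high_min: 100
  n0: 10000
  threshold: 1
bin_edges: [10.0, 100.0]
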