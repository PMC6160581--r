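# 30-vessel demonstration configuration: a complete run finishes in well
# under a minute. All keys are optional; defaults are documented in
# ?run_pipeline.
seed: 4
network:
  n_vessels: 30
  box: [150.0, 151.0, 115.0]
voxel:
  h: 3
  bin_width: 5
lagrangian:
  t_end: 3
  averaging: 1
  dt: 0.001
  spacing_cv: 0.5
  coupling: true
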