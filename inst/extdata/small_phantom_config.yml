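# Small phantom cohort for a fast end-to-end pipeline run:
# 6 healthy eyes on a 64 x 64 grid (10 um pixels over a reduced field).
seed: 42
cohort:
  n_healthy: 6
  n_csc: 0
  grid_nx: 64
  grid_ny: 64
  pixel_pitch: 10
  artefact_fraction: 0
cvd_nominal_depth: 100
write_comparison_maps: true
max_comparison_maps: 2
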