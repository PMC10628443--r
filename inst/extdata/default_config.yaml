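# Example pipeline configuration mirroring the reference experiment.
# All values shown are the package defaults; override any subset.
simulate:
  n_control: 4
  n_drought: 5
  phase_lengths:
    pre_drought: 7
    drought: 12
    recovery: 10
    post_recovery: 10
  pot_capacity: 0.70
  pot_volume: 3000
  deficit_fraction: 0.80
  noise_sd: 0.5
extract:
  guard: 6
  smooth: 5
  min_coverage: 0.8
fit:
  grid: 200
  min_seg: 2
seed: 1
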