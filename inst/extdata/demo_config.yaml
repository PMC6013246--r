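seed: 1
stages:
  synth:
    n_cells: 6
    populations: [vl3, vl4]
    jitter_sd: 2
  metrics:
    nnd: true
    classify: true
    correlate: true
    n_real: 100
  analytics:
    model: M2
    lambda_min: 20
    lambda_max: 80
    b_min: 10
    b_max: 60
    grid_n: 9
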