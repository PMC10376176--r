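# Demo configuration: fully synthetic end-to-end run.
# Layers are standardized (z-scored), so niche coefficients and scenario
# deltas are in sd units.
synthetic:
  grid:
    n_rows: 60
    n_cols: 60
    lon_min: 60.0
    lat_min: 35.0
    cell_size: 0.1666666667
  n_layers: 6
  collinear_pairs:
    - source: env01
      target: env05
      r: 0.95
  niche:
    intercept: -8.0
    coefficients:
      env01: 7.0
      env02: -5.0
  n_presences: 200
  scenarios:
    - period: "2050"
      scenario: SSP126
      deltas: {env01: -0.05}
    - period: "2050"
      scenario: SSP245
      deltas: {env01: -0.10}
    - period: "2050"
      scenario: SSP585
      deltas: {env01: -0.15}
    - period: "2090"
      scenario: SSP126
      deltas: {env01: -0.08}
    - period: "2090"
      scenario: SSP245
      deltas: {env01: -0.15}
    - period: "2090"
      scenario: SSP585
      deltas: {env01: -0.25}
n_pseudo_absences: 1200
train_fraction: 0.7
n_repetitions: 10
learners: [GLM, SRE]
weight_mode: mean_of_both
seed: 1
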