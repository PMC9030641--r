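# Default run configuration (mirrors default_config()).
widths:
  common: [80, 46, 26]
  group: [26, 15, 9]
  individual: [9, 6, 7]
  control: [75, 49, 35, 32]
clustering:
  groups: 5
  m: 2
  u_floor: 0.1
  eps: 1.0e-5
  max_iter: 200
  init: wwo
pretrain:
  corruption: 0.2
  budget: 100000     # full-run evaluation budget
  quick_budget: 5000 # scaled-down default for quick runs
records:
  step_ms: 200
  wind_max: 1.5      # m/s; records above this are rejected
output_weights: [0.24, 0.2, 0.2, 0.15, 0.07, 0.07, 0.07]
control:
  tol: 0.15          # success-rate deviation tolerance (fraction of range)
  t_p_frac: 0.1      # share of training verified on the physical responder
evaluation:
  folds: 5
  repeats: 20
seed: 1
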