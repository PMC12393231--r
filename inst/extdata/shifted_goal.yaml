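name: shifted_goal
env:
  horizon: 30.0
  start: 0.0
  param_convention: endpoint
goal:
  regions:
    R:
      center: 2.5
      width: 1.0
    L:
      center: -2.0
      width: 1.0
  target: R
  reach_mode: terminal
  waypoints: []
rule:
  epsilon: 0.1
complexity:
  default_policy:
    mu: 0.0
    sigma: 1.0
  level: endpoint
  direction: forward
  base: bits
bound:
  delta: 0.25
hops:
  n_hops: 1.0
domain:
  mu_min: -3.0
  mu_max: 3.0
  sigma_min: 0.5
  sigma_max: 2.0
  n_mu: 301.0
  n_sigma: 151.0
estimator:
  method: analytic
  n_mc: 100000.0
seeds:
  trajectories: 1.0
  estimator: 1.0
n_trajectories: 500.0
epsilons:
- 0.0001
- 0.000142601
- 0.000203352
- 0.000289982
- 0.000413519
- 0.000589683
- 0.000840896
- 0.00119913
- 0.00170998
- 0.00243845
- 0.00347726
- 0.00495862
- 0.00707107
- 0.0100834
- 0.0143791
- 0.0205048
- 0.0292402
- 0.0416969
- 0.0594604
- 0.0847913
- 0.120914
- 0.172424
- 0.24588
- 0.350628
- 0.5
deltas:
- 0.0
- 0.25
- 0.5
- 0.75
- 1.0
- 1.25
- 1.5
- 1.75
- 2.0
- 2.25
- 2.5
- 2.75
- 3.0
- 3.25
- 3.5
- 3.75
- 4.0
- 4.25
- 4.5
- 4.75
- 5.0
- 5.25
- 5.5
- 5.75
- 6.0
- 6.25
- 6.5
- 6.75
- 7.0
- 7.25
- 7.5
- 7.75
- 8.0
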