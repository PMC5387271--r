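# Stochastic time-course pipeline: 40 independent exact (Gillespie)
# simulations of the insulin receptor model, summarised as mean, 95% CI of
# the mean, and 1 standard deviation per time point.
pipeline: simulate
model: ../insulin_receptor.yaml
output_dir: results_simulate
title: Stochastic time course of insulin receptor activation
simulator:
  kind: ssa
runs: 40
master_seed: 42
workers: 1
times:
  from: 0
  to: 10
  by: 0.2
level: 0.95
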