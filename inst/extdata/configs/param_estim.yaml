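# Repeated parameter estimation with sampled profile likelihood.
# The dataset path is relative to this file; generate one with
# kinpipe::make_dataset() or point at your own experiment TSV
# (Time column + one column per observed readout).
pipeline: param_estim
model: ../insulin_receptor.yaml
output_dir: results_estim
title: Insulin receptor parameter estimation
dataset: calibration_data.tsv
parameters:
- {name: k1, lower: 1.0e-3, upper: 100, scale: log10}
- {name: k2, lower: 1.0e-3, upper: 100, scale: log10}
- {name: k3, lower: 1.0e-3, upper: 100, scale: log10}
pso:
  swarm_size: 20
  iterations: 80
runs: 50
master_seed: 1
workers: 1
levels: [0.66, 0.95, 0.99]
df: 1
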