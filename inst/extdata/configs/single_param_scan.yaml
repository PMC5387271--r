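# Scan the phosphorylation rate k1 across a range (e.g. its estimated 95%
# confidence interval) with 100 time-course simulations.
pipeline: single_param_scan
model: ../insulin_receptor.yaml
output_dir: results_scan1d
title: Single-parameter scan of k1
scan:
  parameter: k1
  min: 0.25
  max: 1.0
  count: 100
  scale: linear
times:
  from: 0
  to: 20
  by: 0.5
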