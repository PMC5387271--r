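# Scan the insulin input level against the initial receptor level and report
# the phosphorylated-receptor signal at 1, 2, 5 and 10 minutes.
pipeline: double_param_scan
model: ../insulin_receptor.yaml
output_dir: results_scan2d
title: Insulin x receptor level scan
scan:
  parameter: insulin
  min: 20
  max: 200
  count: 10
  scale: percent
  ref: 1.0
scan2:
  parameter: IR_beta
  min: 20
  max: 200
  count: 10
  scale: percent
  ref: 16.0
times: [0, 1, 2, 5, 10]
report_times: [1, 2, 5, 10]
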