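# Minimal three-state insulin receptor activation model.
# Rate and initial values are package defaults chosen for a plausible
# minutes-scale response (see ?ir_receptor_model), not fitted estimates.
name: insulin_receptor
species:
- name: IR_beta
  initial: 16.0
- name: IR_beta_pY1164
  initial: 0.0
- name: IR_beta_refrac
  initial: 0.0
- name: insulin
  initial: 1.0
  fixed: true
reactions:
- 'IR_beta + insulin -> IR_beta_pY1164 : k1'
- 'IR_beta_pY1164 -> IR_beta_refrac : k2'
- 'IR_beta_refrac -> IR_beta : k3'
parameters:
  k1: 0.5
  k2: 1.0
  k3: 0.1
readouts:
- IR_beta
- IR_beta_pY1164
- IR_beta_refrac
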