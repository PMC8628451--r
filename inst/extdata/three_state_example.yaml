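# Minimal worked model-structure config: a three-state illness-death model
# with annual cycles, used in the documentation examples.
cycle_length: 1
states:
  - {name: well, cost: 100, utility: 0.9}
  - {name: sick, cost: 2500, utility: 0.6}
  - {name: dead, absorbing: yes}
transitions:
  edges:
    - {from: well, to: sick, prob: 0.10}
    - {from: well, to: dead, prob: 0.02}
    - {from: sick, to: well, prob: 0.05}
    - {from: sick, to: dead, prob: 0.20}
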