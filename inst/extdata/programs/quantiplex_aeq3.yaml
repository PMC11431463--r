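name: quantiplex_aeq3
initial_holds:
- temperature_c: 95.0
  seconds: 180.0
stages:
- cycles: 16
  steps:
  - label: denature
    temperature_c: 95.0
    base_seconds: 5.0
    increment_seconds_per_cycle: 0.0
  - label: anneal_extend
    temperature_c: 60.0
    base_seconds: 10.0
    increment_seconds_per_cycle: 0.0
- cycles: 24
  steps:
  - label: denature
    temperature_c: 95.0
    base_seconds: 5.0
    increment_seconds_per_cycle: 0.0
  - label: anneal_extend
    temperature_c: 60.0
    base_seconds: 70.0
    increment_seconds_per_cycle: 0.0
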