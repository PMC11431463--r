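name: globalfiler_modified
initial_holds:
- temperature_c: 94.0
  seconds: 180.0
stages:
- cycles: 30
  steps:
  - label: denature
    temperature_c: 94.0
    base_seconds: 10.0
    increment_seconds_per_cycle: 0.0
  - label: anneal_extend
    temperature_c: 59.0
    base_seconds: 60.0
    increment_seconds_per_cycle: 1.56
final_holds:
- temperature_c: 60.0
  seconds: 600.0
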