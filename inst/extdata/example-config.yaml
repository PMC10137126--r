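# Example pipeline configuration.
# `design` may be a preset (visual / auditory / null), a path to a design
# YAML written by write_design_yaml(), or an inline design mapping.
design: visual
modality: visual
seed: 7
alpha: 0.05
preprocess:
  lowpass_hz: 40
  target_rate_hz: 200
  anticipation_floor_s: 0.08
  require_correct: true
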