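# Example run configuration: overrides a few fields, everything else takes
# the nominal defaults.
model:
  beta1: 0.6
  beta: 0.2
survival:
  n_crit: 8000
  t_max: 500
transcription:
  n_nodes: 400
  horizon: 14
seed: 1
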