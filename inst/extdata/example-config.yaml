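# Example run configuration. Parameter names follow the model's conventional
# symbols; anything omitted keeps the published default.
params:
  D: 0.5          # decay rate (1/s)
  Tr: 0.08        # mean refreshing step (s)
trial:
  list_length: 5
  nd: 2
  dac: 0.5
  ft: 0.6
grid:
  nd: [0, 1, 4, 8]
  dac: [0.3, 0.5, 0.7]
  ft: [0.0, 0.1, 0.6, 1.2, 2.0]
  mdo: [0.0, 1.0]
  mdd: [0.0, 1.0]
  hod: [identical, distinct]
  list_length: [1, 2, 3, 4, 5, 6, 7, 8, 9]
  runs_per_case: 20
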