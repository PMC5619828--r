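cell:
  diameter: 16.0
  nc: 0.29
  n_vertices: 3500.0
  assembly: []
thermo:
  kBT: 1.0
  dt: 0.001
  steps: 500000.0
  seed: 1.0
experiment:
  kind: aspiration
output:
  path: out
  cadence: 1000.0
invoked: bogus
seed: 1
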