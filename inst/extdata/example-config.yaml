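# Reduced-scale example configuration (desk-scale; the calibrated cell
# uses diameter 16, nc 0.29, n_vertices 3500 and the default assembly
# parameters).
cell:
  diameter: 6
  nc: 0.29
  n_vertices: 320
  assembly:
    polymerize_steps: 2000
    cl_max_steps: 20000
    link_max_steps: 10000
    window: 2000
thermo:
  kBT: 1
  dt: 0.001
  seed: 1
experiment:
  kind: aspiration
  pipette_radius: 1.2
  n_levels: 6
  steps_per_level: 500
output:
  path: out
  cadence: 1000
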