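# Desk-scale dissection study (~10^3 elements).
# Units: lengths um, pressures kPa or "<value> mmHg", time in model units.
mode: dissection
geometry:
  h_coarse: 60
  h_fine: 20
vv_tree:
  seed: 42
pressure: 120 mmHg
solver:
  dt: 2.0e-4
  t_end: 1.4e-3
output:
  stride: 2
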