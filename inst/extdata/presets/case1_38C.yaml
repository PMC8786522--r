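name: case1_38C
mode: steady
geometry:
  depth_mm: 8
  height_mm: 8
  width_mm: 8
  spacing_mm: 2
layers:
  thicknesses_mm:
    scalp: 4.5
    skull: 3.5
    csf: 2.0
  scalp_split_mm: 2.25
  scalp_Qm_outer: 0
materials:
  scalp: {k: 0.342, rho: 1070, c: 3600, Qm: 1800}
  skull: {k: 0.651, rho: 1520, c: 1590, Qm: 0}
  csf: {k: 0.217, rho: 880, c: 2360, Qm: 300}
shared:
  mb: 0.00606
  cb: 4010
  TA: 38.0
  Qe: 0
  he: 0.64
  Tw: 7.0
boundaries:
  surface: dirichlet
  deep: dirichlet
  robin_order: 2
schedule:
  output_interval_s: 120
  t_end_s: 360
  reset_interval_s: 120
solver:
  init: linear
  reset_action: clamp_surface_dirichlet
  safety_factor: 0.9
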