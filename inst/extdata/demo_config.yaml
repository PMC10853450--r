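# Demo: intratympanic dexamethasone in the default porcine scala tympani.
seed: 1
out_dir: cochleaPK_demo
stages: [geometry, simulate, sample, report]
geometry:
  profile: pig          # pig | human | {csv: path} | {mask: path, voxel_size_um: n}
  rwm_area_mm2: 2.0
  aqueduct_flow_nL_s: 0
  dispersion_factor: 1
drugs: [dex]            # dex | dsp | a full drug_params spec
dose:
  C_me_0: 100           # ug/mL in the middle ear
  injected_volume_mL: 1
  t_end_min: 300
solver:
  dx_mm: 0.1
  dt_s: 0.5
  output_every_min: 5
sampling:
  at_min: 30
  tube_volume_uL: 5
  n_tubes: 5
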