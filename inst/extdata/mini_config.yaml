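# Minimal pipeline configuration: 2 adult phantom sizes x 3 energies
# (SECT 120 kV baseline + VMI 40 and 60 keV) on one DECT scanner label.
seed: 7
phantom:
  set: dect
  dect_sizes: ["Small Adult", "Medium Adult"]
acquisition:
  sect_kv: [120]
  vmi_kev: [40, 60]
contrast_model:
  kv_effective_kev:
    "100": 58
    "120": 65
noise_model:
  sigma_ref: 10
  d_ref_cm: 20
  ctdi_ref: 10
  size_coeff: 0.05
  recon_factor:
    IR: 1.0
grid:
  pixel_spacing_mm: 2.5
  slice_thickness_mm: 5
  n_slices: 5
measure:
  roi_fraction: 0.7
  mode: geometry
  central_fraction: 0.6
plan:
  baseline_energy: 120
  baseline_mode: SECT
  target_mode: DECT-VMI
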