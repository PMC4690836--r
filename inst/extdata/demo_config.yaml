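# Minimal desk-scale demo: coarse grid, small device, short contrast run.
# Units are carried in the key names (mm, um, Pa, s).
parent_diameter_mm: 4
daughter_diameters_mm: [3, 3]
dome_diameter_mm: 8
neck_diameter_mm: 5
device_diameter_mm: 3.5
device_length_mm: 15
n_strands: 48
wire_diameter_um: 30
target_porosity: 0.70
catheter_diameter_mm: 1.0
deploy_enabled: true
n_release_bands: 8
deploy_max_iters: 600
resolution_cells_per_diameter: 8
jailed_bias_sweep_pa: [0, 300]
contrast_enabled: false
out_dir: "stentflow_demo"
seed: 1
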