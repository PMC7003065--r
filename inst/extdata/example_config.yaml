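# Example pipeline configuration (see read_pipeline_config()).
# Defaults fill any omitted field.
acquisition:
  frame_interval: 0.015   # seconds
  n_frames: 10000
  localization_sigma: 0.035  # um
  activations_per_cell_per_frame: 0.01
  survival_prob: 0.6
geometry:
  length: 2.0   # um, cylinder section
  radius: 0.45  # um
  n_cells: 200
linking:
  max_displacement: 0.9  # um per frame
  max_gap: 0
thresholds:
  immobile_max: 0.2  # um^2/s
  fast_min: 1.5
species:
  d: [0.11, 0.41, 1.24]          # um^2/s
  occupancy: [0.16, 0.42, 0.42]
min_steps: 4
k_species: 3
seed: 1
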