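# Default episcan pipeline configuration: simulate a three-animal cohort,
# scan perpendicular to the lamina, average hierarchically, compare the
# Gb1/Gg13 pair within the basal marker window, and run the qPCR stage.
seed: 1
stages: [simulate, scan, average, window_stats, qpcr]
output_dir: episcan_out
simulate:
  model:
    image_height_px: 256
    image_width_px: 512
    lamina_baseline_px: 180
    lamina_amplitude_px: 12
    lamina_wavelength_px: 480
    noise_sd: 0.05
    blob_density_per_um2: 0
  probes: [Gb1, Gg13, GAP43]
  n_animals: 3
  images_per_animal: 2
  scans_per_image: 2
  step_px: 1
average:
  n_points_animal: 500
  n_points_group: 100
window_stats:
  window: [0.63, 0.93]
  pair: [Gb1, Gg13]
  mode: pointwise_values
qpcr:
  reference_gene: Gapdh
  true_rel_expression:
    Gb1: 1.3
    Gg8: 0.5
    Gg13: 9.3
  n_biological: 3
  n_technical: 3
  ct_reference_mean: 18
  ct_noise_sd: 0.2
  mode: delta_ct
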