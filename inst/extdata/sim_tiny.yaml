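# Tiny end-to-end demonstration configuration (seconds-scale): two small
# volumes of retina-like samples on a 256-pixel detector, reconstructed at
# five coefficients in [-40, 40], with a small restoration model.
schema_version: 1
simulator:
  n_pixels: 256
  center_wavelength_nm: 840
  fwhm_bandwidth_nm: 50
  a_lines: 32
  n_volumes: 2
  locations: 2
  repeats: 2
  noise_gaussian_sd: 0.05
  noise_shot_scale: 0
  speckle_density: 4
  curvature_sag_um: 10
  a2_jitter_sd: 2
reconstruction:
  c_min: -40
  c_max: 40
  n_channels: 5
  interpolation: spline
  floor_db: -60
gtruth:
  bands: 5
  feather: 0
  pool_depth: 4
  pool_lateral: 1
model:
  n_channels: 5
  encoder_stages: 2
  growth_per_block: 4
  base_filters: 4
  final_activation: sigmoid
  loss: mae
  learning_rate: 0.002
  epochs: 2
  batch_size: 4
evaluation:
  ssim_scales: 1
  repeats_averaged: true
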