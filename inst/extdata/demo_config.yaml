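# Demonstration run: two U-fiber bundles (FA 0.6 vs 0.4) beneath a flat
# cortical sheet, plus a synthetic 20-vs-20 cohort with a group effect
# injected in a disc of radius 7 mm. The sheet's vertex spacing matches
# the 0.5 mm voxel grid so the subcortical voxel layer is gap-free.
mesh:
  extent_mm: [24, 24]
  vertex_spacing_mm: 0.5
  undulation_amplitude_mm: 0
  origin: [5, 5, 13]
phantom:
  grid_shape: [68, 68, 28]
  voxel_size: [0.5, 0.5, 0.5]
  origin: [0, 0, 0]
  fa_background: 0.05
  noise_sd_fa: 0.0
  noise_sd_dir_deg: 0.0
  rng_seed: 11
  bundles:
    - id: u_left
      endpoint_a: [9, 11, 12]
      endpoint_b: [19, 11, 12]
      arc_depth: 3
      tube_radius: 0.8
      fa_inside: 0.6
    - id: u_right
      endpoint_a: [9, 19, 12]
      endpoint_b: [19, 19, 12]
      arc_depth: 3
      tube_radius: 0.8
      fa_inside: 0.4
tracking:
  fa_threshold: 0.14
  angle_threshold: 35
  step_size: 0.5
  smoothing: 0.5
  min_length: 10
  max_length: 65
parcellation:
  K: 25
  depth_mm: 2
  rng_seed: 7
sficd:
  fwhm_mm: 15
cohort:
  n_per_group: 20
  baseline_mean: 1.0
  noise_sd: 0.05
  noise_fwhm_mm: 15
  months: 27
  rng_seed: 23
  effect_region:
    center: [17, 17, 13]
    radius_mm: 7
    delta: 0.1
stats:
  vertex_p: 0.01
  cluster_p: 0.01
  n_iter: 1000
  rng_seed: 5
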