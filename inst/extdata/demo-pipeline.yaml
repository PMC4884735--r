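# Demo configuration for `ficdmap run --config demo-pipeline.yaml --out out/`:
# a straight high-FA bundle through a small spherical cortex, a 12-subject
# two-group cohort, and the full parcellate -> track -> FiCD -> smooth ->
# Z -> GLM -> Monte Carlo -> ROI chain at desk scale.
rng_seed: 7
phantom:
  grid_shape: [30, 30, 30]
  voxel_size: 2
  fa_background: 0.05
  mesh_subdiv: 3
  mesh_radius: 20
  bundles:
    - points:
        - [-10, 30, 30]
        - [70, 30, 30]
      radius: 6
      fa: 0.8
cohort:
  n_group_a: 6
  n_group_b: 6
K: 60
fwhm: 8
n_iter: 500
cf_p: 0.05
alpha: 0.05
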