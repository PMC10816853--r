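# Loss settings, INbreast-style preset. alpha is the dice weight of the
# pixel hybrid (1 in the plain hybrid setting, 2 in the density-adaptive
# experiments); the gammas use the endpoints of the reported tuning interval
# [0.25, 0.35] since per-term values were not itemized.
pixel:
  alpha: 2
  beta: 1
  dice_epsilon: 1.0
  prob_clamp: 1.0e-7
  dice_dialect: paper
region:
  eta: 1
  tau: 1
  ssim:
    window_size: 11
    window_kind: gaussian
    gaussian_sigma: 1.5
    dynamic_range: 1
  rmi:
    region_size: 3
    downsample_factor: 2
    pooling: avg
    regularization_epsilon: 5.0e-4
rasp:
  i_dice: 0.125
  i_bce: 0.125
  gamma_dice: 0.25
  gamma_bce: 0.35
  p_mode: binary
dasp:
  theta: [0.5, 0.5, 0.85, 0.95]
focal:
  mode: ratio
  upsilon_by_group: [0.25, 0.5]
  upsilon_by_density: [0.2, 0.25, 0.3, 0.35]
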