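# Default calibration design: six-point curve, 1-50 ng of both peptides per
# 0.5 ul spot with a 6.25 ng melittin deposition marker, three independent
# experiments with two replicate slides each.  Generating fixed effects of
# the per-pixel calibration curve: log10 signal = 3.1 * c_pixel + 0.2.
kind: calibration
amounts: [1.0, 2.5, 5.0, 10.0, 25.0, 50.0]
melittin_amount: 6.25
n_experiments: 3
n_replicates: 2
slope: 3.1
intercept: 0.2
exp_sd: 0.05
pixel_sd: 0.10
batch_sd: 0.15
spot_radius: 3
grid_shape: [30, 48]
background_mu: 2.0
background_sigma: 0.10
melittin_log10: 2.0
melittin_sigma: 0.10
seed: 1
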