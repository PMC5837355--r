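# Two-exposure scenario for multivariable IVW over the union of both
# instrument sets. Direct (mutually adjusted) effects -0.45 and +0.42;
# the correlation 0.488 between the two exposures' variant effects and
# the gamma-SD ratio 0.878 are chosen so that the implied univariable
# IVW estimates are -0.27 (waist-like) and +0.17 (hip-like), matching
# the omitted-exposure algebra of correlated instruments.
k_snps: 131
beta_true: -0.45
beta2_true: 0.42
n_exposure: 210088
n_outcome: 29347
maf_range: [0.05, 0.5]
gamma_sd: 0.0242
gamma2_sd: 0.02125
exposure_correlation: 0.488
pleiotropy:
  fraction_invalid: 1.0
  mean: 0.0
  sd: 0.012
  directional: false
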