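# Robustness scenario: 30% of instruments carry large directional
# pleiotropy (direct outcome effects of mean 0.03 on the positive-gamma
# orientation, several times the mediated effect, so the per-variant
# heterogeneity contributions are clearly above the chi-square(1) scale).
# Naive IVW is badly biased; the penalized weighted median downweights
# the invalid variants and stays near the truth; the MR-Egger intercept
# recovers the mean direct effect (0.3 * 0.03 = 0.009).
k_snps: 56
beta_true: -0.27
n_exposure: 210088
n_outcome: 29347
maf_range: [0.05, 0.5]
gamma_sd: 0.0242
pleiotropy:
  fraction_invalid: 0.3
  mean: 0.03
  sd: 0.005
  directional: true
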