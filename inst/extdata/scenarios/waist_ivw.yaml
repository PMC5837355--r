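# Abdominal-fat (waist circumference) instrument scenario:
# 56 independent instruments explaining ~1.2% of exposure variance at
# consortium sample sizes, causal effect -0.27 SD log-adiponectin per SD
# waist. Balanced per-variant pleiotropy sized so the expected I^2 across
# Wald ratios is ~72%.
k_snps: 56
beta_true: -0.27
n_exposure: 210088
n_outcome: 29347
maf_range: [0.05, 0.5]
gamma_sd: 0.0242
pleiotropy:
  fraction_invalid: 1.0
  mean: 0.0
  sd: 0.0155
  directional: false
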