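# Gluteofemoral-fat (hip circumference) instrument scenario:
# 75 independent instruments explaining ~2.0% of exposure variance,
# causal effect +0.17 SD log-adiponectin per SD hip. Balanced pleiotropy
# sized for an expected I^2 of ~46%.
k_snps: 75
beta_true: 0.17
n_exposure: 210088
n_outcome: 29347
maf_range: [0.05, 0.5]
gamma_sd: 0.027
pleiotropy:
  fraction_invalid: 1.0
  mean: 0.0
  sd: 0.0089
  directional: false
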