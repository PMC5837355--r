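# Null scenario: no causal effect, all instruments valid. Used for
# type-I-error checks of the IVW test and the Egger intercept test.
k_snps: 56
beta_true: 0.0
n_exposure: 210088
n_outcome: 29347
maf_range: [0.05, 0.5]
gamma_sd: 0.0242
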