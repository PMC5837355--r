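# Reverse-direction scenario: four strong adiponectin instruments
# (ADIPOQ-region-like, ~4% variance explained) against a girth outcome
# with no true reverse effect.
k_snps: 4
beta_true: 0.0
n_exposure: 29347
n_outcome: 210088
maf_range: [0.05, 0.5]
gamma_sd: 0.1655
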