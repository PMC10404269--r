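# Desk-scale demo configuration for the end-to-end multi-PGS workflow.
# Values override default_config(); see ?default_config for every field.
seed: 42
panel:
  m: 2000
  block_size: 50
  rho: [0.2, 0.9]
architecture:
  n_traits: 20
  h2: 0.5
  rg_target_aux: 0.5
  rg_aux_aux: 0.3
  polygenicity: 0.05
gwas:
  n_target: 1000
  n_aux: 50000
cohort:
  n_ind: 4000
  prevalence: 0.2
evaluate:
  k_folds: 5
  B: 2000
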