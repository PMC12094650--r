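# Demonstration configuration: a desk-scale synthetic cohort mirroring the
# study design the package is organised around (717 cases / 356 controls,
# lifetime risk 1%, six exposure domains), with 2000 variants in LD blocks
# of 50. Runs end to end in a few minutes on one CPU.
master_seed: 1
output_dir: "geiprs_demo_output"
simulation:
  M: 2000
  n_ref: 500
  block_size: 50
  rho: 0.6
  h2: 0.3
  p_causal: 0.03
  N_gwas: 50000
  K: 0.01
  n_case: 717
  n_control: 356
  coef_G: 0.7
  coef_E: 1.0
  coef_GE: 0.3
  mechanism: logit
prs:
  n_iter: 150
  burn_in: 50
power:
  n_reps: 200
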