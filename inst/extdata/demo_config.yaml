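# Example configuration for run_pipeline(); any key omitted here keeps
# its package default (see ?pipeline_config).
seed: 1
design:
  n_metabolites_blood: 12
  n_metabolites_csf: 12
  n_shared: 12
  replicates_per_group: 3
copula:
  base_spearman: 0.5
spectra:
  axis_step: 0.002
  noise_sd: 0.01
preprocess:
  bin_width: 0.002
corrnet:
  alpha: 0.05
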