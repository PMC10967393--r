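seed: 5
cohort:
  n_patients: 60.0
  n_genes: 800.0
  n_modules: 4.0
  module_sizes: 80.0
  module_loading: 0.8
  frac_lncRNA: 0.4
  n_batches: 3.0
threshold:
  min_reads: 10.0
  min_frac: 0.4
  group_by: disease
de:
  enabled: yes
  contrast: UC-inf
  location: colon_nonrectal
  max_genes: 150.0
network:
  power: 8.0
  covariates: batch
  min_module_size: 25.0
  cut_height: 0.99
  merge_height: 0.2
preservation:
  enabled: yes
  frac_train: 0.7
  n_permutations: 50.0
genetics:
  enabled: yes
  n_snps: 300.0
  window: 50000.0
  n_boot: 2000.0
  enrich_first_module: yes
  excess_rate: 0.5
hubs:
  threshold: 0.02
  top_k: 10.0
screen:
  enabled: yes
  n_genes: 80.0
  guides_per_gene: 6.0
  n_controls: 80.0
  n_regulators: 4.0
  effect: 1.5
  depth: 1000000.0
  n_perm: 400.0
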