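# Example pipeline configuration for `cerna-pivot.R run --config ...`
# or cernaPivot::readPipelineConfig(). Omitted keys keep their defaults.
seed: 1
alpha: 0.05
lfc_min: 1
r_min: 0.6
sign_mode: positive
min_shared: 1
k: 10
posterior_threshold: 0.8
reference_gene: REF1
sim:
  n_pairs: 6
  n_mrna: 400
  n_lncrna: 180
  n_mirna: 120
  de_fraction: 0.1
  de_log2fc: 3
  module_size: 8
  module_rho: 0.8
  shared_mirna_count: 3
stages:
  simulate: true
  normalize: true
  de: true
  evaluate: true
  enrich: true
  network: true
  topology: true
  qpcr: true
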