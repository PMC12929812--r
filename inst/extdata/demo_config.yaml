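# Demo pipeline configuration: 20-patient synthetic cohort, all stages.
seed: 1
cohort:
  n_patients: 20
  n_genes: 300
stages:
  thresholds: true
  crosscor: true
  lmm: true
  deg: true
  tcr: true
  spatial: true
  histo: true
crosscor:
  B: 10000
  r_thresh: 0.25
  p_thresh: 0.05
  min_cells: 10
lmm:
  target_gene: CTLA4
  target_cell_type: T
deg:
  cell_type: T
  rule: human
spatial:
  rows: 25
  cols: 25
  rho: 0.5
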