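# Demo configuration: small synthetic cohort, full pipeline.
synthetic: true
design:
  n_per_group: [6, 6]
  grid: [9, 9, 9]
  roi_semiaxes: [3.0, 2.5, 2.0]
  noise_snr: 50
  seed: 42
biomarkers: [DT, KT]
selection: L1L2
split: 0.75
seed: 42
cv_folds: 3
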