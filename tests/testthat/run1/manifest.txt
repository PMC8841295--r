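seed: 42
selection: L1L2
biomarkers: DT, KT
selected_features: DT=354, KT=2
design_seed: 42
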