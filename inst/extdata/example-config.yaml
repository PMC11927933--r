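# Example run configuration for the dyncouple CLI / run_pipeline().
# Omitted keys keep the package defaults (which equal the study's stated
# analysis values). This small setup runs in seconds.
simulation:
  n_subjects_per_group: 4
  eeg_fs: 80
  channels: [P4, P6, P8, PO4, PO8, O2]
analysis:
  lags: [0]
  fdr_q: 0.05
seed: 7
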