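# Example pipeline configuration; unset blocks keep their defaults.
seed: 7
rf:
  alpha0: 2.0
  alphaf: 0.10
  snr_db: 30
ct:
  n_slices: 24
cohort:
  n_fx: 29
  n_nfx: 26
  n_vertebral: 18
  n_other: 21
  missing_spine_frac: 0.15
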