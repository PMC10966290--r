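# Example clotlyse run configuration (synthesis mode).
# Exactly one of `synthesis` or `inputs` must be present.
synthesis:
  n_subjects: 32     # paired subjects (pre + post records each)
  replicates: 2      # duplicate wells per sample
  noise_sd: 0.003    # plate-reader noise, AU
  rho: 0.35          # pre/post correlation of the shared latent factor
  phi: 0.35          # subject-level share of variable-specific variation
# inputs:
#   plate_file: plate.csv
#   layout_file: layout.csv
#   cohort_file: cohort.csv
extraction:
  baseline_points: 3
  lag_threshold: 0.01
  return_tolerance: 0.01
stats:
  alpha: 0.05
  continuity_correction: true
  reml: true
attrition:
  approached: 119
  consented: 63
  post_excluded: 16
  followup_failures: 15
seed: 1
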