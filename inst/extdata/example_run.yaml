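# Example run configuration for the episcore CLI
# (Rscript inst/cli/episcore.R pipeline --config example_run.yaml)
seed: 7
output_dir: episcore_run
log_level: info
simulate:
  n_train: 300
  n_test: 200
  n_target: 600
  n_cpg: 500
  block_size: 20
  rho: 0.5
  n_proteins: 8
  r2: [0.4, 0.3, 0.25, 0.2, 0.0, 0.0, 0.0, 0.0]
  baseline_hazard: 0.02
train:
  alpha: 0.5
  n_lambda: 100
  cv_folds: 10
  min_overlap: 100
select:
  r_threshold: 0.1
  p_threshold: 0.05
associate:
  basic_covariates: [age, sex]
  min_cases: 10
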