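# Example pipeline configuration for read_run_config() / run_gsv_pipeline().
# Omitted fields fall back to package defaults (four acquisitions, three
# GSV strata, nine acquisition sources, five predictors, both models).
scene:
  n_plots: 50
  noise_sd: 0.45
  shadow_frac: 0.0
  seed: 1
predictors: [dbl, dbl_odd, vol_odd, dblxvol, dblxvol_odd]
models: [glm, semiexp]
alpha: 0.01
threshold_rel: 0.5
gsv_cap: 500
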