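# Demo pipeline configuration: a small synthetic world that runs in a few
# seconds and shows the headline coefficient pattern.
# Usage: run_pipeline(read_pipeline_config(system.file(
#   "extdata", "demo-config.yaml", package = "driftforage")))
simulate:
  n_seals: 8
  days_per_seal: 60
windows: [1, 2, 3, 7, 10]
window_mode: block
min_segments: 1
min_dives: 5
classify_habitat: true
metrics: [descent_rate, ascent_rate, dive_residual, surface_residual]
stratify: none
basis_dim: 10
trackfit_restarts: 3
seed: 3
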