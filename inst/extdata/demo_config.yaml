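# Demo pipeline configuration: synthesise a control depressing (STD)
# regime and run every analysis stage on it. Point out_dir somewhere
# writable before running, e.g.
#   run_pipeline(modifyList(yaml::read_yaml(cfg), list(out_dir = tempdir())))
seed: 1
condition: control
class: STD
n_sweeps: 200
n_sites: 10
quantal_size_pa: 15
baseline_sd_pa: 2
cv_quantal: 0.3
dt_ms: 0.05
q_form: constant
delta_classify: 0.1
threshold_sd: 3
model_free_params: p0
out_dir: stspdyn-demo
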