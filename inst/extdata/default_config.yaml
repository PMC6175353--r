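# Default run configuration: the simulation-study setup.
doses: [100, 150, 180, 215, 245, 260]
reference_dose: 200
theta: 0.16
delta: 0.35
method: baseline
max_patients: 60
accuracy_stop: false
min_at_dose: 5
ci_level: 0.95
ci_width_bound: 5
n_iterations: 20000
burn_in: 5000
prior_inclusion: [0.5, 0.5]
inclusion_bound: 0.25
slab_scale: 1
scenarios: [1, 2, 3, 4, 5, 6]
n_replicates: 1000
root_seed: 1
fast: false
out_dir: doseslab-out
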