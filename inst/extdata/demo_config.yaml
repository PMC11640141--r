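# End-to-end demo: simulate a combined-database run, harmonize, fit the
# DMI-only mixed model, and evaluate the registry equations.
out_dir: ch4meta_demo
simulate: true
database: combined
n_studies: 34
treatments_per_study: [3, 6]
equations: [eq1c, eq4c, ipcc2006, mills_linear, ramin_huhtanen2013, patra]
fit_candidates: [dmi_kg_d]
vif_cutoff: 10
alpha: 0.1
seed: 1
verbose: false
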