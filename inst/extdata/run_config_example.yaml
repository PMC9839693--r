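# Example run configuration for run_report() / read_run_config().
# Absent keys keep their defaults.
rarefy_depth: min       # or an integer read depth
min_otu_total: 100      # dataset-wide rare-OTU threshold
window_days: 90         # patient-relative pairing window
n_perm_paired: 1000
n_perm_permanova: 9999
n_perm_plsda: 1000
k_range: [2, 3, 4, 5, 6]
contrasts_on: rarefied
seed: 1
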