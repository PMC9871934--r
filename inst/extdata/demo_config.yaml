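# Demo: end-to-end run on synthetic two-species data with planted truth.
#   Rscript inst/scripts/orthocell.R run --config demo_config.yaml --out demo_out
simulate:
  n_shared_types: 5
  n_specific_types: 1
  cells_per_type_per_condition:
    control: 100
    aneurysm: 100
  seed: 7
n_hvg: 2000
n_pcs: 30
resolution: 0.5
knn_k: 20
top_n_display: 5
top_n_xspecies: 50
do_tsne: false
seed: 7
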