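# example benchmark configuration for `graphburden benchmark --config ...`
paths:
  network: inst/extdata/example_network.tsv
  genes: inst/extdata/example_genes.txt
  counts: sim_out/counts.tsv          # e.g. from `graphburden simulate`
  pheno: sim_out/phenotype.csv
label_rule: pet
counting_mode: site
k: 10
inner_k: 10
ablate_gene: APOE
null_method: rewired
null_count: 100
master_seed: 42
out_dir: run1
gnn:
  n_message_layers: 2
  epochs: 200
  hidden_dim: 128
  aggregation: sum
  readout: mean
  n_seeds: 3
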