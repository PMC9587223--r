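# graphburden

Benchmarking graph neural networks for genotype-to-phenotype prediction on
patient-specific gene networks.

## The problem

For polygenic diseases, per-gene variant burdens are informative but so —
potentially — are the interactions between the affected genes. This package
implements a full benchmark asking whether protein–protein interaction
structure adds predictive value over tabular burdens in phenotype
prediction (the motivating setting is Alzheimer's disease, with amyloid-PET
positivity, PET-plus-diagnosis, and case/control labels):

* **Template extraction** — intersect a disease gene set with an
  interaction network (induced subgraph → largest connected component) and
  report graph statistics (density `2m/(n(n−1))`, diameter) and node loss.
* **Burden counting** — reduce VEP-annotated VCFs to per-gene missense
  burden counts (site or allele-dosage mode).
* **Patient-specific graphs** — one copy of the template per subject, with
  that subject's burdens as scalar node attributes and a binary label.
* **Models** — a graph-level message-passing neural network
  (`H' = relu(H W_self + AGG(H) W_nei + b)`, mean readout, fixed 2 layers /
  200 epochs / 3 seeds) versus logistic regression, linear & RBF SVMs, and
  a random forest on the same burdens without interactions, plus a
  single-gene (APOE) logistic baseline.
* **Null models** — "shuffled" (label-permuted) and "rewired"
  (degree-preserving double-edge-swap) template ensembles.
* **Statistics** — stratified 10-fold evaluation; one-sided t-tests versus
  the baseline mean AUC and versus AUC 0.5; paired model-vs-model tests;
  per-fold tests of original-vs-null AUCs with Benjamini–Hochberg
  correction across folds.

The real cohorts this design targets are access-restricted, so the package
ships a first-class synthetic cohort generator (Poisson burdens with
Gamma-distributed rates, a dominant APOE-like liability effect, optional
edge-aligned epistasis `beta_epi * x_u * x_v` over template edges, SUVR /
diagnosis / case-control phenotypes) that reproduces the structure every
pipeline stage assumes.

## Worked example

```r
library(graphburden)

# synthetic cohort: 300 subjects on a 29-gene scale-free template whose hub
# is the dominant-effect gene ("APOE")
tmpl <- default_template(29, seed = 3)
sim  <- simulate_cohort(sim_params(n_subjects = 300, template = tmpl,
                                   beta_main = 2, seed = 7))
labels <- label_pet(sim$pheno)       # SUVR >= 1.11 / 1.27 by tracer

ds <- build_graph_dataset(tmpl, sim$counts, labels, "example")
sp <- stratified_kfold(ds$labels, k = 5, seed = 1)$folds[[1]]

graph_stats(tmpl)
#> n=29 m=54 density=0.1330 diameter=4

train_gnn(ds, sp, gnn_config(epochs = 50, hidden_dim = 16, n_seeds = 1),
          seed = 1)$auc
#> [1] 0.6582418
apoe_baseline(sim$counts, ds$labels, sp)$auc
#> [1] 0.7340659
train_baseline(sim$counts, ds$labels, sp, "logreg", inner_k = 5, seed = 1)$auc
#> [1] 0.7406593
```

The single-gene baseline matches the full tabular model (and the
short-budget GNN trails slightly) — the expected outcome when one dominant
gene carries the liability signal: neither the remaining burdens nor the
interaction structure add information here. With
`beta_main = 0` and `beta_epi > 0` on template edges the ranking flips: the
GNN on the true template beats GNNs on rewired templates
(`run_benchmark(run_config(..., null_method = "rewired"))` reports per-fold
BH-adjusted p-values).

A full run — all six models, ablation arm without APOE, statistics,
null-model comparison, results written to disk — is one call:

```r
cfg <- run_config(template = tmpl, counts = sim$counts, labels = labels,
                  k = 10, null_method = "rewired", null_count = 100,
                  ablate_gene = "APOE", master_seed = 42, out_dir = "run1")
run <- run_benchmark(cfg)
```

`run1/` then contains `results.csv` (one row per dataset × model × fold),
`summary.csv` (mean ± sd per metric), `statistics.json` (the test battery),
`null_rewired.csv` (per-fold original vs null AUCs with raw and adjusted
p), `splits.json` and `manifest.json` (config hash and every seed —
rerunning an identical config reproduces all outputs exactly).

A command-line interface with subcommands (`simulate`, `build-network`,
`count`, `build-graphs`, `train`, `benchmark`, `nulltest`) is installed at
`system.file("cli", "graphburden", package = "graphburden")`; configs are
YAML with CLI overrides.

## Package layout

| Area | Files |
| --- | --- |
| Networks & statistics | `R/network.R` |
| Null models | `R/nullmodels.R` |
| VCF → burden counts | `R/genotype.R` |
| Labeling rules & graph datasets | `R/labeling.R`, `R/graphdataset.R` |
| Synthetic cohorts | `R/simulate.R` |
| GNN & baselines | `R/models.R`, `src/gnn.cpp`, `src/forest.cpp` |
| Splits, metrics, tests | `R/evaluation.R` |
| Orchestration & CLI | `R/pipeline.R`, `inst/cli/graphburden` |

The methods vignette (`vignettes/methods.Rmd`) documents the generative
model, protocol constants, numerical choices and the desk-scale settings
used by the acceptance suite.
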