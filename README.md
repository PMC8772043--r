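# dgrn — biomarker discovery from gene regulatory network rewiring

`dgrn` is an R package for case–control transcriptomics when a prior
regulatory network is available. Disease perturbs not just the expression of
individual genes but the regulatory wiring between them; this package finds
the *rewired* part of the network and mines it for diagnostic gene panels.

It is aimed at computational biologists who have (a) a background network —
a curated, condition-agnostic edge list of plausible regulations such as a
regulon database export — and (b) a genes × samples expression matrix with
a binary phenotype per sample (normal / disease).

## Method

Four stages, each an exported function, chained by `run_pipeline()`:

1. **Condition-specific networks** — `pc_prune()` deletes background edges
   whose endpoints are (conditionally) independent in one condition's data.
   Dependence is the binned plug-in mutual information
   `I(X;Y) = Σ_ij p(i,j) log[ p(i,j) / (p_x(i) p_y(j)) ]` (nats) and its
   conditional form `I(X;Y|Z)`; a path-consistency loop escalates the
   conditioning order over common neighbors, deleting an edge whenever some
   conditioning set drives the statistic below a threshold (default 0.03
   nats, identical in both conditions).
2. **Differential network (D-GRN)** — `build_dgrn()` takes genes whose
   connections differ between the two pruned networks, adds their
   neighbors, and tags every induced edge `common`, `normal_only` or
   `disease_only`.
3. **Modules** — `greedy_communities()` partitions the D-GRN by greedy
   agglomerative maximization of modularity `Q = Σ_i (e_ii − a_i²)`,
   returning the partition with maximal Q along the merge path.
4. **Biomarker panels** — `rfe_select()` runs recursive feature elimination
   driven by L2-regularized logistic regression (one gene removed per step,
   smallest standardized |coefficient| first), with stratified tenfold
   cross-validation choosing the smallest panel whose mean F1 matches the
   best. Panels are scored on held-out samples (`evaluate_panel()`: F1 and
   rank-statistic AUC) and against size-matched random gene sets
   (`random_panel_test()`, one-sided Wilcoxon signed-rank).

A linear-Gaussian structural-equation simulator with planted rewiring
(`make_instance()`) provides ground-truth instances for every stage;
`evaluate_recovery()` scores a run against the planted truth. The methods
vignette (`vignettes/dgrn-methods.Rmd`) documents the models, defaults and
their rationale.

## Worked example

```r
library(dgrn)

inst <- make_instance(seed = 42)          # 50 genes, 75 true edges, 20% rewired,
                                          # 50% spurious prior edges, 200 samples/condition
cfg  <- run_config(expression = inst$data, background = inst$background, seed = 42)
res  <- run_pipeline(cfg)
#> [load] 50 genes, 400 samples; background 50 nodes / 128 edges
#> [split] 240 training / 160 validation samples
#> [prune] normal GRN: 50 nodes, 75 edges
#> [prune] disease GRN: 49 nodes, 87 edges
#> [diffnet] D-GRN: 50 nodes (41 seeds), 100 edges
#> [modules] 7 modules, Q = 0.4052 (sizes: 8/8/8/8/8/6/4)
#> [select] M1: 8 -> 6 genes, validation F1 0.790, AUC 0.847
#> ...
#> [select] M2: 8 -> 6 genes, validation F1 0.866, AUC 0.929
#> [random] signed-rank p = 0.01562 over 7 modules

rec <- evaluate_recovery(res, inst$truth)
sprintf("normal edge-recovery F1: %.3f", rec$normal$f1)      # "0.893"
sprintf("rewired-edge recall:     %.3f", rec$rewired$recall) # "0.733"
sprintf("best panel AUC:          %.3f", rec$best_panel_auc) # "0.929"
```

Reading the numbers: pruning kept 75 of 128 prior edges in the normal
condition and recovered the planted normal network with F1 0.89; the D-GRN
caught 73% of the planted rewired edges; the best module panel separates
held-out disease from normal samples with AUC 0.93, and the seven module
panels jointly beat size-matched random gene sets (signed-rank p = 0.016).

File-based runs use the same stages: `read_edge_list()` /
`read_expression()` for inputs (TSV/CSV), `write_network()` (TSV/SIF),
`write_modules()` (GMT) and JSON metrics for outputs. A thin command-line
front end ships in `inst/cli/dgrn.R`:

```sh
Rscript inst/cli/dgrn.R simulate --out data/ --seed 7
Rscript inst/cli/dgrn.R run --background data/background.tsv \
    --expression data/expression.tsv --labels data/labels.tsv \
    --out run/ --seed 7
Rscript inst/cli/dgrn.R recover --run run/ --truth data/truth.json
```

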