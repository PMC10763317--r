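# graphlda

Transductive link prediction of lncRNA–disease associations (LDAs) on a
heterogeneous lncRNA / miRNA / disease graph, for computational biologists
who want to prioritize candidate disease lncRNAs from sparse association
catalogues.

## Method

The package assembles the block adjacency matrix

```
        [ S_ll    Z_ld    Z_lm  ]
  X  =  [ Z_ld'   S_dd    Z_md' ]
        [ Z_lm'   Z_md    S_mm  ]
```

where the `Z` blocks are binary interclass associations
(lncRNA–disease, lncRNA–miRNA, miRNA–disease) and the `S` blocks are
intraclass similarities: disease semantic similarity over an ontology DAG
(decayed ancestor contributions, `DS(d_i,d_j) = Σ_t (D_i(t)+D_j(t)) / (DV_i+DV_j)`
with decay `Δ = 0.5`) and lncRNA/miRNA functional similarity by best-match
averaging over their associated disease sets.

Nodes are encoded with a two-layer graph convolutional network
`H_{l+1} = σ(Ẽ^{-1/2}(X+I)Ẽ^{-1/2} · H_l · W_l)` on the row-normalized
feature matrix (embedding size 128). Each candidate pair `(lncRNA, disease)`
is then classified by a transformer encoder over the two-token sequence
`[z_lnc, z_dis]` — multi-head scaled dot-product attention, add & layer-norm,
position-wise feed-forward — followed by a sigmoid head, trained with binary
cross-entropy and Adam. Forward and backward passes are written in plain R
matrix algebra; the analytic gradients are verified against finite
differences in the test suite.

Evaluation follows the field's protocol: balanced negative sampling, a 20%
held-out test set, stratified fivefold cross-validation with held-out
positive edges *masked* out of the graph, and AUC / AUPR / ACC / F1 / MCC
reporting, plus ablation (graph-block and transformer-module toggles) and
GCN hyperparameter sweep harnesses. A seeded synthetic benchmark generator
with planted block structure makes every stage testable without downloads.

## Worked example

```r
library(graphlda)

# 1. simulate a benchmark with planted group structure
spec <- synthetic_preset("tiny", seed = 7)
bench <- generate_benchmark(spec, "bench_tiny")
data  <- load_benchmark("bench_tiny")

# 2. similarities + block adjacency
graph <- build_heterogeneous_graph(data)
graph
#> <het_graph> 12 lncRNAs + 10 diseases + 8 miRNAs = 30 nodes; 25 known LDAs

# 3. labeled pairs (positives + balanced negatives) and the CV protocol
labeled <- build_labeled_pairs(graph, seed = 1)
config  <- load_config(overrides = list(train = list(epochs = 50L)))
report  <- run_cross_validation(graph, labeled, config,
                                make_cv_plan(labeled, seed = 1))
report
#> <cv_report> 5 folds | mean AUC 0.7000, AUPR 0.7769 | test AUC 0.6400, AUPR 0.6978
```

The fold table (`report$folds`) carries AUC, AUPR, ACC, F1, MCC, precision
and recall per validation fold; `report$mean` averages them and
`report$test` is the one-shot evaluation on the 20% test split. On the
larger `small` preset (60/40/50 nodes, the standard benchmark) the default
configuration reaches a mean cross-validated AUC of about 0.80 with the
held-out edges masked, and chance level (AUC ≈ 0.5) on the structure-free
`null` preset — the package's negative control.

A command-line wrapper covering the whole pipeline
(`simulate`, `build-graph`, `train`, `evaluate`, `ablate`, `sweep`,
`predict`) is installed under `inst/cli/`:

```sh
Rscript inst/cli/graphlda simulate --preset small --seed 7 --out bench
Rscript inst/cli/graphlda evaluate --data bench --out results --seed 1 --repeats 1
Rscript inst/cli/graphlda predict --data bench --disease T017 --out ranking.tsv
```

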