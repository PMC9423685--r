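# ddifusion

Multitype drug–drug interaction (DDI) event prediction by deep fusion of
two complementary drug representations:

* a **feature channel** — a multilayer autoencoder over the concatenated
  Jaccard-similarity matrix built from binary drug descriptors (chemical
  substructure, target, enzyme), decoded by an inner product against the
  drug–drug similarity target;
* a **topology channel** — a graph convolutional network (GCN) over the
  known interaction graph.

Most DDI predictors use one source or the other; when two drugs are
co-administered the *type* of their interaction (one of C event classes,
e.g. "metabolism decreased") depends both on what the drugs are and on
where they sit in the interaction network, and either source alone wastes
the other. This package is for computational pharmacologists and method
developers who want a multitype DDI event predictor that fuses the two
sources *during* representation learning rather than after it.

## Model

Given binary descriptor views, each view is turned into a drug-by-drug
Jaccard similarity matrix `J(d_i, d_j) = |d_i ∩ d_j| / |d_i ∪ d_j|` and
the views are concatenated into the node feature matrix
`X = X_s ⊕ X_t ⊕ X_e`. The labeled interaction graph gives the
symmetrically normalized, self-looped adjacency
`Â = D̃^{-1/2}(A + I)D̃^{-1/2}`.

The two channels run in lockstep for L layers with tied widths:

```
H^(l) = ReLU(H^(l-1) W_e^(l) + b_e^(l))            feature channel, H^(0) = X
Z̃^(l-1) = (1 − α) Z^(l-1) + α H^(l-1)              delivery operation
Z^(l)  = ReLU(Â Z̃^(l-1) W^(l))                     topology channel, Z^(0) = X
```

The per-layer **delivery operation** injects feature information into the
graph propagation (α ∈ [0,1], default 0.5), which also counteracts the
oversmoothing that plain deep GCN stacks suffer. The two final embeddings
are fused per drug by a two-way attention softmax over scores
`w_z^i = qᵀ tanh(w Z^i + b)` (same `w`, `b`, `q` for both channels),
giving `E_i = α_z^i Z_i + α_h^i H_i` with `α_z^i + α_h^i = 1`.

Drug-pair vectors are built from rows of `E` with one of four combiners
(average, Hadamard, elementwise |difference|, concatenation) and mapped
by an affine softmax head to the C event classes. Training minimizes
`cross-entropy + λ · MSE(sigmoid(H Hᵀ), similarity target)` end to end
with Adam (learning rate 0.003, minibatches of 128 pairs, early stopping
on class-balanced validation cross-entropy, patience 20).

Evaluation utilities cover stratified fivefold pair cross-validation,
frequency-ranked class subsets, cold-start splits (Task A: known–new drug
pairs; Task B: new–new pairs), ablation variants (`no_ae`, `no_gcn`,
`no_att`, `no_delivery`) and the standard multiclass bundle
(ACC, micro-AUPR, micro-AUC, macro precision/recall/F1).

A synthetic-data module generates descriptor views and interaction tables
with planted community structure whose strength in the features and in
the topology is separately tunable, so the whole pipeline is testable
without any external download.

## Worked example

```r
library(ddifusion)

ds <- simulateDDIData(syntheticConfig(seed = 42))
ds
#> DDIDataset: 120 drugs, 3 views (substructure, target, enzyme), 1424 labeled pairs, 8 event classes
#>   ground-truth communities: 4

folds <- splitPairs(ds, seed = 42)                  # stratified 5-fold
ab <- runAblation(ds, "full", split = folds[[1]], seed = 42)
round(unlist(ab$metrics[c("acc", "auprMicro", "aucMicro",
                          "f1Macro", "preMacro", "recallMacro")]), 3)
#>         acc   auprMicro    aucMicro     f1Macro    preMacro recallMacro
#>       0.951       0.939       0.982       0.963       0.962       0.966

ab$fit
#> FusionFit (full): 120 drugs, 8 classes, layers {64, 32, 8}, alpha=0.50, combiner=average
#>   trained 44 epochs (best 24, val CE 0.7159)

round(unlist(ab$attention[c("meanAttZ", "meanAttH")]), 3)
#> meanAttZ meanAttH
#>    0.048    0.952
```

The dataset plants a strong community signal in both the descriptors and
the interaction graph; the model recovers the held-out event classes with
macro-F1 0.96 on this fold, and the attention weights show which channel
the trained model leaned on (here the feature channel).

There is also a command-line front end (`inst/scripts/ddifusion`) with
`simulate`, `prepare`, `train`, `evaluate`, `ablate`, `predict` and
`report` subcommands; every run directory receives the resolved
configuration, a plain-text log and a JSON-lines event log.

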