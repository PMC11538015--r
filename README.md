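# dualnetgo

Multi-label protein function prediction from heterogeneous protein-protein
interaction (PPI) evidence, by **selecting an effective subset of feature
matrices** instead of concatenating them all.

STRING distinguishes seven evidence channels for an interaction
(*neighborhood, fusion, cooccurence, coexpression, experimental, database,
textmining*), each defining its own network over the same proteins. These
networks differ in density, structure and noise, and pooling all of them
indiscriminately dilutes the informative ones. `dualnetgo` implements the
DualNetGO dual-network strategy for Gene Ontology (GO) term prediction:

* a **Classifier** — one ReLU projection MLP per candidate feature matrix
  (graph embeddings of the seven channel networks, a Pfam/subcellular
  attribute matrix, optional extras such as sequence embeddings) feeding a
  shared two-layer prediction head, trained with the **asymmetric loss**

  ASL = (1/NK) Σᵢₖ [ −y_ik (1−p_ik)^γ⁺ log p_ik − (1−y_ik) p_ik^γ⁻ log(1−p_ik) ],
  γ⁺ = 0, γ⁻ = 2;

* a **Selector** — a small surrogate MLP mapping a binary selection mask
  m ∈ {0,1}^|M| to the Classifier's validation loss; the absolute gradients
  of its output at an all-0.5 probe rank matrix importance.

Training alternates the two networks in three stages: random-mask
**exploration** (E1 epochs), gradient-guided **exploitation** over the
top-N_f subspace (E2 epochs), and **refinement** with the best recorded
mask m\* frozen (E3 epochs, early-stopped on validation Fmax). Evaluation
follows the CAFA conventions: Fmax over a threshold grid, micro/macro
AUPR, F1, Macro-F1 and subset accuracy, with a temporal (annotation-date)
train/validation/test split.

The package also ships a planted-signal synthetic generator — a feature
space in which a known pair of matrices carries the label signal — so the
entire selection machinery is testable end-to-end on one CPU with no
downloads.

## Worked example

```r
library(dualnetgo)

# a planted benchmark: 600 proteins, 8 candidate matrices, 2 informative
ds  <- generate_planted_dataset(synthetic_spec(seed = 1))
fit <- run_dual_training(ds$space, ds$labels, train_config(seed = 1))
fit
#> dualnet_fit
#>   m* = 01000010 ( planted2, planted7 )
#>   test:Fmax 0.5078 (tau* = 0.53)  m-AUPR 0.4827  M-AUPR 0.5478  M-F1 0.4565  F1 0.4771  acc 0.6083
which(fit$m_star == 1)   # the selected matrices
#> [1] 2 7
ds$planted               # the generator's informative pair
#> [1] 2 7
```

The printed line is the full test-split evaluation at the
validation-selected threshold: the selector identified exactly the two
informative matrices out of eight, and the resulting protein-centric Fmax
(0.51 here) is what the same Classifier trained with *all eight* matrices
always selected does not reach (about 0.37 on average over seeds — noise
matrices dilute the signal).

The file-based pipeline mirrors this through a command-line layer
(`inst/cli/dualnet`): `dualnet synth` writes edge lists, annotations and
attributes; `dualnet embed --backend {noembed,mlpae,transformerae}` caches
one feature matrix per channel; `dualnet train` runs the three stages and
writes `report.json` with all metrics, the mask and the per-epoch record;
`dualnet baseline naive` and `dualnet evaluate` complete the toolbox.

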