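# blockdti

Drug–target interaction (DTI) prediction in R, built around stacked gated
graph-neural-network blocks.

## The problem

Predicting whether a small molecule binds a protein is a screening problem:
given a compound library and a target, rank the candidates so that the true
binders surface early. `blockdti` frames DTI prediction as binary
classification of (drug, target) pairs and provides the full workflow —
featurization, encoding, training, evaluation under increasingly strict data
splits, virtual-screening metrics, and interpretability diagnostics — with no
external services and no pretrained downloads, so every stage runs and tests
offline.

## The model

**Drug branch.** A SMILES string is parsed (ChemmineR/OpenBabel) into a
heavy-atom graph; each atom carries a 64-dimensional indicator vector
(element one-hot over a 48-symbol vocabulary + other, formal charge, degree,
aromaticity, ring membership). The encoder stacks *blocks* of *N* GNN layers
(message passing `x_i' = σ(F₁(x_i) + F₂(Σ_{j∈N(i)} x_j))`, with attention-
weighted aggregation in GAT layers). Each block:

1. **expands** — its last layer doubles the output channels,
2. **refines** — a gated linear unit `GLU(h) = a ⊙ σ(b)` compresses the
   expansion back to C channels, added to the penultimate layer's output
   scaled by a factor *d* (feature enhancement), and
3. **gates** — GRU-style reset/update gates, shared across blocks, filter
   the block output against the block input:
   `R = σ(h_new W₁ʳ + h_prev W₂ʳ + bʳ)`, `Z` likewise,
   `h̃ = tanh(h_new W₁ʰ + R ⊙ (h_prev W₂ʰ) + bʰ)`,
   `h = (1−Z) ⊙ h_prev + Z ⊙ h̃`.

A channel-wise max over atoms reads out a permutation-invariant embedding.
The default architecture is an initial 3-layer block followed by L = 5
blocks of N = 2 layers, attention layers everywhere except a plain graph
convolution closing each block.

**Target branch.** Residues (21-letter alphabet) are embedded by a learned
21×30 lookup (any per-residue embedding matrix, e.g. from a protein language
model, can be substituted). Two pathways share these inputs: three stacked
same-padded 1D convolutions (windows 3/5/7, outputs combined multi-scale)
and three weighted graph convolutions over the residue contact graph,
`h_i' = σ(h_i W₁ + Σ_j (M_ij/√(d_i d_j)) h_j W₂)`, where `M` is the
contact-probability map. The pathways are projected, L2-normalized per
residue, summed, projected and max-pooled:
`T = maxpool((L2(T_seq W_s) + L2(T_graph W_g)) W_t)`.

**Head and training.** Concatenated embeddings pass a 3-layer MLP with a
sigmoid output; training is mini-batch Adam on binary cross-entropy with
best-on-validation model selection. Everything — initialization, shuffling,
dropout, undersampling — runs off one master seed on the package's own
reverse-mode autodiff tape (no deep-learning framework required).

**Around the model.** Random, unseen-entity and similarity-cluster splits
(ECFP4/Tanimoto for drugs, BLOSUM62 global-alignment identity for targets,
average-linkage clustering); AUROC/AUPR/ACC/PR/RE/F1; enrichment factor and
ROC enrichment for ranked libraries; a per-block node-feature diversity
metric (mean pairwise Euclidean distance) that detects over-smoothing; and
gradient-weighted per-atom attribution maps.

## Worked example

```r
library(blockdti)

# a self-contained dataset with a planted rule: a pair interacts iff the
# drug carries a CF3 motif AND the target contains a 4-residue motif
ds <- generate_dti_data(synthetic_spec(
  n_drugs = 300, n_targets = 100, n_pairs = 1000,
  pos_fraction = 0.5, label_noise = 0, seed = 1
))
sets <- split_pairs(ds$pairs, split_spec("random", c(0.7, 0.1, 0.2), seed = 1))

cfg <- dti_model_config(channels = 64, n_blocks = 2, n_layers = 2,
                        gnn_type = "gat_gcn")
model <- train_dti(ds, sets$train, sets$val, cfg,
                   train_config(max_epochs = 6, seed = 1), verbose = TRUE)
#> epoch 1: loss 0.6931, val AUROC 0.9612
#> epoch 2: loss 0.6177, val AUROC 0.9838
#> ...
#> epoch 6: loss 0.0488, val AUROC 1.0000

evaluate_predictions(predict(model, ds, sets$test), sets$test$label)
#> AUROC 1.0000 | AUPR 1.0000 | ACC 0.8400 | PR 0.7519 | RE 1.0000 | F1 0.8584
```

The test AUROC of 1.0 says the model ranks every held-out positive above
every negative — it recovered the planted conjunction (the clean rule is
separable). Accuracy and F1 at the fixed 0.5 threshold are lower only
because six epochs leave the scores miscalibrated around the cutoff, not
because any pair is mis-ranked.
Per-block interpretability:

```r
g <- ds$graphs[[sets$test$drug_id[1]]]
diversity_by_block(model, g)      # DS_G per block; > 0 means no collapse
grad_attribution(model, g, ds$records[[sets$test$target_id[1]]])
```

A command-line mirror of the workflow ships in `inst/cli/blockdti`
(subcommands `simulate`, `split`, `train`, `predict`, `rank`, `explain`,
`diversity`).

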