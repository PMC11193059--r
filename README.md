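# seqdta

Sequence-only protein–ligand binding-affinity prediction in R.

## What this package is for

Early-stage drug discovery needs fast estimates of how tightly a small
molecule binds a protein — the drug–target affinity (DTA), expressed as
−logKi, −logKd or −logIC50 (higher = tighter). Most accurate predictors
require a solved 3D structure, which the vast majority of known proteins
lack. `seqdta` implements a regressor that needs only one-dimensional
sequence inputs:

* the protein's amino-acid sequence,
* optionally, a binding-pocket mask over that sequence (the "v1"
  variant; without it the model runs as pocket-free "v2"),
* the ligand's SMILES string.

## The model

Sequences are label-encoded against fixed token dictionaries
(21 protein tokens, 53 SMILES tokens, index 0 = padding) and clipped or
zero-padded to fixed lengths (L_P = 1024, L_S = 256 at full scale). Each
stream then passes through:

1. **Dynamic word embedding** — token lookup to E = 128 dims, then 1D
   convolutions with kernels 1/3/5/7 (32/32/64/128 filters, "same"
   padding) concatenated to H = 256 channels per position, gated by a
   highway layer `x = g⊙f + (1−g)⊙ReLU(Wf+b)`, `g = σ(W_g f + b_g)`, and
   projected back to E. Each position's vector thus depends on its
   neighbourhood, not just its own token.
2. **Pocket fusion (v1)** — the pocket mask, embedded with the same
   weights, is added position-wise onto the protein stream.
3. **Split-head self-attention** — 6 layers, 8 heads of width 16: the
   feature axis is split into contiguous blocks, each head computes
   `softmax(Q_i K_iᵀ/√d_k) V_i` with bias-free square projections, heads
   are concatenated through an output projection; residual connections;
   padded positions are masked as keys.
4. **Interaction head** — the cross-attention map `α = P Sᵀ`
   (L_P × L_S) is average-pooled over the ligand axis into
   `β ∈ R^{L_P}` and regressed through FC layers 1024/256/64/1 with
   PReLU and dropout.

Training is mean-squared-error with a from-scratch decoupled-weight-decay
AdamW (β₁ = 0.9, β₂ = 0.999, α = 1e−4, ε = 1e−8), early stopping (cap 50
epochs, or a 3-epoch training-loss plateau below the validation loss),
10-fold cross-validation and ensemble-mean prediction. Evaluation
reports RMSE, MAE, SD (residual spread after linear recalibration),
concordance index and Pearson R.

Because no benchmark download is feasible offline, the package ships a
synthetic-data generator that plants a multiplicative pocket×ligand
signal — `affinity = base + w·(#motif in pocket)·(#token in SMILES) +
noise` — with decoy motifs outside the pocket, so pocket use (v1 vs v2)
and the cross-interaction stage are both testable end to end. See the
methods vignette (`vignettes/seqdta-methods.Rmd`) for every design
decision and the reduced problem sizes used in tests.

## Worked example

```r
library(seqdta)

# canonical label-encoding examples
encode_sequence("PTAPSD", protein_dictionary(), 6)$indices
#> [1] 13 17  1 13 16  3
encode_sequence("C(=O)CCC", smiles_dictionary(), 8)$indices
#> [1]  1  2 10  5  3  1  1  1

# synthetic corpus with a planted pocket-ligand interaction signal
ds <- generate_dataset(synthetic_spec(n_records = 200, noise_sd = 0.1, seed = 1))

# reduced-size v1 model: train on 160 records, evaluate on 40 held out
cfg <- dta_config(embed_dim = 16, kernel_sizes = c(1, 3), filter_counts = c(8, 8),
                  num_heads = 2, num_layers = 2, protein_length = 48,
                  smiles_length = 24, fc_hidden = 32)
model <- new_dta_model(cfg, seed = 1)
model <- train_dta(model, ds[1:160, ], epochs = 120, batch_size = 16,
                   lr = 1e-3, weight_decay = 1e-4, seed = 1)
metric_report(ds$affinity[161:200], predict(model, ds[161:200, ]))
#> Affinity prediction metrics (n = 40)
#>   RMSE 1.038  MAE 0.758  SD 0.832  CI 0.855  R 0.887
```

The held-out concordance index of 0.855 means that for 85.5% of
record pairs with genuinely different affinity, the model ranks them in
the right order — far above the ≈0.5 a label-permuted control achieves —
and the RMSE of about 1 log unit is dominated by records whose planted
signal is partially hidden by the pocket mask boundary. A shell
front-end with `generate`, `crossval`, `predict` and `evaluate`
subcommands is installed as `exec/seqdta`.

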