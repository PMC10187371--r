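# clclsa

Multi-omics disease classification when some subjects are missing whole
omics layers.

Cohorts profiled on several molecular layers — mRNA expression, DNA
methylation, miRNA expression — are rarely complete: assays fail, samples
run out, budgets cap. `clclsa` implements **CLCLSA** (cross-omics linked
embedding with contrastive learning and self-attention), a deep model that
uses *all* subjects, complete or not:

- **Self-attention gating.** Each omics block is gated twice before fusion:
  a per-feature sigmoid score `fatt_i = σ(f_i(x_i))` selects informative
  features, and a per-subject scalar score `matt_i = σ(g_i(x̂_i))` weights
  the whole block. Gated blocks are embedded into a shared latent dimension
  D and concatenated: `Z = [ẑ_1, …, ẑ_M]`.
- **Cross-omics completion.** For every ordered pair of layers an
  encoder–decoder bridge `h_ik = dec_i ∘ enc_k` learns to predict layer i's
  latent from layer k's, trained on subjects observed in both
  (`L_co = Σ_j Σ_{i≠k} ‖h_ik(ẑ_k) − ẑ_i‖²`). A missing latent is completed
  as the mean of the bridge predictions from the subject's observed layers —
  imputation happens in latent space, never on raw features.
- **Contrastive alignment.** Row-softmaxed latents of two layers form a
  D×D joint probability table P; the loss
  `L_cl = −Σ_{d,d'} P_{dd'} ln( P_{dd'} / (P_d^{α+1} P_{d'}^{α+1}) )`
  rewards high mutual information between layers (and, for α > 0, high
  per-layer entropy).
- **Objective.** `L = L_clf + λ_al·L_al + λ_co·L_co + λ_cl·L_cl`, with a
  confidence-tied auxiliary head per layer
  (`L_al = Σ_i (matt_i − conf_i)² + CE_i`). Training alternates per epoch
  between complete subjects (all components) and incomplete subjects
  (classification through bridge-completed latents).

Because the reference benchmark cohorts (ROSMAP, LGG, BRCA, KIPAN) are
external downloads, the package ships a linear-Gaussian synthetic
multi-omics generator with the exact structure the method assumes — a
class-structured shared latent factor observed by every view — plus
experiment harnesses for missing-rate sweeps, omics-combination ablations
and loss-component ablations. See `vignette("clclsa-methods")` for the
model, assumptions, and every open design choice.

The neural-network layer (linear/ReLU/dropout/batch-norm stacks, Adam,
reverse-mode gradients) is written in plain BLAS-backed R; every gradient
path, including the deliberate stop-gradients, is verified against finite
differences in the test suite.

## Worked example

```r
library(clclsa)

# 400 subjects, 3 omics layers, 3 classes; 40% of subjects are missing
# at least one layer
ds <- simulate_omics(sim_config(eta = 0.4, seed = 0))
sp <- split_dataset(ds, train_fraction = 0.7, seed = 0)

cfg <- clclsa_config(V = c(100, 100, 60), C = 3, D = 64,
                     weights = loss_weights(0.1, 0.1, 0.1), epochs = 300)
model <- train_clclsa(sp$train, cfg, seed = 0)
model
#> clclsa_model: M = 3 omics layers, D = 64 , C = 3 classes
#>   lambda (al, co, cl): 0.1, 0.1, 0.1; alpha = 9
#>   trained 300 epochs; final total loss 2966.29

compute_metrics(predict(model, sp$test), sp$test$labels)
#> ACC = 0.9583, WeightedF1 = 0.9585, MacroF1 = 0.9585  (n = 120)

# how well do the bridges reconstruct a held-out latent, versus imputing
# the per-dimension training mean?
latent_imputation_mse(model, sp$train, sp$test)
#>    bridge      mean
#> 0.0663019 0.2342382
```

The test accuracy sits near the generator's Bayes ceiling (about 0.97 at
the default class separation), and the bridge reconstruction error is
roughly a quarter of the mean-imputation baseline — the completion module
is doing real work in latent space.

Command-line equivalents (`simulate`, `train`, `predict`, `grid-search`,
`sweep`, `ablate-omics`, `ablate-components`) live behind a thin script:

```sh
Rscript inst/cli/clclsa simulate --config sim.yaml --out data/
Rscript inst/cli/clclsa train --config run.yaml --out run/
```

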