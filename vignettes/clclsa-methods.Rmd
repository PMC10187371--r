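---
title: "CLCLSA: model, training regime and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CLCLSA: model, training regime and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Multi-omics classification studies profile the same subjects on several
molecular layers — typically mRNA expression, DNA methylation and miRNA
expression — and ask a supervised question: disease versus control, tumour
grade, molecular subtype. In practice many subjects lack one or more layers
(assay cost, sample volume, QC failures). Discarding incomplete subjects
shrinks the cohort; imputing thousands of raw features per layer is
ill-posed. CLCLSA (cross-omics linked embedding with contrastive learning
and self-attention) instead completes missing layers *in a shared latent
space*, where each omics block has already been compressed to a common
dimension D.

## The model

For subject $j$ and omics layer $i$ with features $x_i^{(j)} \in
\mathbb{R}^{V_i}$:

1. **Feature-level self-attention.** A linear encoder $f_i$ scores every
   feature, $\mathrm{fatt}_i^{(j)} = \sigma(f_i(x_i^{(j)}))$, and the raw
   features are gated elementwise before embedding.
2. **Omics embedding.** $\hat{x}_i^{(j)} = \mathrm{emb}_i(x_i^{(j)} \odot
   \mathrm{fatt}_i^{(j)})$, where $\mathrm{emb}_i$ is linear → ReLU →
   dropout and maps into the shared dimension $D$ (identical for all
   layers).
3. **Omics-level self-attention.** A linear encoder $g_i: \mathbb{R}^D \to
   \mathbb{R}$ produces one scalar gate per subject per layer,
   $\mathrm{matt}_i^{(j)} = \sigma(g_i(\hat{x}_i^{(j)}))$, broadcast across
   the $D$ latent dimensions: $\hat{z}_i^{(j)} = \hat{x}_i^{(j)} \cdot
   \mathrm{matt}_i^{(j)}$. The scalar (rather than per-dimension) gate
   follows the published layer sizes, which give $g_i$ a single output.
4. **Fusion.** $Z^{(j)} = [\hat{z}_1^{(j)}, \dots, \hat{z}_M^{(j)}]$, a
   concatenation in fixed view order, feeds the final softmax classifier
   $c$. Each layer also has an auxiliary softmax head $c_i$ on its own
   latent.

**Cross-omics completion.** For every ordered pair $(i, k)$ a small
encoder–decoder bridge $h_{ik} = \mathrm{dec}_i \circ \mathrm{enc}_k$ maps
$D \to D$ through a bottleneck (default `D-64-BN-ReLU-32-ReLU-64-BN-ReLU-D`).
Bridges are fitted by the summed squared reconstruction error
$\sum_j \lVert h_{ik}(\hat z_k^{(j)}) - \hat z_i^{(j)} \rVert_2^2$
over subjects observed in *both* layers; at $M = 2$ the fully connected sum
reduces to the bi-view form. A missing latent is completed as the
unweighted mean of the bridge predictions from all observed source layers —
the symmetric choice, degrading gracefully to the single-source case.

**Contrastive alignment.** Latent rows of two layers are mapped to
probability vectors by row-softmax; their batch-averaged outer product,
symmetrized and renormalized, is read as a $D \times D$ joint probability
table $P$. The pair loss
$$
L_{cl} = -\sum_{d,d'} P_{dd'} \,
  \ln \frac{P_{dd'}}{P_d^{\alpha+1} \cdot P_{d'}^{\alpha+1}}
$$
is minus the mutual information between the two views' latent dimensions at
$\alpha = 0$, with an additional marginal-entropy reward for $\alpha > 0$.
The total sums all ordered pairs over jointly observed subjects.

**Objective.** $L = L_{clf} + \lambda_{al} L_{al} + \lambda_{co} L_{co} +
\lambda_{cl} L_{cl}$, where $L_{clf}$ is summed cross-entropy of the final
head and $L_{al} = \sum_i \big[ (\mathrm{matt}_i - \mathrm{conf}_i)^2 +
\mathrm{CE}(c_i) \big]$ ties the omics gate to the auxiliary head's
confidence. All published tables use these names; all losses are sums over
subjects, not means.

## Training regime

Each epoch runs two full-batch Adam steps:

1. **Complete subjects** optimize everything: both attention levels, the
   embeddings, both classifier heads, all $M(M-1)$ bridges and the
   contrastive alignment.
2. **Incomplete subjects** have missing latents completed through the
   bridges (eval-mode batch norm, i.e. running statistics) and contribute
   to $L_{clf}$ and $L_{al}$ (observed layers) only.

Defaults follow the published recipe: Adam at learning rate $10^{-4}$, up
to 2500 epochs, full batch, dropout 0.5 in the embedding stacks. With a
complete training mask $\lambda_{co}$ is forced to 0 and the bridges are
never updated.

Three gradient-flow rules matter and are deliberate:

* the reconstruction **targets** $\hat z_i$ are treated as constants inside
  $L_{co}$ (otherwise the encoders can collapse all latents onto a single
  point, the trivial solution the bridge design is meant to avoid);
* the **confidence** $\mathrm{conf}_i$ (the auxiliary head's true-class
  probability, TCP; max-softmax is a config alternative) is a constant in
  the squared gate term, so the gate chases the confidence and not vice
  versa;
* classification gradients flow **through** imputed latents into the
  bridges and onward into the observed source encoders, end-to-end.

All three, plus every other gradient path, are verified against central
finite differences in the test suite (detached paths are compared against
detach-aware oracles).

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `D` | 64 | shared latent dimension (per layer) |
| `lambda_al, lambda_co, lambda_cl` | 0.1 each | loss weights; canonical grid `{0, 0.01, 0.02, 0.05, 0.1, 1}` |
| `alpha` | 9 | entropy/MI balance in the contrastive loss; the value used by the dual-prediction loss this objective adopts, exposed because the source publication does not print its own |
| `dropout` | 0.5 | embedding-stack dropout |
| `lr`, `epochs` | 1e-4, 2500 | Adam rate and epoch cap |
| `lr_decay_every`, `lr_decay_factor` | 500, 0.2 | stepwise decay (the source states only that decay is used; the schedule is config-exposed) |
| `epsilon` | 1e-8 | log floor; avoids $-\infty$ on sparse joint tables |

Weight initialization is fan-in uniform, seed-controlled. Batch norm uses
batch statistics in training and running statistics at imputation and
evaluation; with full-batch training these coincide with the published
regime.

## The synthetic generator

Real benchmark cohorts (ROSMAP, LGG, BRCA, KIPAN) are external downloads
and are out of scope; the generator provides data with exactly the
structure the method assumes. Subjects draw a class-structured shared
latent $u^{(j)} \sim N(\mu_{y_j}, I_q)$ and every view observes it
linearly: $x_i^{(j)} = A_i u^{(j)} + \varepsilon$, $\varepsilon \sim N(0,
\sigma^2)$. Consequently (i) classes are separable from the fused
representation and (ii) any view is linearly predictable from any other —
the premise of cross-omics completion, checkable with
`cross_view_predictability()`.

Defaults: $N = 400$, $M = 3$, $C = 3$, $V = (100, 100, 60)$, $q = 8$,
$\sigma = 0.5$. Where the structure left free choices: class means sit at
$\Delta \cdot e_c$ with $\Delta = 3$ — about three within-class standard
deviations, i.e. clearly but not trivially separated at the default noise
(the Bayes accuracy of the latent itself is about 0.97); loadings have
standard deviation $1/\sqrt{q}$ so features have unit-order variance.
Balanced classes use largest-remainder apportionment (exact to one
subject); imbalance and an elementwise `tanh` nonlinearity are exposed but
off by default.

What the generator does **not** emulate: count-distributed expression,
beta-valued methylation, feature correlation structure beyond the shared
factor, batch effects. Passing tests validate the *mechanism* — gating,
completion, alignment, optimization — not biological realism, and say
nothing about performance on real cohorts.

One property of this design is worth stating plainly: because every view
carries full-rank loadings on the shared latent ($V_i \ge q$), any single
observed view already determines the class. Imputation therefore recovers
latents very accurately (bridge reconstruction error is several times
smaller than a mean-imputation baseline) but classification accuracy is
nearly indifferent to *how* missing blocks are filled — an intrinsically
redundant regime, unlike real cohorts where layers carry complementary
signal.

## Numerical choices and degenerate inputs

* Logs are floored at `epsilon` in every loss; batch-norm variances are
  clamped at zero against floating-point cancellation.
* Softmax and row-softmax subtract row maxima before exponentiation.
* A contrastive pair with no jointly observed subjects contributes zero
  with a warning; single-view models skip bridges and the contrastive term
  entirely.
* Ties in `grid_search` are broken by mean F1, then by the smaller
  $\lambda$ sum (the less-regularized-is-simpler convention).
* `make_missing_mask` draws the number of dropped layers per incomplete
  subject uniformly from $\{1, \dots, M-1\}$, then the layers uniformly
  without replacement — the least-informative pattern, since the source
  does not state one; exactly `round(eta * N)` subjects are incomplete and
  every subject keeps at least one layer.
* Train/test splits are seed-controlled stratified random splits (the
  original protocol's exact indices are not published).

## Problem sizes used in the shipped experiments

The test suite and the acceptance script run the synthetic benchmark at
$N = 400$ with 300 training epochs, a missing-rate grid
$\{0, 0.2, 0.4, 0.6, 0.8\}$ for the degradation sweep (3 seeds), 5 seeds
for the imputation study at $\eta = 0.4$ and for the component ablation at
$\eta = 0.3$. These sizes are the package's chosen benchmark scale: large
enough that accuracies are stable to a few percent, small enough to run
routinely. The full 2500-epoch schedule remains the training default for
real use.

## Known limitations

* Full-batch training only by default; mini-batching is exposed but the
  published batch sizes equal the training-set sizes.
* No early stopping (the published regime trains to a fixed cap).
* The contrastive table reads latent *dimensions* as categories; with
  $D \gg N$ the table is sparse and the loss noisy.
* No GPU path; the hand-written engine is plain BLAS-backed R, adequate at
  the published layer sizes but not for much wider networks.
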