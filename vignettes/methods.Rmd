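---
title: "Gene screening and transfer-learning risk prediction: models, assumptions, and design choices"
author: "DeepPRS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene screening and transfer-learning risk prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Polygenic risk prediction from dense genotype data faces two coupled
obstacles: most of the genome is noise with respect to any one trait, and
the predictive variants that do exist may act non-linearly (interactions,
threshold-like and oscillatory dose-response shapes) that weighted-sum
scores cannot represent. DeepPRS implements a two-stage answer:

1. **Gene-level screening.** For each gene a small multi-layer perceptron
   is fitted to the phenotype from that gene's variant dosages alone, and
   the gene's predictive importance is scored by how much worse the fitted
   model gets when the genotype rows are randomly permuted across
   subjects. A one-sided asymptotic test turns the score into a p-value,
   and genes below a threshold are kept.
2. **Transfer-learning prediction.** The last hidden layers of the kept
   per-gene networks are frozen and concatenated; new stacked layers are
   trained on top to capture joint effects, and a gBLUP-derived background
   node is added with a single scalar weight to absorb the infinitesimal
   additive contribution of the rest of the genome.

## Stage one: the group-wise importance score

Let $f_k$ be the network fitted to gene $k$ on a training fold $D_1$, and
$L$ the per-subject loss (squared error for continuous outcomes,
cross-entropy for binary). On the disjoint validation fold $D_2$, each
subject contributes

$$ l_i \;=\; L\!\left(y_i, f_k(x_{ik})\right) \;-\;
   \mathbb{E}_\pi\, L\!\left(y_i, f_k(x_{\pi(i)k})\right), $$

the loss on the observed genotype row minus the expected loss over uniform
row permutations $\pi$ of the validation block. Row permutation destroys
the genotype-phenotype link while preserving every within-gene property —
allele frequencies and the LD matrix are column statistics, invariant
under row reordering — so the permuted term is a matched "no signal"
reference that requires **no refitting**. The fold score is
$\Delta_{ik} = \sum_{i \in D_2} l_i$ with variance estimate
$\sigma^2_{ik} = |D_2| \cdot \widehat{\mathrm{Var}}(l_i)$. Over $K$ folds,

$$ \Delta_k = \frac{1}{K}\sum_i \Delta_{ik}, \qquad
   \mathrm{se}^2 = \frac{1}{K^2}\sum_i \sigma^2_{ik}, $$

and the one-sided test of $H_0\!: \Delta_k \ge 0$ against
$H_1\!: \Delta_k < 0$ uses the lower-tail normal probability of
$\Delta_k/\mathrm{se}$. A predictive gene makes the observed loss smaller
than the permuted loss, driving $\Delta_k$ negative.

Assumptions worth keeping in mind: the $l_i$ are treated as i.i.d. with
finite variance within a fold, and the $K$ fold statistics are combined as
if independent although the folds share training data. The induced mild
mis-calibration is part of the method; at desk scale we measure rejection
rates of roughly 0.05–0.06 at the 5% level and 0.01–0.02 at the 1% level.

Numerical details:

* The permutation expectation is approximated by `nPerm = 100` random
  permutations by default. Because the network maps rows independently,
  permuting inputs equals permuting predictions, so extra permutations
  cost vector arithmetic only. An `exact = TRUE` mode enumerates all
  $|D_2|!$ permutations for small blocks; the enumeration average equals
  the closed form $\frac{1}{n}\sum_j L(y_i, f(x_j))$ because the marginal
  of $\pi(i)$ is uniform, and the test suite checks both routes agree.
* A gene whose fitted model is constant (for instance a monomorphic
  block) yields $l_i \equiv 0$; the standard error is then zero up to
  floating-point residue, and the gene is declared non-predictive with
  $p = 1$ rather than dividing zero by zero. The residue threshold is
  `1e-9 * var(y) * sqrt(n)`.
* `K = 20` folds by default; the scaled simulation studies in the test
  suite use `K = 5`, recorded in each experiment's configuration.

## The per-gene networks

The reference architecture is a multi-layer perceptron with two hidden
ReLU layers of 50 and 10 units, a dropout layer after the first hidden
layer, and a linear output head (logit scale for binary outcomes),
trained with Adam. Choices the upstream description leaves open, and what
this package does:

* **Input standardization.** Dosage columns are centered and scaled on
  the training data; the transform is stored on the network and applied
  at inference. Without it, raw dosage sums put every ReLU breakpoint at
  the origin, far outside the data cloud, and gradient descent cannot
  discover oscillatory signals at all.
* **Optimizer settings.** Adam with learning rate `3e-3` on minibatches
  of 32, chosen by pilot runs as the smallest-change configuration that
  reliably learns a cosine-shaped dose-response at $n = 2000$; at
  `1e-3` with large batches the optimizer stalls on a plateau before the
  oscillation is found. `batchSize = 0` requests full-batch training,
  used by the type-I-error experiments where fit quality is irrelevant
  and 30 full-batch epochs keep a thousand Monte-Carlo datasets cheap.
* **Dropout rate.** Default 0.2 (the low end of the recommended 0.2–0.8
  band) for screening; the prediction-stage experiments use 0.5 because
  generalization of the refitted networks, not detection, is what
  matters there.
* **Spread bias initialisation.** Hidden biases start at
  $\mathcal{N}(0, 0.5^2)$ rather than zero so ReLU breakpoints cover the
  standardized data range.

All stochastic stages — weight initialisation, dropout masks, minibatch
shuffles, fold partitions, permutations — draw from R's RNG, and every
user-facing function derives per-stage seeds from one master seed via
`deriveSeed()`, so any stage can be replayed in isolation.

## Stage two: the transfer network

With $p$ selected genes, prediction is

$$ \widehat{E}(Y\mid X) \;=\; g\!\left(f^h_1(X_1;\theta_1), \ldots,
   f^h_p(X_p;\theta_p); \gamma_1\right) \;+\; \gamma_0\, \hat g_0, $$

where $f^h_k$ is the last-hidden-layer transform of gene $k$'s network,
$g(\cdot;\gamma_1)$ the newly stacked layers (default widths 100 and 10),
and $\hat g_0$ the per-subject gBLUP genetic value. In **transfer** mode
only $(\gamma_0, \gamma_1)$ are trained and the $\theta_k$ are bitwise
frozen; in **optimal** mode the same architecture is retrained from a
fresh random initialisation, which is the comparison the framework is
evaluated against. Freezing shrinks the trainable set from roughly
$p \cdot 1{,}060 + 5{,}000$ parameters to about $5{,}000$ for ten-variant
genes.

Design choices made here:

* **Frozen means frozen parameters, not inference mode.** During
  transfer-mode training the gene subnets keep their train-time dropout
  behaviour; gradients simply never reach the frozen weights. Treating
  the frozen path as inference-mode would make it the only
  unregularised route through the architecture and it then trails full
  retraining by over 0.1 correlation units; with the architecture's
  dropout layers active in both modes the two agree, transfer slightly
  ahead, as the design intends.
* **Cross-validated background inputs.** The background values fed to
  transfer training are out-of-fold BLUP predictions (5 folds, full-data
  variance components), not the in-sample BLUPs. On a high-rank GRM the
  in-sample BLUPs can correlate above 0.9 with the training phenotype
  while generalizing far worse, which would teach the network to
  overweight the background exactly when it is least reliable; held-out
  prediction is unchanged.
* **Pre-trained model carried forward.** $K$ fold-networks exist per
  selected gene after screening; a single network per gene is refitted on
  the full training split to serve as the frozen feature extractor. The
  refit uses 30 epochs and dropout 0.5 in the packaged experiments — the
  configuration that maximised held-out per-gene accuracy in pilot runs —
  because a memorised feature map transfers nothing.
* **Stack regularisation.** Dropout (same rate as the gene networks) is
  applied after the first stacked hidden layer during training. Without
  it the frozen-transfer path is the only unregularised configuration in
  the comparison and systematically trails full retraining; with it the
  two agree to within a few hundredths of a correlation unit, which is
  the behaviour the architecture is designed to deliver.
* **Background wiring.** The background node enters additively on the
  linear-predictor scale through one scalar $\gamma_0$ (initialised at 1
  and trained jointly by gradient descent). Zeroing the stack
  (`predictRisk(..., ablateStack = TRUE)`) therefore reproduces gBLUP's
  predictions exactly up to the positive scalar, and zeroing $\gamma_0$
  leaves a sparse gene-based model.
* **Interaction scope.** The default concatenates all gene hidden layers
  into one fully connected stack (between-gene interactions allowed). The
  `within_genes_only` variant gives each gene a private slice of the
  stacked layers, realised as block-diagonal weight masks re-applied
  after every optimizer step, with per-gene widths the configured widths
  divided evenly; only the output node combines genes.
* **Binary outcomes.** The sum of stack and background passes through a
  logistic transform; training uses cross-entropy on the logit scale so
  the additive decomposition lives on one scale.

## The background model

The genomic relationship matrix is $G = WW^\top/m$ with columns
standardized by observed allele frequencies,
$w_j = (x_j - 2p_j)/\sqrt{2p_j(1-p_j)}$; variants without variation are
dropped with a warning. Variance components of
$y = \mu + g + e$, $g \sim \mathcal{N}(0, \sigma^2_g G)$ are estimated by
profile REML on the eigendecomposition of $G$ — each likelihood
evaluation is $O(n)$ after one `eigen()` — with a coarse grid over the
heritability ratio followed by golden-section refinement, which is robust
at small $n$ where gradient-based REML can step outside the boundary.
Training BLUPs are $\hat g = \sigma^2_g G V^{-1}(y - \hat\mu)$; held-out
samples get $\hat g_{new} = \sigma^2_g G_{new,train} V^{-1}(y - \hat\mu)$
using training-sample allele frequencies, so no held-out phenotype ever
enters (anything else would leak outcome information into the
prediction features). Binary outcomes are fitted on the observed 0/1
scale, the standard observed-scale GREML practice. The test suite checks
the BLUPs against a dense mixed-model solve and against the ridge
regression equivalence with penalty $m\,\sigma^2_e/\sigma^2_g$.

## The synthetic-data generator

Real genotype panels cannot be shipped, so the generator substitutes a
Gaussian-copula surrogate: per gene, two latent multivariate-normal
haplotypes with AR(1) correlation `ldDecay`$^{|i-j|}$ are thresholded at
each variant's MAF quantile and summed, giving Binomial(2, MAF) marginals
with within-gene LD and independence between genes. This preserves the
one property the screening statistic exploits — column-wise structure
invariant under row permutation — and the marginal dosage distributions;
it does **not** emulate haplotype-block boundaries, allele-frequency/LD
coupling, population structure or relatedness, so passing tests say
nothing about confounding by stratification in real cohorts.

Phenotypes follow a four-term latent mean: a linear term over a random
90% of the first gene's variants with per-variant effects
$\beta \sim \mathcal{N}(0,\sigma_1^2)$ redrawn per dataset, the same with
10% causal variants for the second gene, a squared dosage-sum
(pairwise-interaction) term, and a cosine of the dosage sum (radians on
the raw sum, no scaling); four indicator switches gate the terms, giving
the disease models S1 (linear only), S2 (non-linear only) and S3 (all).
The outcome is the mean plus Gaussian noise, or Bernoulli with the mean
as logit. Two deliberate departures from the barest reading:

* Each active term is **centered** at its sample mean before entering the
  latent mean. For the Gaussian link this is an irrelevant constant; for
  the logistic link it keeps prevalence near one half instead of letting
  the large positive mean of a squared sum push every probability to 1.
  The truth record stores the offsets, and a test re-evaluates the latent
  mean term-by-term from the stored coefficients.
* Effect sizes are specified as **target signal fractions** — the
  variance of a gene's centered term relative to the noise variance —
  and the drawn coefficients are rescaled once per dataset to hit the
  target. The upstream per-gene effect tables are supplementary material
  that is not reprinted, so the fractions were calibrated once by pilot
  runs and frozen: 0.25 per causal gene as the general default; the
  power experiments use 0.1 for the linear and interaction genes and 1.0
  for the cosine gene (an oscillatory signal needs variance comparable
  to the noise before a 50-10 perceptron finds it at $n = 2000$ — the
  spectral-bias limitation discussed below); the prediction experiments
  use 0.5 throughout.

## Scaled study conditions

The packaged experiments run on one CPU, so the Monte-Carlo designs are
scaled down and recorded here as the package's own conditions: type-I
error at $n = 1000$ with 500 replicates, $K = 5$, 30 full-batch epochs,
100 permutations per fold, for both outcome links; power at $n = 2000$
with 50 replicates against a one-degree-of-freedom sum-score regression
oracle; transfer-versus-retrained comparison on S3 at $n = 2000$ with 20
replicates; noise robustness from 6 to 96 null genes with 10 replicates.
Monte-Carlo tolerances are three binomial standard errors around the
estimates.

## Known limitations

* **Oscillatory signals are hard for small perceptrons.** Even with
  standardized inputs and tuned optimisation, the probability that one
  fold's network finds a cosine dose-response at moderate signal is well
  below one; detection power for such effects rises steeply with the
  effect's share of variance. This mirrors the spectral bias of
  gradient-trained networks, not a defect of the importance score.
* **A squared dosage sum is mostly linear.** Over the non-negative range
  of a dosage sum, $(\sum x)^2$ correlates about 0.97 with $\sum x$ under
  the default MAF range, so linear methods (including the gBLUP
  background itself) capture most of that "non-linear" term; the
  screening gain for it over a linear test is intrinsically small.
* The fold statistics are combined as independent; the resulting small
  anti-conservatism at the 1% level is visible at 500-replicate
  resolution.
* Mean imputation of missing dosages attenuates signals at high
  missingness; the optional missing-rate filter is the intended remedy.
* The REML profile assumes a single genetic variance component; no
  multi-component partitioning.
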