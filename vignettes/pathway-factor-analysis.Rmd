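---
title: "Pathway-constrained probabilistic factor analysis: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-constrained probabilistic factor analysis: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathfact)
```

## The problem

Bulk multi-omics cohorts — matched transcriptomics and proteomics profiles of
the same samples — are usually small (tens of samples) and high-dimensional
(thousands of markers). Classical factor analysis compresses such data into a
few latent factors, but the factors live in an arbitrary rotation of marker
space and are hard to interpret; pathway-level methods are interpretable but
typically single-modality. `pathfact` combines the two ideas: samples are
represented by low-dimensional loadings that act through *pathways* — named
gene sets from collections such as MSigDB Hallmark — and both modalities are
reconstructed jointly from the same pathway-level representation.

## The model

For a modality $x$ with $m_x$ markers and $n$ shared samples, let
$Y_x \in \mathbb{R}^{m_x \times n}$ be the (normalized) observation matrix and
$C_x \in \{0,1\}^{m_x \times p}$ the binary pathway membership mask over $p$
pathways ($C_{m,q} = 1$ iff marker $m$ belongs to pathway $q$). The model is

$$ Y_x \sim \mathcal{N}\!\left(c_x\, C_x U B,\; \mathrm{diag}(\sigma_x^2)\right)
   \quad\text{entrywise,} $$

with shared parameters across modalities:

* $U \in \mathbb{R}_{\ge 0}^{p \times k}$ — non-negative pathway-to-latent
  weights; row $q$ says which latent factors drive pathway $q$;
* $B \in \mathbb{R}^{k \times n}$ — per-sample loadings, the low-dimensional
  representation;
* $\sigma_x \in \mathbb{R}_+^{m_x}$ — *per-marker* noise standard deviations,
  learned, so noisy markers are automatically down-weighted (marker noise is
  strongly heteroscedastic in real cohorts, within and across modalities);
* $c_x$ — a free scalar per modality absorbing normalization inconsistencies
  between assays.

The interpretable output is the pathway activity matrix $P = U B$
($p \times n$): per-sample pathway abundances, directly usable for downstream
association testing without post-hoc gene-set enrichment.

Entrywise Gaussian automatic-relevance-determination (ARD) priors provide
sparsity and model selection:

$$ U_{q,j} \sim \mathcal{N}(0, \Lambda_{q,j}^{-1}), \qquad
   B_{j,\cdot} \sim \mathcal{N}(0, \delta_j^{-1} I_n), $$

with every precision $\Lambda_{q,j}$ and $\delta_j$ optimized rather than
fixed, so no sparsity level or regularization strength needs to be chosen a
priori. A multimodal fit simply multiplies the two modality likelihoods, which
share $U$ and $B$.

## Inference

Parameters are fit by maximum a posteriori estimation with alternating damped
Newton steps (ALS): the objective is quadratic in each of $U$ and $B$ at the
other held fixed. With $C_{x,\sigma} = \mathrm{diag}(\sigma_x^{-2}) C_x$, the
B-Hessian factorizes as $(\sum_x c_x^2 U^\top C_{x,\sigma}^\top C_x U +
\mathrm{diag}(\delta)) \otimes I_n$, so each sample column updates through one
$k \times k$ solve; the U-Hessian is a dense $pk \times pk$ matrix
($\sum_x c_x^2\, (B B^\top) \otimes (C_{x,\sigma}^\top C_x) +
\mathrm{diag}(\mathrm{vec}\,\Lambda)$ under the column-stacking vec
convention), inverted once per iteration — tractable because $p$ is hundreds,
not thousands. Odd iterations update $U$, even iterations $B$.

Hyperparameters are optimized by maximizing a Laplace approximation of their
marginal likelihood at the current MAP point, with the Hessian taken
block-diagonal in $U$ and $B$. The resulting fixed-point updates,

$$ \Lambda_{q,j} \leftarrow \frac{1 - \Lambda_{q,j} [H_U^{-1}]_{(q,j),(q,j)}}{U_{q,j}^2},
\qquad
\delta_j \leftarrow \frac{n\,(1 - \delta_j [A_B^{-1}]_{jj})}{\sum_n B_{j,n}^2},
\qquad
\sigma_m^2 \leftarrow \frac{\sum_n r_{m,n}^2}{d}, $$

consume exactly the Hessian factors the Newton steps already computed (the
package memoizes one Cholesky factorization per factor per iteration and
asserts the sharing by call counting), so ARD costs essentially nothing on top
of ALS. They run every iteration from the start. The scale factors $c_x$ have
a closed-form weighted-least-squares update
$c_x \leftarrow \langle Y_x, R_x\rangle_w / \langle R_x, R_x\rangle_w$ with
$R_x = C_x U B$ and weights $\sigma_{x,m}^{-2}$.

### Tunable parameters

All knobs live in `fit_control()`; the fit is otherwise hyperparameter-free:

| parameter | default | meaning |
|---|---|---|
| `k` | 10 | latent dimensions; surplus latents are shrunk by ARD, so generous values are safe |
| `step_size` | 0.1 | Newton damping $\gamma \in (0,1]$; 1 is the exact blockwise minimizer, 0.1 is a robust default |
| `n_iter` | 500 | outer iterations; convergence typically needs tens to a few hundred |
| `rel_tol` | 1e-6 | relative objective change declaring convergence |
| `prec_min`, `prec_max` | 1e-6, 1e12 | clamps on $\Lambda, \delta$; `prec_max` marks pruned entries/latents and keeps the linear algebra finite |
| `sigma_floor` | 1e-8 | lower bound on noise variances (zero-residual guard) |
| `init_precision_log_range` | (-4, 4) | decade range of the log-spaced initial precisions along the latents |
| `diagonal_U` | FALSE | use only the diagonal of the U-Hessian when $pk$ is large ($O(pk)$ instead of $O(p^3k^3)$) |
| `dof_mode` | "sbl" | denominator of the $\sigma^2$ update (below) |

### Numerical choices

* **$\sigma^2$ degrees of freedom.** The literal textbook form of the noise
  denominator, $n - p + \mathrm{tr}(\delta A_B^{-1})$, can turn negative
  whenever $p > n$ — common in pathway models. The default `dof_mode = "sbl"`
  uses the sparse-Bayesian-learning effective degrees of freedom
  $d = n - k + \mathrm{tr}(\mathrm{diag}(\delta) A_B^{-1})$; both modes clamp
  $d \ge 1$ so variances stay positive.
* **Prune guards.** A precision update with numerator
  $1 - \text{prec}\cdot[H^{-1}]_{jj} \le 0$, or a $0/0$ ratio
  ($U_{q,j} = 0$, or a zero-energy loading row), signals no evidence for the
  entry and sets the precision to `prec_max` (prune) rather than `prec_min`.
* **Projected U update.** The non-negativity constraint on $U$ makes the
  naively clamped joint Newton step (`solve`, then zero out negatives)
  a *non*-descent direction whenever clamping is active, because the free
  coordinates' step assumes the clamped ones move. `update_U()` therefore
  freezes coordinates sitting at zero with an inward gradient, solves the
  Newton system on the remaining free set (two-metric projection), and halves
  the step — down to a null step — while the clamped candidate would increase
  the objective. When no constraint is active this is exactly the plain
  damped Newton step, and the fit's objective trace is monotone at frozen
  hyperparameters.
* **Initialization.** $U = 0$; $B$ from the $k$-truncated SVD of the first
  modality, rows scaled by their singular values so the loadings carry the
  data scale, and each row's arbitrary SVD sign oriented so the implied
  pathway-weight direction has non-negative net mass — a misoriented dominant
  row would otherwise be clamped to a zero $U$ column at the first projected
  step and permanently pruned. Initial precisions are log-spaced over
  `init_precision_log_range` along the latents; noise starts at 1, scales
  at 1.
* **Linear algebra.** All Hessian solves go through Cholesky factorizations:
  near the ARD clamps the factors become extremely ill-conditioned while
  still positive definite, and triangular solves remain stable where a
  generic `solve()` would report singularity. A genuinely non-PD factor
  raises an error.
* **Degenerate inputs.** Markers in no pathway (all-zero mask rows) are legal:
  their rows are explained entirely by noise. Empty pathways are kept (with a
  warning) so pathway indices stay aligned across modalities. `k` larger than
  a data dimension is allowed with a warning; ARD handles the surplus.

## Preprocessing

`normalize_matrix()` implements the standard chain that makes raw counts or
intensities approximately Gaussian, in this order: counts-per-million per
sample, $\log(1+x)$, a per-sample rank-based inverse-normal transform, and
per-marker z-scoring. The inverse-normal transform maps the value of rank $r$
(average ranks for ties) to $\Phi^{-1}((r - 0.5)/m)$; the plotting position
and tie rule are our choice — the goal is only per-sample approximate
normality, and any order-preserving variant would do. Z-scoring uses the
$n-1$ denominator and zeroes zero-variance rows instead of dividing by zero.
Inputs are assumed complete; missing values are a hard error (upstream QC and
imputation are out of scope).

## The synthetic benchmark

`simulate_truth()` / `simulate_dataset()` generate data emulating a
Hallmark-scale two-modality design:

* 50 pathways, each assigned (round-robin, then shuffled) to one of 8 process
  categories; the binary assignment matrix is the ground-truth $U$. A config
  switch can weight the memberships by positive draws for harder recovery
  tests.
* An RNA marker universe of 2000 markers; each pathway draws 200 of them
  (overlaps allowed), approximating Hallmark set sizes at desk scale.
* A proteomics modality covering a global 25% subsample of the RNA universe
  (500 markers, relabelled through a generated gene-to-protein mapping
  table), approximating the coverage ratio of matched proteomics/RNA assays.
  The subsample is global rather than per-pathway so the proteomics marker
  count is a fixed, reportable quantity.
* Loadings from a mixture of three isotropic Gaussians (cluster means drawn
  with sd 2, members with sd 1) — emulating sample clusters.
* Per-marker noise standard deviations from log-normal laws moment-matched to
  a mean of 0.95 (RNA) and 0.98 (proteomics), with marker-level spreads 0.25
  and 0.10: proteomics noise is slightly higher on average but much more
  homogeneous across markers. The log-normal family is our choice; only the
  means and the spread ordering are externally constrained.

What the generator does *not* emulate: marker-marker correlation beyond the
pathway structure, count overdispersion or zero inflation (observations are
Gaussian around the reconstruction), batch effects, or missing values. Tests
passing on this benchmark therefore certify the inference machinery, not
robustness to those real-data complications.

## Evaluation protocol

For held-out samples, `infer_loadings()` computes the exact ridge solution for
new loading columns under a frozen model, and `reconstruction_loglik()` scores
the held-out observations under the model's reconstruction — comparable
across models and bounded above by the ground-truth model scoring its own
noise-free reconstruction. `noise_mae()` measures mean absolute error of the
fitted per-marker noise. Downstream, `associate_continuous()` (Pearson, with
the $t$-transform p-value on $n-2$ df) and `associate_binary()` (Welch
two-sample $t$-test) relate pathway activity rows to sample covariates;
"activity" here is the row of $P = U B$, and an optional Benjamini–Hochberg
flag adjusts the p-values (raw by default).

## Test problem sizes

The package's own test suite runs the full default benchmark (2000 + 500
markers, $n = 100$) for the parameter-recovery check, and a proportionally
downscaled benchmark (800-marker universe, 80 markers per pathway, same
noise laws) for the multimodal-benefit, noise-trend and latent-pruning
checks; oracle comparisons (finite differences, dense determinants and
inverses) use instances of a few dozen markers. These sizes are the package's
choice of desk-scale study conditions.

## Known limitations

* **Surplus-latent pruning is asymptotic, not exact.** With more latents than
  the data supports, ARD drives the surplus loadings' energy toward zero and
  their precisions $\delta_j$ up by many orders of magnitude, but each latent
  retains a per-latent scale indeterminacy ($U_{\cdot j}\alpha$,
  $B_{j\cdot}/\alpha$): a few weight entries can absorb scale through the
  $\Lambda$ floor, keeping a nominal data term alive, and $\delta_j$ then
  converges to an interior optimum that can sit below `prec_max`. Surplus
  latents are thus effectively but not always *nominally* pruned; rank
  selection by the evidence trace is the robust alternative.
* **Exactly noise-free data** (a degenerate corner for a learned-noise model)
  stiffens the reweighted least-squares landscape — learned weights span many
  decades — and reconstruction can plateau at a local optimum with moderate
  error even though pathway activities stay well recovered. Any realistic
  noise level avoids the corner.
* The Laplace approximation is evaluated at a boundary point when entries of
  $U$ are clamped at zero; no constrained-Laplace correction is attempted.
* Gaussian likelihood only; raw counts must go through the normalization
  chain first.
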