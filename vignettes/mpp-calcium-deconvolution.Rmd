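---
title: "Marked-point-process deconvolution of calcium imaging movies: model and methods"
author: "mppdeconv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marked-point-process deconvolution: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A calcium imaging movie records, frame by frame, the fluorescence of a
field of neurons. Extracting science from it requires three entangled
inversions: which pixels belong to which cell (footprints overlap
spatially), when each cell fired (calcium decays slowly, so transients
overlap temporally), and how firing depends on an external covariate such
as the animal's position (the tuning curve). Pipeline approaches solve
these sequentially — demix, threshold, then regress on the stimulus — and
each step discards information the next one needed. `mppdeconv` instead
treats the movie as the output of a single generative model in which the
spikes of all neurons form a *marked point process* modulated by the
stimulus, and recovers footprints, 0–1 spike trains, firing rates and
tuning curves jointly as a variational posterior.

# Generative model

## Calcium dynamics and observation

Time is discretized into $R$ frames of width $\Delta$ covering $(0, T]$;
frame $r$ is the bin $((r-1)\Delta, r\Delta]$. A latent calcium state
$c_r \in \mathbb{R}^{d_\kappa}$ (with $d_\kappa \ll d_y$, the pixel
count — movies are low rank) follows a vector autoregression with jumps:

$$
c_1 \sim \mathcal{N}(\mu_{\mathrm{init}}, (\Sigma_{\mathrm{init}})^{-1}),
\qquad
c_r = F c_{r-1} + \begin{cases} \kappa_r & \text{(spike in bin } r\text{)} \\
v_r, \; v_r \sim \mathcal{N}(0, V) & \text{(no spike),}\end{cases}
$$

and each frame is observed as $y_r = G c_r + w_r$ with
$w_r \sim \mathcal{N}(0, W)$, $W$ diagonal. Throughout this package the
second argument of every Gaussian is a **precision** matrix; this single
convention makes the state-space, prior and variational formulas mutually
consistent. $G c_r$ is the denoised frame; $G \kappa_r$ is the fluorescent
image a spike imprints on the movie — the spiking neuron's footprint.

A spike's mark $\kappa_r$ is the vector of fluorescence it injects. Spike
frames deliberately carry *no* transition noise: the two branches of the
recursion are exclusive, and the mark itself is a random variable (below),
which plays the role the noise would.

## Spike generation

The marked spike sequence is an inhomogeneous marked Poisson process whose
conditional intensity factorizes over a mixture of product kernels:

$$
\lambda(\kappa \mid x, \xi) = \sum_k \pi_k\,
f^\kappa(\kappa \mid \mu^\kappa_k, \Lambda^\kappa_k)\,
f^x(x \mid u^x_k),
$$

with $f^\kappa$ a Gaussian mark kernel (the distribution of the neuron's
fluorescent footprints) and $f^x$ a normalized tuning curve: Gaussian for
a real-valued stimulus, von Mises for a circular one (e.g. position on a
circular track). The factorization asserts that the stimulus shapes *when*
a neuron fires, not *what its spike looks like*. Component $k$'s tuning
curve — its firing rate as a function of the stimulus — is
$\pi_k f^x(x \mid u^x_k)$, because the mark kernel integrates to one.
The discretized point-process likelihood multiplies per-bin spike
probabilities $\lambda(\kappa_r \mid x_r)\Delta$ (at most one spike per
bin) against the compensator $\exp(-T \int\!\!\int \lambda \,d\kappa\,
\eta(dx))$, where $\eta$ is the empirical occupancy measure of the
stimulus path, represented with uniform weight $1/R$ on the sampled
values; no occupancy smoothing is applied.

## Prior and the rate correction $\beta^*$

The mixing measure $\xi$ receives a truncated mixture-of-weighted-gamma-
process prior with $K$ atoms: concentration $\alpha_0$, weight scale
$\beta_0$, and a Normal–Wishart base measure
$\mathrm{NW}(m^\kappa, \gamma^\kappa, \nu^\kappa, S^\kappa)$ over each
mark kernel's $(\mu^\kappa, \Lambda^\kappa)$. The Wishart here is
inverse-scale parameterized, so the prior mean precision is
$\nu^\kappa (S^\kappa)^{-1}$. Stimulus kernel parameters $u^x_k$ are
treated as hyperparameters and estimated by empirical Bayes (their
dimension is small, so a point estimate is adequate).

Marginalizing the gamma process in the posterior leaves Dirichlet weights
$\pi \sim \mathrm{Dir}(\alpha_0/K, \ldots)$, latent assignments $z_{rk}$,
and a closed-form *rate correction*

$$
\beta^*(u^x) = \frac{\beta_0}
{1 + \beta_0\, T \int f^x(x \mid u^x)\, \eta(dx)},
$$

which multiplies each spike factor. It is how the compensator survives the
augmentation: a component whose tuning curve overlaps the occupied
stimulus region heavily is discounted ($\beta^* \to$ small), one whose
field was never visited keeps $\beta^* = \beta_0$. The posterior atom
weight of component $k$ is
$\lambda_k = \beta^*(u^x_k)(\alpha_0/K + \sum_r \zeta_{rk})$, the rate
reported by `extract_tuning()`.

# Variational inference

The posterior over $(c, z, \pi, u^\kappa)$ is approximated under the
mean-field factorization $q(c)\,q(z)\,q(\pi)\,q(u^\kappa)$. All four
stationary families are conjugate:

* $q(c)$ — a Gaussian chain with block-tridiagonal precision. At
  transition $r$ the effective precision is the responsibility mixture
  $(1-\sum_k \zeta_{rk})V + \sum_k \zeta_{rk}\,\mathbb{E}[\Lambda_k]$ with
  mean offset $\sum_k \zeta_{rk}\,\mathbb{E}[\Lambda_k] m_k$. The update is
  one forward block-elimination and one backward smoothing pass
  (implemented in C++), returning marginal means, covariances and the
  lag-one cross covariances that the innovation moments
  $\mathbb{E}[c_r - F c_{r-1}]$, $\mathrm{Cov}(c_r - F c_{r-1})$ require.
* $q(z)$ — independent per-frame categorical responsibilities over
  "no spike" and the $K$ active components, from expected log densities
  of the innovation (digamma forms for the Dirichlet and Wishart
  expectations), plus $\log \beta^*$, the stimulus kernel log density and
  $\log \Delta$; normalized by log-sum-exp.
* $q(\pi)$ — Dirichlet with $\alpha_k = \alpha_0/K + \sum_r \zeta_{rk}$.
* $q(u^\kappa)$ — per-component Normal–Wishart with soft pseudo-counts
  $N_k = \sum_r \zeta_{rk}$ and responsibility-weighted innovation
  moments (the covariance contribution of $q(c)$ included).

Hyperparameters are maximized in the same sweep: $u^x_k$ by bounded
quasi-Newton ascent of
$N_k \log\beta^*(u) + \sum_r \zeta_{rk}\log f^x(x_r \mid u)$ from a
weighted-moment warm start; $(F, V, G, W, \mu_{\mathrm{init}},
\Sigma_{\mathrm{init}})$ by their exact M-steps. The $F$ step deserves a
note: $F$ enters both the no-spike factors (through $V$) and the spike
factors (through each $\mathbb{E}[\Lambda_k]$), so its stationary point is
a linear system in $\mathrm{vec}(F)$ assembled from $K+1$ Kronecker
products of weighted state second moments with the respective precisions.
When those second moments are nearly singular the ridge-regularized solve
can drift off the stationary point, so the update evaluates its own
quadratic objective and keeps the previous $F$ (similarly $G$) whenever
the proposal scores worse — every coordinate update is then monotone in
the evidence lower bound, a property the test suite asserts on randomized
instances.

The ELBO is computed in closed form (full conjugacy) with terms itemized
for debugging. One sweep runs, in order: $q(c)$, $q(z)$, $q(\pi)$,
$q(u^\kappa)$, $u^x$, state-space M-steps — states first, so that
innovations are stable before responsibilities are reassigned. Stopping is
iteration-count based (default 10 sweeps), matching how this family of
models is used in practice; the trace of per-sweep ELBO values is
recorded for inspection.

## Component pruning

After each sweep, components with fewer than 0.5 expected spikes
($\sum_r \zeta_{rk} < 0.5$) are deactivated: they revert to their prior
and stop competing. This realizes the shrinkage of the weighted-gamma-
process prior as explicit model selection — surplus components of the
truncation lose their spikes to better-fitting ones (the Dirichlet
rich-get-richer term, the $d/\gamma_k$ Occam factor and the sharper
fitted precisions all push the same way) and are removed. Pruning is a
discrete move, not a coordinate-ascent step, so the recorded ELBO trace is
taken *before* it each sweep; the bound can dip transiently when a
component that still held probability mass is removed, and recovers as the
survivors absorb its spikes.

## Initialization

The scheme (deterministic given the seed):

1. Rank-$d_\kappa$ truncated SVD of the movie gives $G$ (orthonormal
   columns) and the state trajectory $\mu^c$.
2. $F = \rho I$ with $\rho$ the median lag-one autocorrelation of the
   leading temporal components, clipped into $(0, 1)$.
3. Innovations $e_r = \mu^c_r - \rho \mu^c_{r-1}$ whose squared norm is a
   robust outlier (MAD z-score > 5) become spike candidates.
4. Candidate innovations are projected onto their leading principal
   components (mark means span a low-dimensional subspace; the estimation
   noise is broad-band) and clustered by a BIC-selected spherical Gaussian
   mixture, capped at $K$ clusters. Selecting the cluster count matters:
   fixed-$K$ clustering splits neurons and seeds duplicate components
   that the ascent is slow to merge.
5. Each cluster seeds a responsibility column ($\zeta = 0.9$ at its
   frames) and, through hard-assignment conjugate updates, a
   Normal–Wishart factor. $V$ and $W$ come from quiet-frame innovation and
   pixel-residual moments; stimulus kernel locations are spread over the
   observed range.

When no prior is supplied, the Normal–Wishart base measure is
scale-matched to the data: $m^\kappa = 0$, $\gamma^\kappa = 10^{-2}$,
$\nu^\kappa = d_\kappa + 2$, and $S^\kappa = \nu^\kappa \hat\Sigma$ with
$\hat\Sigma$ the pooled *within-cluster* covariance of the candidate
innovations, so the prior mean precision is $\hat\Sigma^{-1}$ — the mark
noise scale, not the between-neuron spread. The distinction is
consequential at $d_\kappa = 40$: with $\nu^\kappa = 42$ pseudo-counts
against ~10 spikes per neuron, a between-neuron scale would leave every
component's mark precision broad enough to cover several neurons and the
ascent merges them; the within-cluster scale keeps components crisp.
$\alpha_0 = 1$ and $\beta_0 = 1$ by default; an optional one-dimensional
numeric maximization of $\alpha_0$ is available but off by default, since
the weight-concentration data signal in one movie is weak.

## Numerical choices

* All densities are evaluated in log space; a $d_\kappa = 40$ Gaussian
  underflows linear space routinely. The von Mises normalization uses the
  exponentially scaled Bessel function.
* Responsibilities below $10^{-12}$ are treated as exact zeros in
  entropy terms ($0 \log 0 = 0$).
* Covariance-like matrices receive a relative jitter ($10^{-9}$ of their
  dominant scale) before inversion; observation variances are floored at
  $10^{-10}$ of the mean movie power so that exactly-fitted pixels cannot
  drive $W$ to infinity and amplify round-off into the ELBO.
* Per-pixel residuals are accumulated as
  $\sum_r (y - G\mu^c)^2 + g^\top(\sum_r \Sigma^c_r)g$, never by expanding
  the square across large cancelling sums.
* Frame 1 never carries a spike (jumps enter the recursion from frame 2);
  a spike "at frame $r$" means an event in $((r-1)\Delta, r\Delta]$, and
  the stimulus is sampled at the bin end.
* One integer seed drives every random element (stimulus, spikes, noise,
  clustering restarts) through deterministically derived sub-seeds;
  identical seeds give bit-identical runs.

# The simulator and what it does (not) emulate

`simulation_study()` draws from exactly the generative model above, at the
reference configuration: nine stimulus-tuned neurons observed for
$T = 150$ s at $\Delta = 0.1$ s ($R = 1500$) on a $40 \times 40$ pixel
grid, fitted with $K = 20$, $d_\kappa = 40$ and 10 sweeps. Values the
study design leaves open are fixed once at what a calcium-imaging
practitioner would call realistic, and are deliberately not revisited:

| parameter | default | rationale |
|---|---|---|
| rate weight $\lambda_k$ | 0.4 /s | sparse-firing regime typical of hippocampal place cells |
| footprint blobs | $\sigma = 3$ px on a jittered $3\times3$ grid | several neighbour pairs overlap partially, the regime demixing exists for |
| mark amplitude / jitter | 1 / 0.05 | transient clearly above noise; footprints fluctuate a few percent between spikes |
| receptive field SD | 0.3 (stimulus units) | fields cover ~15% of the stimulus range each |
| decay per frame | 0.8 | ~0.45 s fluorescence decay constant at 10 Hz |
| transition / observation noise SD | 0.02 / 0.05 | peak-pixel SNR ≈ 20, mid-range for a good indicator |
| stimulus | reflected Ornstein–Uhlenbeck walk, SD 1.5 on $[-2, 2]$ | slow, bounded covariate with near-uniform occupancy; `circular_track` provides monotone laps for the von Mises case |

The observation matrix is built from the nine footprint blobs plus a
random orthonormal complement, so the low-rank premise holds by
construction. The simulator omits — intentionally — motion artifacts,
photobleaching drift, non-Gaussian noise, correlated spiking between
neurons, and baseline fluorescence offsets. Passing the recovery tests
therefore demonstrates correctness of the inference under the model's own
assumptions, not robustness to the full messiness of experimental
two-photon data; for real movies the practical accommodations are the
movie patching utilities (large fields of view are tiled into ~100×100
patches fitted independently, as with the 25-patch treatment of a
~500×500 recording) and the von Mises stimulus family.

Problem sizes used by the automated checks: the reference scene above for
the end-to-end recovery experiments (ten seeds), and instances with
$R \le 24$ frames and $d_\kappa \le 4$ for the oracle-equivalence and
bound-monotonicity properties, where dense joint-Gaussian solves and
brute-force integration are exact yardsticks.

# Known limitations

* Mean-field $q$ underestimates posterior correlations between, e.g.,
  footprints and spike times; the ELBO gap to the true evidence is not
  monitored.
* Components are never split or merged during the ascent — only pruned —
  so initialization quality matters; the BIC-selected clustering is the
  load-bearing ingredient.
* Two neurons with near-identical footprints *and* near-identical tuning
  are unidentifiable in principle; the fit returns one component.
* The 0–1 spike trains come from thresholding responsibilities at 0.5
  with an argmax tie-break; sub-frame timing and spike amplitudes beyond
  the mark posterior are out of scope.
* Patch-wise fitting does not merge components that straddle patch
  borders; border neurons can be reported twice.
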