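---
title: "Cross-subject mapping with Gauss-Bernoulli RBMs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-subject mapping with Gauss-Bernoulli RBMs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Neural decoders trained on one subject generally fail on another: even when
two animals perform the same task, the geometry of their feature spaces
differs enough that a classifier carried across subjects performs near
chance. `crossrbm` addresses this with a generative approach. The feature
vectors of all $M$ subjects are concatenated into one visible vector
$x = (x_1, \ldots, x_M) \in \mathbb{R}^D$, a single joint density $p(x)$ is
learned over the whole population, and at test time the feature vector of a
*target* subject is transferred into the space of a *source* subject by
conditional sampling from the fitted joint. The source subject's linear
decoder then classifies the transferred representation directly; no decoder
is ever trained for the target.

The motivating data are spike-resolved recordings of the complete flight
motor program of hawk moths: ten muscles, six visual stimulus classes,
trials segmented at wing strokes of 50-70 ms. But nothing in the model is
specific to that preparation; any collection of per-subject trial-by-feature
matrices with shared class structure fits the interface.

## The model

The joint density is a Gauss-Bernoulli restricted Boltzmann machine:
continuous visible units $x \in \mathbb{R}^D$, binary hidden units
$h \in \{0,1\}^H$, and energy

$$E(x, h) = \tfrac{1}{2}(x - c)^\top \Lambda (x - c) - h^\top W \Lambda x - b^\top h,$$

with couplings $W \in \mathbb{R}^{H \times D}$, biases $b \in \mathbb{R}^H$
and $c \in \mathbb{R}^D$, and a learnable diagonal visible precision
$\Lambda = \mathrm{dg}(\lambda)$. (The textbook unit-variance variant is the
special case $\Lambda = I$; it is available by freezing $\lambda$ at 1
rather than as a separate class.) The two conditionals are exactly

$$p(h \mid x) = \sigma(W \Lambda x + b), \qquad
  p(x \mid h) = \mathcal{N}(W^\top h + c,\; \Lambda^{-1}),$$

and summing the Boltzmann factor over the $2^H$ hidden configurations gives
the free energy of the visible marginal in closed form,

$$F(x) = \tfrac{1}{2}(x - c)^\top \Lambda (x - c)
  - \textstyle\sum_j \mathrm{softplus}\big((W \Lambda x + b)_j\big),$$

so that $p(x) \propto e^{-F(x)}$. `rbm_free_energy()` implements this with a
numerically stable softplus (evaluated as
$\max(z,0) + \log(1 + e^{-|z|})$), because mapping evaluates the model at
noise-initialised states where pre-activations can be large. The identity
$e^{-F(x)} = \sum_h e^{-E(x,h)}$ is asserted in the tests at relative error
$10^{-10}$ against brute-force enumeration.

## Two estimators

### Contrastive divergence

Maximum likelihood requires the gradient
$\nabla_\theta F(x_{\text{data}}) - \mathbb{E}_{p}[\nabla_\theta F(x)]$,
whose second term is intractable. CD-$k$ estimates it with chains started at
the minibatch and advanced by $k$ Gibbs sweeps (`k_cd = 1` by default, the
standard choice). The analytic $\nabla_\theta F$ blocks are verified against
finite differences, and the model-expectation term is verified on a small
$D = 2, H = 2$ model against exact quadrature of the normalised density
(using the enumerated log partition function).

### Fisher divergence (score matching)

The pointwise Hyvärinen score
$s_F(x) = \tfrac{1}{2}\|\nabla_x \log p(x)\|^2 + \Delta_x \log p(x)$ has a
closed form for this model:

$$s_F(x) = \tfrac{1}{2}\big\|\Lambda(W^\top \sigma + c - x)\big\|^2
  + \mathrm{tr}\big({-\Lambda} + \Lambda W^\top \mathrm{dg}(\sigma') W \Lambda\big),
  \qquad \sigma = \sigma(W \Lambda x + b).$$

Minimising its data average fits the model without ever evaluating $Z$ or
running a sampler — the package counts sampler invocations and the test
suite asserts the count stays at zero throughout FD training. The parameter
gradients of $s_F$ are derived analytically by differentiating the closed
form. We deliberately treat agreement with central finite differences of the
batch-mean score as the binding definition of these gradients, and certify
every block ($W$, $b$, $c$, $\lambda$) to $10^{-4}$ relative error in the
tests; the derivation reproduces the familiar
$\nabla_c s_F = \Lambda^2 (W^\top \sigma + c - x)$ and
$\nabla_b s_F = \mathrm{dg}(\sigma') W \Lambda^2 (W^\top\sigma + c - x) +
\mathrm{dg}(W \Lambda^2 W^\top)\, \sigma''$ forms.

### Optimisation

Both estimators share one minibatch loop: Adam (default) or plain SGD,
learning rate 0.005, batch size 150, 350 epochs, minibatches drawn without
replacement and reshuffled each epoch under the run seed. These defaults are
the experimental configuration for the moth-scale problem ($P = 10$ features
per subject, $H = 15$ hidden units, split ratio $\omega = 0.5$). There is no
early stopping: a fixed epoch budget keeps runs reproducible and
comparable. The precisions are optimised as $\log \lambda$ so they remain
positive; no other constraints are active.

Initialisation (the estimators are silent on it): $W \sim
\mathcal{N}(0, 0.01^2)$, $b = 0$, $c$ at the training-data mean and
$\lambda$ at the reciprocal training-data variances (clipped to
$[10^{-3}, 10^3]$). This starts the Gaussian part of the model at its
moment-matched optimum, so early training only has to learn the coupling
structure. A convenient corollary: with $W$ frozen at zero, score matching
on Gaussian data is already at its closed-form optimum $c = \mu$,
$\lambda = 1/v$, and the tests verify the optimiser stays within $\pm 0.05$
of $\mu$ and $\pm 10\%$ of $1/v$ at $n = 10^4$.

For CD the true objective is implicit, so the trace logs a one-sweep
reconstruction mean squared error and the free-energy gap between data and
model samples; both are monitoring quantities and are never optimised.

## The mapping procedure

Given a trained model and a layout assigning each subject a block of
columns, `predict()` (or `cross_subject_map()`) transfers target features to
source spaces:

1. initialise $\hat{x}^{(0)}$ with the supplied target features in their
   blocks and independent standard normal noise everywhere else;
2. sample $\hat{h} \sim p(h \mid \hat{x})$, then update the visible state
   from $p(x \mid \hat{h})$;
3. repeat $k$ times and return the source blocks.

Defaults and the reasoning behind them:

* **k = 1.** One sweep is the standard test-time choice and is what the
  evaluation harness uses. Larger $k$ is exposed; with clamping it converges
  to the proper conditional.
* **mode = "mean_readout".** The final visible draw is replaced by the
  conditional mean $W^\top \hat{h} + c$ restricted to the source blocks (the
  maximising readout of the final step). This removes one layer of sampling
  variance from the decoder input; `"sampled"` is available when genuine
  draws from $p(x_S \mid x_T)$ are wanted.
* **clamp = "clamped".** Re-imposing the target features after every visible
  update makes the chain an exact Gibbs sampler for $p(x_S \mid x_T)$. The
  fully resampled (`"unclamped"`) chain follows the literal one-pass
  description and coincides with the clamped chain at $k = 1$ — under a
  shared seed the outputs are identical vectors, which the tests assert —
  but forgets the target as $k$ grows, so clamping is the default for
  $k > 1$. Neither variant is claimed to be "the" intended chain for large
  $k$; both are provided.
* Subjects in neither role are noise-initialised and freely resampled. One
  fitted model therefore serves every target/source partition of its roster
  without retraining.

### Feature scale and the noise initialisation

A consequential design choice. We initially z-scored each feature dimension
(training-split statistics) before RBM training, expecting only better
optimizer conditioning. That silently changes the mapping problem: the
unknown blocks are initialised with standard normal noise, and on z-scored
features that noise has exactly the marginal scale of real data. With one
informative block out of nine, the hidden pre-activations are then dominated
by the eight noise blocks, and mapped decoding stalls around 0.45 even
though the hidden code computed from complete rows separates classes
perfectly. On features kept at their natural scale (e.g. PCA scores, whose
spread is several times the unit noise), the same model and procedure reach
about 0.8 or higher. The harness therefore does **not** standardise by
default; `run_scenario(standardize = TRUE)` retains the alternative, and the
interaction is worth knowing about for any data whose natural scale is close
to 1.

## From spike trains to features

`smooth_spikes()` converts a trial's spike times to a continuous trace by
summing unit-height Gaussian kernels,
$x(t) = \sum_n \exp(-(t - t_n)^2 / 2\sigma^2)$ on the grid
$t \in \{0, 1/f_s, \ldots\}$, $0 \le t \le \tau$, with defaults
$\tau = 60$ ms (spikes with $t_n \le \tau$ are kept, later ones dropped) and
$\sigma = 2.5$ ms. The sampling frequency is not dictated by the method;
the default $f_s = 1$ kHz resolves the 2.5 ms bandwidth comfortably
(60 samples per muscle, 600 per trial) and is configurable. Trials shorter
than $\tau$ need no padding beyond the fixed grid. Missing muscles are
zero-filled in a fixed ten-muscle roster order, traces are flattened across
muscles, and a per-subject PCA (training split only) retains the first
$P = 10$ modes with a deterministic sign convention (largest-magnitude
loading positive). Per-subject PCA means each subject's feature space is
its own — exactly the misalignment the mapping is for.

## The synthetic testbed

`synth_features()` generates the study conditions every numerical claim in
the package is tested under: 9 subjects, 6 balanced classes, ~400 trials
per class and subject, $P = 10$. Shared latent class means sit at centred
simplex vertices scaled by `class_separation = 8`; each subject sees them
through its own random orthogonal rotation (options: affine, or a saturating
tanh warp for stressing linear aligners), plus unit Gaussian noise. The
separation default makes within-subject classes ~$8\sqrt{2}$ noise standard
deviations apart: subject-specific linear decoding is then near-perfect
(as it is on the real preparation) while cross-subject decoding without
transfer sits at the 1/6 chance floor in expectation, by the rotational
symmetry of the maps. `synth_spikes()` generates the same structure at
spike level: per (class, muscle) template phases 9 ms apart (far beyond the
2.5 ms kernel bandwidth), per-trial Gaussian jitter (1 ms) and rare spike
drop/insertion (2%), per-subject muscle phase offsets, and optional missing
muscles capped at two per subject.

What the generator does *not* emulate: trial-to-trial correlation within a
session, non-stationarity over time, unbalanced classes, heteroscedastic or
structured (non-isotropic) noise, and any physiological realism in the
spike patterns. Passing tests therefore demonstrate the machinery is
correct under the method's own assumptions — shared class structure seen
through subject-specific geometry — not that the method succeeds on any
particular real recording.

## Evaluation harness

`run_scenario()` repeats the full pipeline over random splits: per repeat,
each subject is split $\omega / (1 - \omega)$ stratified by class
(stratification prevents class dropout at $\omega = 0.5$ with small
per-class counts), decoders and the joint RBM are re-fitted on the training
halves, and test trials are scored. Two scenarios: one source decoding all
remaining subjects as targets (I), or one target decoded in the space of
every remaining subject by that subject's own decoder (II). The joint
training matrix pairs trials across subjects at random *within* stimulus
class, redrawn once per split (pairing is a dataset-construction step, not
a per-epoch operation); per class, the row count is the largest class count
across subjects, with each subject's pool drawn without replacement until
exhausted.

The decoder is linear discriminant analysis (`MASS::lda`), trained only on
source data, with a ridge-regularised pooled-covariance fallback for
singular cases; accuracy is micro-averaged 0/1 over test trials (classes
are balanced). Benchmarks: subject-specific decoding (upper bound),
no-transfer (lower bound, near chance), the two RBM estimators, and a
plug-in hook for external alignment methods (e.g. hierarchical Wasserstein
alignment) supplied as a function — none is re-implemented here. Reports
carry one accuracy per (source, target, repeat); summaries give means and
95% percentile intervals over repeats.

Problem sizes used in the automated checks are scaled for a single CPU: the
end-to-end checks run 9 subjects at 60 trials per class with 20 repeats of
the full re-fit pipeline, and the chance-floor check averages over freshly
drawn rosters (fresh rotations) rather than only fresh splits, which is the
variance that actually matters for that quantity. The defaults in the
function signatures remain the full-scale configuration.

## Numerical choices and degenerate inputs

* Sigmoid/softplus arguments are $W \Lambda x + b$ everywhere, including in
  all gradients; both are evaluated in overflow-safe forms.
* `rbm_log_partition()` (hidden-configuration enumeration plus closed-form
  Gaussian integrals) refuses $H > 12$; it exists as an exact oracle for
  small-model tests, and nothing at runtime depends on $Z$.
* PCA refuses $P$ beyond the effective rank; ties in explained variance are
  broken by the deterministic sign rule.
* Training aborts with a diagnostic if the objective turns non-finite;
  `epochs = 0` returns the initialisation unchanged (useful for baselines).
* Every stochastic step — initialisation, shuffling, Gibbs draws, splits,
  pairing — flows from explicit seeds; identical seeds give byte-identical
  results.

## Known limitations

* Score matching is blind to the relative weights of well-separated modes;
  this does not disturb class-conditional mapping but means fitted mixture
  proportions should not be over-interpreted.
* The mapping is directional (targets to sources) and provides no
  subject-similarity metric.
* With many subjects and a single informative block, $k = 1$ mapping quality
  depends on the feature scale relative to the unit noise initialisation
  (see above); clamped $k > 1$ reduces but does not remove this.
* The harness assumes every class is present for every subject; absent
  classes are a hard error rather than a marginalised case.
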