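# crossrbm

Cross-subject transfer of neural feature vectors with Gauss–Bernoulli
restricted Boltzmann machines.

## The problem

A classifier ("neural decoder") trained on one subject's neural features
usually collapses to chance on another subject, because each individual's
feature space has its own geometry even when the subjects perform identical
tasks. `crossrbm` is for the setting where decoders exist for some
*source* subjects and trials from *target* subjects must be decoded without
ever training a target decoder: it learns one joint generative model of all
subjects' features and, at test time, transfers a target trial into a
source subject's feature space so the source decoder applies directly.

The package was built around spike-resolved recordings of the hawk moth
flight motor program — ten muscles, six visual stimulus classes, trials
segmented at 50–70 ms wing strokes — and ships the full pipeline for that
kind of data: Gaussian-kernel smoothing of spike trains, per-subject PCA
features, the RBM with two training methods, the Gibbs-sampling mapping, a
repeated-split evaluation harness with the standard benchmarks, a synthetic
multi-subject data generator, plain-text file formats and a command-line
interface. Any collection of per-subject trial × feature matrices with
shared class labels fits the interface.

## The model

The concatenated feature vector x = (x₁, …, x_M) ∈ ℝᴰ of all M subjects is
modelled by a Gauss–Bernoulli RBM with binary hidden units h ∈ {0,1}ᴴ and
energy

    E(x, h) = ½ (x − c)ᵀ Λ (x − c) − hᵀ W Λ x − bᵀ h,

where Λ = dg(λ) is a learnable diagonal visible precision. The conditionals
are p(h|x) = σ(WΛx + b) and p(x|h) = N(Wᵀh + c, Λ⁻¹), and the visible
marginal has closed-form free energy F(x) = ½(x−c)ᵀΛ(x−c) − Σⱼ
softplus((WΛx + b)ⱼ). Two estimators are provided:

* **`method = "cd"`** — k-step contrastive divergence, the classical
  likelihood-gradient approximation via Gibbs chains started at the data;
* **`method = "fd"`** — Fisher-divergence minimisation (score matching):
  the Hyvärinen score ½‖∇ₓ log p‖² + Δₓ log p has a closed form for this
  model, so training uses exact analytic gradients and never runs a
  sampler.

Mapping initialises the visible vector with the target subject's features
in their blocks and standard normal noise elsewhere, runs k Gibbs sweeps
(k = 1 by default), and reads out the source blocks — either sampled or via
the conditional-mean (maximising) readout. One fitted model serves every
target/source partition of its roster.

## Worked example

```r
library(crossrbm)

# 1. synthetic roster: 3 subjects, 6 classes, subject-specific rotations
moths <- synth_features(n_subjects = 3, trials_per_class = 40, seed = 1)

# 2. joint training set by within-class pairing, then fit the RBM
set.seed(1)
joint <- build_joint_training_set(moths)
fit <- gbrbm(joint$X, hidden = 15, method = "fd", epochs = 300,
             batch_size = 150, layout = joint$layout, seed = 1)
print(fit)
#> Gauss-Bernoulli RBM (FD), D = 30 visible, H = 15 hidden
#>   trained 300 epochs on 240 rows (batch 150, adam, lr 0.005)
#>   final objective: -14.94132
#>   layout: 3 subjects (s1, s2, s3)

# 3. map subject s2's trials into s1's feature space and decode there
mapped  <- predict(fit, moths$s2$X, targets = "s2", sources = "s1", seed = 2)
decoder <- train_decoder(moths$s1$X, moths$s1$y)
mean(predict(decoder, mapped) == moths$s2$y)     # 0.975
mean(predict(decoder, moths$s2$X) == moths$s2$y) # 0.25  (no transfer)

# 4. full repeated-split benchmark (scenario I: s1 is the source)
report <- run_scenario("I", "s1", moths,
                       methods = c("subject_specific", "no_transfer", "rbm_fd"),
                       repeats = 5, epochs = 300, seed = 3)
summarize_report(report, by = c("scenario", "method"))
#>   scenario           method n_rep  mean ci_low ci_high
#> 1        I      no_transfer     5 0.213  0.177   0.271
#> 2        I           rbm_fd     5 0.968  0.931   0.996
#> 3        I subject_specific     5 1.000  1.000   1.000
```

Read the table as the three standard benchmarks: decoding a subject with
its own decoder is near-perfect (upper bound), carrying a decoder across
subjects raw is near the 1/6 chance floor (lower bound), and RBM-mapped
transfer recovers most of the gap. `run_scenario("II", ...)` evaluates the
converse setting (one target decoded in every other subject's space), and
`methods = "rbm_cd"` adds the contrastive-divergence-trained model.

Spike-level data enter through `synth_spikes()` / `read_spike_table()` and
`featurize_spikes()` (smoothing, zero-fill of missing muscles, flattening,
per-subject PCA). A thin CLI wraps the same functions:

```sh
inst/cli/crossrbm simulate features --out data --seed 1
inst/cli/crossrbm train --features data --out model.json --method fd
inst/cli/crossrbm map --model model.json --targets data/features_s2.tsv \
    --target-id s2 --source-id s1 --out mapped.tsv
```

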