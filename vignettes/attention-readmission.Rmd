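---
title: "Attention-gated networks for interpretable clinical risk prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention-gated networks for interpretable clinical risk prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(attnrisk)
library(dplyr)
```

## The problem

Clinical prediction models built from electronic health record tables face a
tension: flexible models (neural networks) predict well but are opaque, while
transparent models (logistic regression) expose their reasoning but may
underfit. The motivating task is one-year readmission prediction for heart
failure patients from a table of roughly a hundred numeric features —
demographics, vital signs, laboratory values (e.g. NT-proBNP), echocardiography
measurements, comorbidity indicators, medications. Clinicians will not act on
a risk score they cannot interrogate, so the model must say, per patient,
*which* features drove its prediction.

`attnrisk` implements an attention-gated feed-forward network that buys
interpretability structurally rather than post hoc. For a patient with feature
vector $x \in \mathbb{R}^m$:

$$\alpha = \mathrm{softmax}(Wx + b), \qquad g = \alpha \odot x,$$

where $W$ is $m \times m$ and $b$ length $m$. The attention vector $\alpha$
lies on the probability simplex (every entry in $(0,1)$, summing to one), and
gates the input element-wise before a standard multilayer perceptron with ReLU
hidden layers and a sigmoid output unit produces the readmission probability
$y'$. Attention and classifier are trained jointly by minimizing

$$L = -\frac{1}{n}\sum_{i=1}^n \left[ y_i \log y_i' + (1-y_i)\log(1-y_i')
\right] + \lambda \lVert \Theta \rVert_2^2 ,$$

with $\Theta$ the collection of weight matrices (the attention $W$ and every
MLP layer weight; bias vectors are not penalised, following standard
weight-decay practice — see "Open choices" below). Because $\alpha$ is a
probability vector computed per patient, it reads directly as a per-patient
feature-importance profile; aggregating top-$k$ membership across patients
gives a cohort-level ranking.

## What the package contains

- preprocessing for clinical feature tables: drop features with **more than
  30%** missing values (a feature at exactly 30% is kept), impute the rest
  with the feature median, z-score features, and split 80/20 stratified by
  outcome;
- the attention model plus the three standard comparators: logistic
  regression (ridge-penalised MLE), a plain MLP sharing the same training
  engine, and a stacked denoising autoencoder (SDAE) classifier;
- an evaluation protocol: repeated stratified 80/20 holdout, five-fold
  cross-validation on the training split for hyperparameter selection
  (number of hidden layers), metrics (accuracy, precision, recall, F1, AUC)
  summarised mean ± sd over repetitions, paired t-tests between models'
  pooled predicted labels, and a hidden-layer depth sweep;
- interpretation outputs: per-patient attention rankings, a global
  frequency ranking (how often a feature lands in patients' top-10), the
  logistic $|\hat\beta|$ ranking as the transparent-model counterpart, and
  log-attention heat-map matrices;
- a synthetic cohort generator with known informative features, so the
  claim "attention finds the features that matter" is testable.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `learning_rate` | 0.001 | Adam step size (both phases of the SDAE too) |
| `lambda` | 0.001 | L2 coefficient on weight matrices, per the loss above |
| `threshold` | 0.5 | classification cut; *strictly greater* maps to 1 |
| `n_hidden_layers` | 1 (sweep 1–5) | MLP depth |
| `hidden_width` | 64 | units per hidden layer |
| `epochs`, `batch_size` | 300, 32 | Adam budget |
| `patience` | 20 | early stopping on a 10% validation split |
| `max_missing` | 0.30 | strict missingness threshold for dropping features |
| SDAE `layer_widths` | 64, 32 | encoder stack (two coding layers) |
| SDAE `corruption_rate` | 0.2 | masking corruption during pretraining |

Learning rate, λ, the strict 0.5 threshold and the 1–5 depth sweep are the
core protocol settings; optimizer (Adam), width, activation, batch size,
early stopping and the SDAE corruption recipe are implementation choices set
to common defaults, all exposed through the config objects.

## Why standardize features

The gating step multiplies attention *into the raw feature values*, so the
gated representation — and the comparability of attention magnitudes across
features — depends on feature scale: NT-proBNP in pg/mL would dwarf ejection
fraction in percent. All model-fitting examples therefore z-score features
with training-split statistics, applied unchanged to test data
(`standardize_features(test, stats = scaling_stats(train))`). The protocol
does this per split internally.

Median imputation defaults to a dataset-level step (computed over all rows
before splitting), matching how a single-table clinical study typically
preprocesses once. That leaks a small amount of test information into
training; the leak-free alternative is to impute inside each split, and the
protocol's per-split standardization shows the pattern to follow if you need
it. For the missingness rates and sample sizes involved the difference is
negligible, but it is a real distinction and the default is stated rather
than hidden.

## The synthetic cohort generator

`generate_cohort()` draws $m$ standard-normal features under an optional
equicorrelation $\rho$ (a single shared Gaussian factor), forms a linear
predictor $\eta_i = \beta_0 + \sum_j \beta_j x_{ij}$ over a chosen set of
informative features, and draws the outcome from
$\mathrm{Bernoulli}(\mathrm{sigmoid}(\eta_i))$. `study_shaped_spec()` is a
preset with 736 patients, 105 features, ten informative features of
coefficient magnitude 0.3, and $\beta_0$ calibrated by root-finding on
$\mathbb{E}[\mathrm{sigmoid}(\beta_0 + sZ)]$ so the expected prevalence is
0.63 (≈461 events in 736) — the shape of a mid-size single-centre heart
failure cohort. `inject_missingness()` masks cells completely at random to
exercise the preprocessing path.

What this emulates: a numeric clinical feature table with a binary outcome,
class imbalance, weak-to-moderate effects, correlated measurements, and
missingness. What it does **not** emulate: mixed variable types beyond
optional dichotomised indicators (`binary_idx`), informative (MNAR)
missingness, longitudinal structure, measurement error, or site effects.
Passing tests on these cohorts therefore show that the implementation is
correct and that attention can recover known signal under clean conditions —
not that attention rankings on real EHR data are clinically valid. The
equicorrelation knob exists precisely to observe a known failure mode:
attention mass smearing across features correlated with the truly
informative ones.

## Numerical choices

- **Softmax stabilization.** Logits are max-shifted before exponentiation, so
  any finite attention parameters are safe; row sums are 1 to ~1e-16. At
  extreme logit spreads (hundreds of units) the smallest weights underflow
  double precision to exactly 0 — normalization still holds.
- **Cross-entropy clipping.** Probabilities are clipped to
  $[10^{-7}, 1-10^{-7}]$ before the logs; the analytic gradient is the exact
  derivative of the clipped loss (zero in the clipped region), so the
  finite-difference gradient check holds everywhere.
- **Initialization.** Glorot-uniform weights, zero biases, fully seeded.
  Initializing the attention $W$ at zero (uniform attention) also works, but
  Glorot lets attention break symmetry from the first step.
- **Determinism.** Every stochastic step (initialization, batching,
  validation split, corruption masks, splits, folds) runs under seeds derived
  from the relevant config seed; refitting with the same seed reproduces
  parameters bit for bit. Seeded code never disturbs the caller's RNG state.
- **Threshold tie.** A probability exactly equal to the threshold maps to 0;
  a constant-0.5 (untrained) model predicts the negative class rather than
  flipping on representation noise.
- **Zero-variance features** are centered but not scaled (no division by 0).
- **Ties in rankings** break by original feature order everywhere (stable),
  so outputs are reproducible across platforms.
- **Degenerate tests.** All-zero paired differences give $t=0, p=1$; a
  constant nonzero difference gives infinite $t$, $p=0$, flagged
  `degenerate`. Precision with no predicted positives is 0 with a warning.

## Open choices, and one subtlety about the penalty

Three places were genuinely open and are worth recording:

1. **What $\Theta$ covers.** Biases are excluded from the L2 penalty
   (standard weight decay). One consequence: as $\lambda \to \infty$ all
   weight matrices collapse to zero, and attention becomes the *same* vector
   $\mathrm{softmax}(b)$ for every patient — patient-independent, but not
   necessarily uniform, because the unpenalised attention bias is a free
   parameter at that optimum and retains wherever early training left it.
   The test suite asserts the patient-independence form, which is what the
   mathematics implies under this Θ. Penalising biases too would pin
   attention to exactly uniform in that limit; it is a one-line change but
   departs from common practice.
2. **Paired t-tests on binary labels.** The protocol applies the paired
   t-test to per-patient predicted labels pooled across repetitions because
   that is the comparison the study design describes; statistically, a
   t-test on paired binary outcomes is questionable, so `mcnemar_test()` is
   computed alongside and a per-repetition mode
   (`t_test_mode = "per_repeat"`) is exposed.
3. **Repetition variance.** The 80/20 split is redrawn each repetition
   (seed = `base_seed + r`); with a fixed split a deterministic pipeline
   would produce ten identical repetitions and zero standard deviations,
   which would make the mean ± sd summaries meaningless.

The per-patient attention threshold used for short "explanation sheets"
(`min_weight` in `rank_patient_features()`) deliberately has no default: any
cutoff on simplex weights is a presentation choice, not a model property,
and a sensible value depends on `m`.

## Problem sizes used by the test suite

The suite exercises full-scale shapes but reduced optimization budgets, the
package's own choice to keep feedback loops short: the protocol-shape test
runs the four models on a 736 × 105 cohort for 10 repetitions at 20 epochs;
the attention-recovery test fits 10 seeds on a 2000 × 20 cohort (3 informative
features, $|\beta| = 2$) at 60 epochs; gradient checks run at $m=5$, $n=8$,
one hidden layer of width 4 where central differences are sharp. At default
budgets (300 epochs, patience 20) the fits simply converge further; none of
the asserted properties depend on the reduced budgets.

## A complete run

```{r example, eval = FALSE}
co <- generate_cohort(study_shaped_spec(seed = 1))
parts <- split_holdout(co$data, train_fraction = 0.8, seed = 2)
train <- standardize_features(parts$train)
test  <- standardize_features(parts$test, stats = scaling_stats(train))

fit <- fit_attention(train, config = model_config(seed = 3))
compute_metrics(test$outcome,
                predict(fit, test)$.label,
                predict(fit, test, type = "prob"))

A <- extract_attention(fit, test)
global_frequency_ranking(A, k = 10, top = 10)
autoplot(A, sample_n = 50)               # log-attention heat map
plot_patient_attention(rank_patient_features(A[1, ], colnames(A), k = 10))
```

## Known limitations

- Attention weights are nonnegative and directionless: they quantify how
  much a feature mattered, never whether it raised or lowered risk. The
  package pairs them with signed logistic coefficients instead of inventing
  signs.
- Attention agreement with ground truth is demonstrated on synthetic
  cohorts; on real data, correlated features can share or swap attention
  mass, and no causal reading is warranted.
- The trainer is plain R (BLAS matrix products); it is comfortable at
  hundreds-to-thousands of patients and ~100 features, and not intended for
  cohorts orders of magnitude larger.
- Single binary outcome only; no visit-sequence (longitudinal) attention,
  no multi-class outputs, no text.
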