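---
title: "Methods: the falldet fall-detection pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the falldet fall-detection pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(falldet)
```

## The problem and the pipeline

Falls are a leading cause of injury among elderly people living alone, and
wearable monitors are the main practical route to timely assistance. The
`falldet` package implements a complete, reproducible fall-detection
pipeline for tabular wearable-sensor records in the cStick schema: six
channels per episode (obstacle distance, ordinal pressure level, heart-rate
variability, blood sugar, SpO2, accelerometer magnitude) and a three-class
decision label — 0 *no fall*, 1 *slip / stumble / predicted fall*, 2
*actual fall*.

The stages, each an exported module: synthetic data generation →
cleaning and train/test splitting → feature extraction (statistical
moments, lagged autocorrelation, PCA) → wrapper feature selection by the
HTLSS hybrid metaheuristic → the TriNet three-branch neural ensemble →
a nine-metric evaluation suite → a hash-chained event ledger with
severity-based alert routing.

## Synthetic data: what it emulates and what it does not

No public accession exists for the cStick recordings, so the package ships
a seeded generator rather than data. `gen_cstick_table()` emulates the
documented shape of that dataset — 2,039 records with class counts
690 / 682 / 667 — and its schema, not its measured physics:

* Continuous channels are class-conditional Gaussians. The mean of class
  $c$ is shifted by $c \cdot s \cdot \sigma$ from the class-0 mean, where
  $s$ is the `separation` argument in pooled standard-deviation units.
  SpO2 falls with severity; the other channels rise. Draws are clamped to
  physical ranges (SpO2 to $[70, 100]$, non-negative magnitudes), which
  slightly biases extreme-class means; at the default separation this is
  negligible for every channel except SpO2 near its ceiling.
* The ordinal pressure level comes from a latent Gaussian with the same
  class shift, cut at the tercile points of the class-0 latent plus the
  midpoints between adjacent class means, so that `separation = 0` yields
  uniform thirds.
* Channel base values and spreads (e.g. HRV 72 ± 9 beats/min, SpO2
  96.5 ± 1.4 %, blood sugar 110 ± 22 mg/dL) are plausible clinical numbers
  chosen once and documented in `cstick_channel_spec()`; no units or ranges
  are documented for distance, sugar or accelerometer in the source
  dataset, so these are package choices, not inferences.

The default `separation = 2.0` places the classes in the strongly
separable regime that the reported accuracies of cStick-style classifiers
imply; it is the regime in which ensemble comparisons are meaningful, and
all default test conditions use it. What the generator deliberately does
*not* model: sensor noise correlation across channels, drift,
class-imbalanced missingness, or real fall biomechanics. A passing test
suite therefore demonstrates correctness of the pipeline machinery and its
behaviour under the stated statistical structure — not clinical
performance on real recordings.

`gen_sensor_windows()` adds an optional per-record time series for the
window-based feature path: stationary noise for class 0, a transient
mid-window accelerometer spike for class 1, and a large spike followed by
a sustained level shift (impact, then lying still) for class 2.
`gen_feature_matrix()` plants a known informative/noise column split for
feature-selection ground truth.

## Cleaning and splitting conventions

Missing and null cells are treated as one sentinel (`NA`, serialized as an
empty CSV field). Three resolution policies are provided because no single
rule suits all deployments: `drop` (row removal), `column-mean`, and
`forward-fill` (last observation carried forward, first-row gaps falling
back to the column mean).

`split_dataset()` uses the dataset's "learning rate" convention: the train
count is `floor(rate * n)`. Floor rounding is the only rule consistent
with both documented splits of the 2,039-record set (0.7 → 1,427 / 612 and
0.8 → 1,631 / 408). The default split is a seeded shuffle; stratification
is offered as a flag and apportions the train quota per class by largest
remainder, keeping every class within one row of the global fraction.

## Feature extraction conventions

`stat_features()` emits seven moments per channel with deliberate,
documented conventions:

* population denominators ($N$, not $N-1$) for standard deviation and
  variance, so `variance = std^2` holds exactly;
* skewness as Pearson's second coefficient,
  $3(\bar{x} - \mathrm{median})/\sigma$, which is robust on the short
  windows used here;
* kurtosis as the non-excess ratio $m_4 / m_2^2$ (a normal signal scores
  3);
* both statistics defined as 0 for a constant channel instead of `NaN`.

`autocorr()` is the *raw* (non-mean-subtracted) autocorrelation
$s(m) = \sum_{i=0}^{I-m-1} a(i{+}m)\,a(i)$, normalized by $s(0)$ on
request; an all-zero signal defines $r(m) = 0$. This is intentionally not
`stats::acf()`, which subtracts the mean — the raw form is the quantity
the downstream features are defined on, and the test suite pins it to an
independent double-loop oracle at $10^{-10}$.

`pca_fit()` standardizes by z-score by default. True min-max scaling is
available via `scale_method = "minmax"`, but z-scoring is the default
because PCA on mixed-unit physiological channels is otherwise dominated by
the widest-range column. The covariance matrix uses the $N-1$ denominator;
eigenvalues are sorted descending and components retained either by
cumulative variance (default 0.95) or by an absolute eigenvalue floor
`lambda_eig`, always keeping at least one. An eigenvector-norm threshold
is accepted for completeness but off by default: thresholding unit-norm
eigenvectors is a no-op for any threshold at or below 1, and we found no
principled rule for setting it.

Two feature paths are supported, because window features and tabular
features serve different acquisition modes: `build_feature_matrix()`
(per-channel moments then lags, for windowed episodes; default 10 lags)
and the tabular path in `run_pipeline()`, where the six raw cStick columns
pass through PCA directly.

## HTLSS: the hybrid optimizer

HTLSS is a bounded continuous minimizer blending teaching-learning-based
optimization (TLBO) with spring-search-style interaction. Design choices,
several of which resolve ambiguities in how optimizers of this family are
usually written down:

* **Opposition-based initialization** evaluates each uniform start and its
  classical box reflection $\hat{x} = lo + up - x$ and keeps the better.
  The classical reflection is used because it keeps the midpoint fixed and
  never leaves the feasible box.
* **Five teachers** (configurable), the best member being chief; learners
  are grouped with the teacher of *nearest fitness*, which keeps each
  teacher instructing learners at its own level.
* **Teacher phase**: $x' = x + q \odot (x_{teacher} - T_f M)$ with
  per-dimension $q \sim U(0,1)$, group mean $M$, and teaching factor
  $T_f = \mathrm{round}(1 + \mathrm{rand}) \in \{1, 2\}$ sampled per
  learner. Per-learner sampling (rather than per-iteration or
  per-dimension) is the package's choice; the alternatives are not
  distinguishable on our benchmarks and one had to be fixed for
  reproducibility.
* **Learner phase**: a time-ratio blend
  $x' = x + r \odot ((1 - t/T)x + (t/T)x_{teacher} - x)T_f$ pulling
  increasingly toward the teacher as the run matures, then an exploration
  move with factor $e_f \in \{1,2\}$ whose $e_f = 2$ branch makes the
  self-term repulsive. Published update rules in this family reuse symbols
  across equations and leave operator precedence unstated; the
  implemented readings are stated above and at the point of use in the
  code.
* **Greedy acceptance** after every move and **per-group elitism** (the
  group's snapshot best replaces its worst at the end of each iteration) —
  standard TLBO practice, and what makes the best-so-far history provably
  non-increasing.
* **Spring term**: an optional Hooke-law pull
  $x' = x + K(x_{chief} - x)$, $K \in [0,1]$, disabled by default. Only
  the displacement-style interaction above is active out of the box; the
  spring pull is offered as a documented extension rather than a default
  because it adds a parameter without a printed default to inherit.
* **Determinism**: one seeded RNG stream with a documented draw order
  (header of `R/hsstl.R`). A degenerate configuration — one teacher,
  fixed $T_f = 1$, interaction off, plain initialization,
  `learner_rule = "tlbo"` — reduces exactly to canonical TLBO, which the
  test suite verifies trajectory-for-trajectory against an independently
  coded oracle.

Wrapper feature selection (`select_features()`) decodes positions in
$[0,1]^d$ to masks at the 0.5 threshold (with an argmax rescue so a mask
is never empty) and scores them by nearest-centroid misclassification on a
fold held fixed across the whole search, plus a sparsity penalty
$\alpha \cdot k/d$ (default $\alpha = 0.01$). The inner model is
nearest-centroid deliberately: it is fast enough to sit inside a
population search and has no hyperparameters that could interact with the
mask.

## TriNet

Three independently trained branches vote on each episode:

* **LSTM branch** — the standard gated recurrences over the feature
  vector presented as a length-$d$ sequence of scalars;
* **CNN branch** — 1-D valid convolution, ReLU, max pooling with the
  floor output-length rule, dense softmax; its hyperparameters (filters,
  kernel, log-learning-rate, dropout) can be tuned by HTLSS via
  `optimize_cnn()`;
* **gated RNN branch** — the same LSTM-form cell under its own parameter
  set (the package treats the "RNN" as gated by design; an ungated RNN
  adds nothing the LSTM branch does not already cover, and the gated form
  is what its usual write-ups actually specify).

Feature vectors are adapted to the sequence models as pseudo-sequences and
to the CNN as a 1-D signal; when sensor windows are available the same
branches can consume window-derived features through
`build_feature_matrix()`. Fusion is a soft vote — the arithmetic mean of
the three probability vectors, argmax, ties to the smallest class — with
hard majority voting as an option. Soft voting is the default because it
uses branch confidence rather than discarding it.

Training is plain mini-batch gradient descent (batch 32, fixed step) on
softmax cross-entropy, with hand-derived gradients verified against
central finite differences at $10^{-4}$ relative error in the test suite.
Plain SGD is a deliberate floor: it keeps runs bit-reproducible under a
seed and leaves no optimizer hyperparameters to tune away a comparison.
HTLSS tunes the CNN's *hyperparameters* rather than its weights — weight
optimization by a population metaheuristic is dominated by gradient
descent at these scales, and hyperparameter search is where a wrapper
optimizer earns its cost.

## Evaluation

`metrics_report()` reduces the 3-class confusion matrix one-vs-rest and
reports accuracy, precision, sensitivity, specificity, F-measure, MCC,
NPV, FPR and FNR, macro-averaged by default (per-class and binary modes
available). Conventions: F is the standard $F_1 = 2PR/(P+R)$ (the
unscaled product ratio $PR/(P+R)$ is available behind
`f_variant = "product"` for comparison with reports that print it); any
0/0 cell is defined as 0 so degenerate folds never crash; in every binary
reduction $FPR = 1 - \text{specificity}$ and $FNR = 1 - \text{sensitivity}$
hold identically. `roc_points()` sweeps one-vs-rest thresholds over the
unique scores and integrates by trapezoid; it is cross-checked against
`pROC` in the tests.

## The event ledger

`ledger_append()` / `ledger_verify()` implement a single-writer local hash
chain: each block stores the SHA-256 of
`index ‖ timestamp ‖ payload ‖ prev_hash`, payloads are canonical JSON
(sorted keys, no insignificant whitespace, full-precision numbers), and
the genesis block carries an all-zero previous hash. This is the
desk-scale embodiment of tamper-evident fall-event storage: any
retroactive edit of any stored byte is detected, which the suite verifies
exhaustively on a 10-block chain. Distributed consensus, smart contracts
and encryption-at-rest are explicitly out of scope; `route_alert()`
returns the severity-ordered recipient plan (class 2 → emergency medical
first, then family and neighbours; class 1 → family and caregiver;
class 0 → nobody) that a transport layer would act on.

## Problem sizes and numerical choices

The default test conditions are the study conditions: 2,039 records split
690 / 682 / 667, separation 2.0, learning rates 0.70 and 0.80. Heavier
properties run at sizes chosen to be statistically decisive yet quick on a
single CPU: feature-selection recovery uses 600 records with 5 planted
informative and 15 noise features over 10 seeds; the end-to-end accuracy
property uses 600 records over 10 seeds; the epoch-direction comparison
(50 vs 100 epochs) uses 400 records over 5 seeds; optimizer benchmarks use
the 10-dimensional sphere with a 3,000-evaluation budget over 20 seeds.

Numerical conventions worth knowing: zero-variance columns get unit scale
(with a warning) rather than an error; PCA retains at least one component
regardless of thresholds; all probability outputs are renormalized only
through the softmax (no clipping except a $10^{-12}$ floor inside the
cross-entropy); metric 0/0 cells are 0; fitness ties in HTLSS keep the
incumbent (strict-improvement acceptance) and teacher ties break toward
the earlier index.

## Limitations

The synthetic generator's Gaussian class structure is easier than real
accelerometry; accuracy numbers on it characterize the pipeline, not a
device. The recurrent branches process features as pseudo-sequences, so
their temporal machinery only becomes meaningful on the windowed path.
Training is CPU-bound R; the defaults are sized for hundreds-to-thousands
of records, not millions. The ledger is single-writer and unencrypted by
design.
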