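---
title: "Mortality risk from irregular ICU event streams: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mortality risk from irregular ICU event streams: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Intensive-care records are event streams: infusion events (`itemid`,
`starttime`, `endtime`, `rate`, `totalamount`) arrive at irregular times,
vitals are charted at other irregular times, and a large fraction of numeric
fields is simply missing. Predicting in-hospital mortality from such data
requires three things that ordinary feed-forward or even vanilla recurrent
models do not provide:

1. a representation of *which* drug an event is that reflects clinical
   relatedness (heparin belongs near other haematology fluids),
2. a principled way to fill missing numeric values and to read a value for an
   arbitrary time interval off an irregular series, and
3. a recurrent cell that consumes the *event time itself* rather than
   assuming evenly spaced steps.

`icurisk` implements this pipeline: word2vec-style embeddings over the drug
vocabulary reduced by PCA, per-patient per-channel Gaussian-process (GP)
regression for imputation and regular resampling, and a peephole LSTM /
Phased-LSTM classifier trained by backpropagation through time, evaluated by
MCC, precision/recall and ROC/AUC. Protected clinical data are not required
anywhere: a synthetic cohort generator with stored ground truth stands in for
a real extract, and any real extract with the same three CSV tables can be
ingested instead.

# The synthetic cohort generator

`sim_config()` / `simulate_cohort()` emulate a fluid-event extract:

* **Drug vocabulary with co-therapy structure.** `n_items` (60) drugs are
  partitioned into `n_groups` (6) groups; each patient is assigned 1–3
  groups and draws each event's drug from the assigned groups with
  probability 0.9, else uniformly. Group 1 is the designated *risk group*,
  and `exposure` is the fraction of a patient's events drawn from it. This
  is the co-occurrence structure the embedding stage must recover.
* **Event times and quantities.** Event start times are uniform on the
  72-hour window; durations are exponential (mean 2 h), truncated at the
  horizon; intervals are half-open `[start, end)`. Log infusion rate is a
  drug-level offset plus a smooth per-patient titration curve (an SE-GP with
  a 16 h length-scale) plus noise; bag totals likewise. Titration gives the
  event-level channels temporal structure, as real infusion records have.
* **Vitals.** Each channel (body temperature, pulse rate, respiration rate,
  blood pressure) is a latent smooth curve — an SE-kernel GP draw on a
  regular 2 h grid (so the imputer's model is correctly specified in this
  regime; a `vitals_mode = "sinusoid"` alternative exists for
  misspecification checks) — shifted by an exposure-linked level
  (e.g. pulse `78 + 30·exposure`), thinned to irregular timestamps (each
  grid point kept with probability 0.7) and measured with channel-specific
  noise. Sicker patients therefore *look* sicker in their vitals, which is
  what lets imputation quality matter downstream.
* **Labels.** `P(death) = sigmoid(base_rate + effect_size · exposure)`,
  drawn once per patient. Ground truth (latent curves, pre-mask values,
  group assignments, exposures, label probabilities) is stored alongside.
* **Missingness.** Every numeric field is masked independently (MCAR) with
  probability `missing_rate` (0.3). No informative-missingness mechanism is
  modelled.

**Calibration of the label model.** `effect_size = 8`, `base_rate = -4.5`
were fixed once, by a small design simulation run before the package was
built: with the group-assignment scheme above they give an in-hospital death
rate of ≈ 11.5% — the rate typical of adult ICU cohorts — while an oracle
that sees exposure and the vitals shift attains AUC ≈ 0.92–0.96, i.e. the
outcome is learnable but individually stochastic. These defaults are the
package's reference study conditions and are not tuned per experiment.

**What the generator does not emulate.** Real extracts have informative
missingness, multi-admission patients, thousands of item codes with heavy
tails, charting artefacts, and outcome mechanisms far richer than a single
exposure logit. Passing the package's tests therefore demonstrates the
*machinery* (correct GP algebra, correct gradients, recoverable structure),
not clinical performance.

# Gaussian-process imputation

Each patient × channel series is modelled independently (series are never
pooled across patients) as \(y = f(x) + \varepsilon\),
\(f \sim GP(m, k_{SE})\), \(\varepsilon \sim N(0, \sigma_n^2)\), with the
squared-exponential kernel
\(k_{SE}(x, x') = \sigma_f^2 \exp(-(x-x')^2 / 2\ell^2)\). The mean function
is the constant training mean, subtracted before conditioning and added back
at prediction. The posterior mean
\(\bar f_* = k(x_*, x)(K+\sigma_n^2 I)^{-1} y\) fills missing values and,
evaluated on the grid \(\{0, s, 2s, \dots\}\), turns an irregular series
into a regular one; event features then take the mean of the grid values in
`[starttime, endtime)` (nearest grid point if the interval is empty).

Hyperparameters \((\sigma_f^2, \ell, \sigma_n^2)\) are fitted by minimising
the negative log marginal likelihood with L-BFGS-B and the analytic
gradient \(\partial L/\partial\theta_i = \tfrac12 \mathrm{tr}[(K^{-1} -
\alpha\alpha^\top)\,\partial K/\partial\theta_i]\).

Numerical choices:

* optimisation in **log-parameter space** (positivity for free), bounded
  away from degenerate values relative to the data scale;
* **multi-start** (3 by default; cohort-scale imputation uses 1 start and a
  50-iteration cap, which is accurate enough for imputation at a fraction of
  the cost), with seeded jitter around a data-driven initialisation
  (\(\sigma_f^2 = \mathrm{var}(y)\), \(\ell = 3\times\) median spacing);
* a **jitter** of \(10^{-8}\sigma_f^2\) on the diagonal keeps the Cholesky
  factorisation positive definite; with \(\sigma_n^2 = 0\) this bounds how
  exactly the posterior can interpolate — near-duplicate timestamps at long
  length-scales are mathematically ill-posed without it;
* series with **fewer than 3 distinct timestamps** cannot identify the
  hyperparameters and fall back to defaults with a warning flag; series with
  **zero observations** are filled with the cohort-level channel mean.

Baselines `mean_substitution`, `locf` and `linear` mirror the standard
comparison set. `compare_imputers()` scores every masked value against the
stored truth; because channels live on different scales, errors are
standardised by the per-series truth standard deviation before pooling, and
"precision" is the fraction of imputed points within `0.1 × sd` of the truth
(the within-δ operationalisation; δ is configurable).

# Event representation

Each patient's drug tokens, ordered by start time, form a document; the
cohort is the corpus. A multi-word item name ("Sodium Chloride 0.9%") is one
token. `train_embedding()` implements word2vec with a full-softmax objective
— exact and affordable at these vocabulary sizes — plus an optional
negative-sampling objective; CBOW (context predicts centre) is the default,
Skip-Gram (centre predicts context) the alternative, both in their standard
literature definitions. Learning rate decays linearly; everything is
deterministic given the seed.

The embedding is centred and reduced by PCA (`stats::prcomp`). The event
vector is `[reduced embedding (p), totalamount, rate, body_temperature,
pulse_rate, respiration_rate, blood_pressure]`, so its length is `p + 6`;
with `p = 99` this is the 105-input configuration of the reference
architecture. Note a rank constraint: `p` cannot exceed `V − 1` for a
`V`-token vocabulary, so on the default synthetic cohort (60 items) the
pipeline clamps `p` to 59 and the event vector has length 65; the 105-input
figure is reachable only with vocabularies of 100+ items.

Sequences are padded at the end (or truncated) to `L`, the 95th percentile
of cohort event counts, with a validity mask; padded steps never touch the
state or the loss. Patients with zero events cannot form a sequence and are
dropped with a warning at assembly.

# Sequence models

The peephole LSTM step is implemented exactly as:

\[
\begin{aligned}
i_t &= \sigma(W_{xi}x_t + W_{hi}h_{t-1} + w_{ci}\odot c_{t-1} + b_i)\\
f_t &= \sigma(W_{xf}x_t + W_{hf}h_{t-1} + w_{cf}\odot c_{t-1} + b_f)\\
c_t &= f_t\odot c_{t-1} + i_t\odot\tanh(W_{xc}x_t + W_{hc}h_{t-1} + b_c)\\
o_t &= \sigma(W_{xo}x_t + W_{ho}h_{t-1} + w_{co}\odot c_{t-1} + b_o)\\
h_t &= o_t\odot\tanh(c_t)
\end{aligned}
\]

The output gate's peephole deliberately reads \(c_{t-1}\) rather than the
canonical \(c_t\); this follows the reference formulation and has the
convenient side effect that all four pre-activations are functions of
\((x_t, h_{t-1}, c_{t-1})\), so the step vectorises as one fused matrix
product per gate block.

The Phased-LSTM adds a periodic time gate per hidden unit. With phase
\(\phi_t = ((t - s) \bmod \tau)/\tau\), the openness is the three-phase
schedule

\[
k_t = \begin{cases}
2\phi_t/r_{on} & \phi_t < r_{on}/2\\
2 - 2\phi_t/r_{on} & r_{on}/2 \le \phi_t < r_{on}\\
\alpha\,\phi_t & \text{otherwise,}
\end{cases}
\]

and the update blends proposed and previous state:
\(c_t = k_t\odot c^*_t + (1-k_t)\odot c_{t-1}\), likewise for \(h_t\). A
fully open gate (\(k_t \equiv 1\)) reduces the cell to the plain LSTM to
machine precision — a reduction the tests exploit. A **masked (padded) step
is exactly \(k_t = 0\)**: one mechanism implements both the time gate and
padding for both cell types.

Gate parameters: periods initialised log-uniform over `[1, horizon]` hours
(the bank of units covers short and long rhythms), shifts uniform over
`[0, τ)`; `r_on = 0.1` and leak `α = 0.001` are fixed, while `τ` and `s`
are trainable by default (in log-/raw-space respectively), with the exact
piecewise gradient `dk/dφ` per branch and
\(\partial\phi/\partial\log\tau = -(t-s)/\tau\),
\(\partial\phi/\partial s = -1/\tau\). The gate is non-differentiable on
branch boundaries (a measure-zero set); finite-difference checks avoid it
automatically in practice.

Training: the default loss is **MSE between the softmax output and the
one-hot label** — unusual for classification but retained as the reference
setup; cross-entropy is available. Gradients are full BPTT (verified against
central finite differences to < 1e-4 relative error on every parameter,
including gate periods and shifts); the optimiser is Adam (lr 0.01 default)
or plain SGD. Features are standardised with training-split statistics
stored in the model; event times stay in hours so gate periods keep
physical units. When a validation split is supplied the returned model
carries the weights of the epoch with the lowest validation loss (standard
early-stopping-style selection; `keep_best = FALSE` disables it). The output
head maps the final hidden state through a max-subtracted softmax to
`[p(survival), p(death)]`, and a patient is classified dead iff
`p(death) > p(survival)` (ties go to survival). Death is coded 1 and is the
positive class throughout; the reference text states both codings in
different places, and this is the convention consistent with its
precision/recall tables.

The reference architecture is 2 × 310 hidden units; desk-scale runs and the
package's own experiments use 8–16 units, which the synthetic task does not
benefit from exceeding. Whether both stacked layers should be phased is not
specified anywhere; both are phased here. The time fed to the gate is the
event's `starttime`.

# Evaluation

`split_data()` partitions 60/20/20 (train/validation/test), stratified by
outcome so small splits keep the cohort death rate; within each stratum
sizes follow largest-remainder rounding. MCC uses the standard formula with
any zero denominator factor mapped to 0; it equals the Pearson correlation
of the two binary vectors, which the tests assert directly. ROC curves come
from a descending threshold sweep with tied scores grouped, prepended (0,0)
and appended (1,1); AUC is trapezoidal and equals the normalised
Mann–Whitney U statistic (also asserted, and cross-checked against pROC).
Precision/recall use death as the positive class with 0/0 → 0 plus a
warning. Accuracy is reported as a bonus metric.

# Reproducibility and problem sizes

Every stochastic operation takes a seed; the pipeline derives stage seeds
from one global seed by hashing the stage name, so stages can be re-run in
isolation and two `run_pipeline()` calls with the same config produce
byte-identical persisted reports. Artifacts (cohort tables, embedding,
imputed tables, model, report) are plain CSV/JSON with JSON sidecars naming
the producing stage, seed and config hash.

The package's reference experiment — run by `scripts/acceptance.R` and the
acceptance tests — uses the default cohort (500 patients, ≈ 40 events each,
72 h window), a Phased-LSTM with 16 hidden units in 2 layers trained for 100
epochs, and 3 replicate seeds; imputer comparison scores ≈ 27k masked
values; GP length-scale recovery uses n = 200 with 20 replicates. These
sizes were chosen as the smallest at which the respective quantities are
stable.

# Known limitations

* **The with/without-imputation contrast is weak on synthetic data.** Under
  the stated label rule, outcome-relevant information enters vitals only
  through an exposure-linked *level*, which a per-patient series mean —
  i.e. mean substitution — largely preserves. GP imputation reconstructs
  masked values far better (see `compare_imputers()`), but the downstream
  AUC difference is small relative to test-split noise at n = 500, and its
  sign can flip between seeds. A larger real-data advantage would require
  temporally structured outcome mechanisms the generator does not model.
* MCAR only; no informative missingness.
* Posterior variances are computed but not propagated into the classifier.
* One admission per patient; no cohort-selection modelling.
* Full-softmax word2vec scales linearly in vocabulary size; for
  MIMIC-scale vocabularies use the negative-sampling option.
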