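# icurisk

Mortality-risk modelling for irregularly sampled ICU event streams.

Critical-care records are awkward for sequence models: medication events
(`itemid`, `starttime`, `endtime`, `rate`, `totalamount`) and vitals arrive
at irregular times, and a large share of the numeric fields is missing.
`icurisk` implements an end-to-end pipeline for predicting in-hospital
mortality from such streams, for researchers who want a tested, fully
reproducible reference implementation that runs without access to protected
clinical data:

* **Semantic event representation** — each drug token is a "word", each
  patient's time-ordered events a "document"; a word2vec model (CBOW or
  Skip-Gram, full-softmax or negative sampling) embeds the vocabulary and
  PCA reduces it. The event vector is the reduced embedding plus six
  numeric channels (`totalamount`, `rate`, body temperature, pulse rate,
  respiration rate, blood pressure), length `p + 6`.
* **Gaussian-process imputation** — one SE-kernel GP per patient per
  channel, `k(x,x') = σ_f² exp(−(x−x')²/2ℓ²)`, hyperparameters fitted by
  maximum marginal likelihood (L-BFGS-B on log-parameters with the analytic
  gradient). The posterior mean fills missing values and resamples each
  irregular series onto a regular grid; mean-substitution, LOCF and linear
  interpolation are provided as baselines.
* **Phased-LSTM classifier** — a peephole LSTM whose state updates are
  modulated by a per-unit periodic time gate
  `k_t = f(φ_t; r_on, α)`, `φ_t = ((t−s) mod τ)/τ`, so the cell consumes
  real event times; gates blend `c_t = k_t c*_t + (1−k_t) c_{t−1}`.
  Trained by backpropagation through time (finite-difference-verified
  gradients) with Adam, MSE-on-softmax loss by default.
* **Evaluation** — stratified 60/20/20 splits, Matthews correlation
  coefficient (the binary Pearson correlation), precision/recall with death
  as the positive class, ROC by threshold sweep and trapezoidal AUC (equal
  to the normalised Mann–Whitney U).
* **Synthetic EHR generator** — MIMIC-shaped cohorts with latent co-therapy
  group structure, smooth latent vitals, MCAR missingness and a known
  label rule `P(death) = sigmoid(base_rate + effect_size · exposure)`, with
  full ground truth retained so every stage is scorable.

See the methods vignette (`vignettes/mortality-risk-pipeline.Rmd`) for the
models, the numerical choices and the design rationale.

## Worked example

The whole pipeline — simulate, embed, impute, assemble, split, train,
evaluate — runs from one config (about 90 seconds on one CPU):

```r
library(icurisk)

cfg <- pipeline_config(
  sim = sim_config(),                     # 500 patients, 72 h window, 30% MCAR
  model = model_config(cell = "phased_lstm", hidden_size = 16, layers = 2,
                       epochs = 100, lr = 0.01, batch_size = 64, horizon = 72),
  imputation_method = "gp",
  seed = 42)

res <- run_pipeline(cfg, out_dir = "artifacts")
print(res$report)
#> evaluation on 100 patients: MCC 0.5155, precision 0.5000, recall 0.6923, AUC 0.8700
#>   counts: TP 9  TN 78  FP 9  FN 4
```

The held-out test split has 100 patients; the Phased-LSTM separates
deceased from surviving patients with AUC 0.87, and at the
`p(death) > p(survival)` operating point recalls 9 of the 13 deaths (MCC
0.52). The embedding recovers the latent co-therapy groups — the nearest
neighbours of a risk-group drug are drugs from the same group:

```r
emb <- read_embedding(file.path("artifacts", "embedding.csv"))
nearest_neighbors("drug_003", emb, k = 3)
#>      token similarity
#> 1 drug_007  0.9976679
#> 2 drug_010  0.9969276
#> 3 drug_004  0.9968308
```

And scoring imputers against the generator's ground truth (errors
standardised per series; "precision" = fraction of masked points recovered
within 0.1 sd):

```r
cohort <- simulate_cohort(cfg$sim)
compare_imputers(cohort, methods = c("gp", "mean_substitution", "locf"),
                 seed = 1)
#>              method      rmse  precision n_points
#> 1                gp 0.7105480 0.13995936    27558
#> 2              locf 0.8885966 0.10664780    27558
#> 3 mean_substitution 1.0216055 0.06919951    27558
```

GP imputation reconstructs masked values with the lowest error, reproducing
the expected ordering over the simple baselines.

A thin command-line front end over the same functions ships in
`inst/cli/icurisk`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/icurisk", package="icurisk"))')
Rscript $CLI simulate --out tables --seed 7
Rscript $CLI run-all --out artifacts --seed 7 --cell phased_lstm
```

Real extracts can be ingested by exporting the three tables
(`inputevents.csv`, `vitals.csv`, `labels.csv`; schema in
`?read_cohort_tables`) and running `validate`/`embed`/`impute`/`train`
against that directory.

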