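# wellcast

One-day-forward wellness forecasting for elderly subjects from short
single-lead ECG recordings.

## The problem

In daily monitoring of community-dwelling elderly people, each subject
records a short (20–25 s, 500 Hz) single-lead ECG and reports a
self-evaluated health index (HI, ordinal 1–5) every day. `wellcast` builds
and evaluates classifiers that use only day *d*'s ECG to forecast whether
day *d + 1* will be a **better** or **worse** day for that subject —
advance warning that lets caregivers intervene before a bad day.

The pipeline:

1. **Denoise** — exponentially weighted moving average (EWMA), window
   `n = 40` samples, weights `∝ (1 − α)^k` with `α = 2/(1 + n)`,
   normalized to unit DC gain.
2. **Segment** — 5 s sliding windows with 1 s stride (a 20 s trace yields
   15 segments), each min–max scaled to [0, 1].
3. **Label** — per subject, HI scores are transformed with the rank-based
   inverse-normal (Fisher–Yates) map `Φ⁻¹(r/(I+1))`, which removes skew
   and subject scoring bias; scores > 0 become *better* (0), otherwise
   *worse* (1); each day's segments inherit the **next** day's condition.
4. **Classify** — four families: LSTM and bidirectional LSTM (built from
   the gate equations with hand-derived backpropagation), a
   single-hidden-layer sigmoid ANN, and a soft-margin RBF-kernel SVM
   (`C = 10`, `Γ = 0.01`, `Γ = 1/2σ²`), trained under the binary
   cross-entropy objective.
5. **Evaluate** — recall, precision, false-positive rate, accuracy,
   F-score (percent, worse = positive class) and ROC/AUC, with k-fold
   cross-validation grouped by subject-day so overlapping windows never
   leak across a split.

Because real cohorts of this kind are private, the package includes a
first-class synthetic cohort generator: AR(1) latent wellness per subject,
skewed ordinal scores with subject-specific cut-points, and quasi-periodic
five-wave ECG beats with amplitude lability, baseline wander and
high-frequency noise. The next-day link is constructed through a
heart-rate shift with tunable effect size, so recovery can be verified
against ground truth and calibrated against a zero-effect null.

## Worked example

```r
library(wellcast)

coh <- generate_cohort(cohort_config(n_subjects = 4, n_days = 40,
                                     effect_size = 2, seed = 42))
ds  <- build_dataset(coh)
ds
#> wellcast labeled dataset: 2647 segments x 2500 samples; 156 subject-days; 1320 worse / 1327 better

sp  <- grouped_holdout_split(ds$group, ds$y, test_frac = 0.3, seed = 42)
fit <- train_model("bilstm", ds$x[sp$train, ], ds$y[sp$train],
                   hidden_size = 32,
                   config = train_config(learning_rate = 0.3,
                                         decay_factor = 0.5, patience = 5,
                                         epochs = 50, seed = 42))

mean(predict(fit, ds$x[sp$test, ]) == ds$y[sp$test])
#> [1] 0.8769231
roc_and_auc(ds$y[sp$test], predict(fit, ds$x[sp$test, ], type = "score"))$auc
#> [1] 0.9514444
```

About 88% of held-out segments are classified into the correct next-day
condition and the worse-class score ranks a random worse day above a
random better day about 95% of the time — on a cohort whose constructed
heart-rate link (8 bpm class separation) the model has recovered from raw
scaled segments. With `effect_size = 0` the same pipeline sits at chance,
as it must.

See the vignette (`vignettes/wellness-forecasting.Rmd`) for the model
equations, generator design, and the reasoning behind every default.

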