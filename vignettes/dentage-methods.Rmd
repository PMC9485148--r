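---
title: "Models and methods in dentage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in dentage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

dentage estimates chronological age in juveniles (2–18 years) from the
Demirjian mineralization stages (A–H) of the seven left mandibular
permanent teeth, and provides the statistical machinery that
comparative dental-age studies use around such estimators. This
vignette documents the models, the tunable parameters, the synthetic
cohort generator, and the numerical and design choices, so that a
maintainer can see *why* the package behaves as it does rather than
only what it computes.

## Score-table estimators

A score table maps each (tooth, stage) cell to a number. Two kinds are
supported:

- **Age-sum (Willems-type).** Scores are in years and the dental age is
  the plain sum over the seven teeth, DA = Σₜ s(t, stageₜ). No
  conversion step; the table *is* the model.
- **Maturity (Demirjian-type).** Scores are maturity points; the summed
  maturity score M is mapped to an age through a sex-specific monotone
  conversion curve, represented as interpolation knots (score, age) and
  evaluated piecewise-linearly. Outside the knot range the age is
  clamped to the endpoint value and the estimate is flagged rather than
  extrapolated: conversion curves are only defined on the score range
  they were built from.

Published tables print dashes for stages never observed in their
source population — typically early stages that complete before the
cohort's entry age. Those cells are *absent* here: looking one up is an
error naming the (tooth, stage) pair, never a silent zero. Absent is
distinct from *missing* (an unscorable tooth in a subject): the default
missing-tooth policy is also a hard error, because the summation model
presumes seven scores; an opt-in `on_missing = "skip"` policy sums the
scorable teeth and marks the estimate `partial` for exploratory use.

The package ships one set of tables — the sex-specific southern-China
reweighted age-sum tables — because those are the only tables whose
full cell values the package can vouch for. The original Willems and
Demirjian scores and the Demirjian conversion curves are published
elsewhere and load from the documented JSON formats
(`read_score_table()`, `read_maturity_conversion()`).

## Non-intercept reweighting

The reweighting procedure regresses chronological age on stage-score
predictors *without an intercept*, per sex, and turns the coefficients
back into an age-sum table. Forcing the fit through the origin keeps
the model interpretable as a score table: with an intercept, the
per-cell scores would no longer sum to an age on their own.

Two design strategies are implemented because the procedure is
genuinely ambiguous:

- **`per_tooth`** — seven columns, column t holding the base table's
  score for tooth t's attained stage; the coefficients bₜ are per-tooth
  scale factors. This is the literal reading of "reweighting each
  tooth's parameters", but a single positive scale factor cannot change
  the sign structure within a tooth's row, which published modified
  tables exhibit (e.g. a first-bicuspid row running from −1.10 to
  +2.53).
- **`per_cell`** (default) — one 0/1 indicator column per (tooth,
  stage) cell observed in the fitting data; the coefficients *are* the
  new cell scores, and unobserved cells stay absent, which is exactly
  how dashed cells plausibly arise.

**Identifiability and the minimum-norm solution.** The per-cell design
is structurally rank-deficient: for every tooth, its indicator columns
sum to the all-ones vector, so any two teeth's column sums coincide —
six exact linear dependencies among the 7 column groups. Consequently
the individual cell scores are only identified up to shifts that move a
constant from one tooth's row to another's; all such tables give
identical predictions. The package resolves this by solving the
per-cell fit with the SVD pseudoinverse (minimum-norm least squares):
predictions, residuals and the residual orthogonality X′r = 0 are those
of any least-squares solution, and the reported table is the canonical
minimum-norm representative. The `per_tooth` design is full rank and
uses a QR solve; a genuinely singular QR fit is an error listing the
aliased columns. This is also why "recovering the generating table"
only makes sense for tables already in the design's row space: the test
suite checks exact recovery by idempotence (a refit of a refit
reproduces every observed cell to 1e-8) plus exact reproduction of the
generating ages, which together pin down everything that is
statistically identifiable.

`residual_sd` is reported on n − rank degrees of freedom. No
regularization is applied anywhere — the procedure is plain least
squares.

## Native learners

All learners use the same features: sex (0 female, 1 male) and the
seven stages coded ordinally A = 1 … H = 8, missing = 0. The ordinal
encoding (rather than one-hot) reflects that staging is ordered and
lets trees split on thresholds; missing sorts below A.

**CART.** Squared-error regression tree with best-first growth: at each
step the frontier leaf whose best split gives the greatest decrease in
summed squared error is expanded. Best-first is the only standard way
to honour a leaf budget (`max_leaf_nodes`, default 50) together with a
depth limit (default 10). Candidate thresholds are midpoints between
consecutive distinct feature values; ties in impurity decrease break
toward the lower feature index, then the lower threshold, and ties
between frontier leaves toward the earlier-created node — so the fit is
fully deterministic. A split must decrease the summed squared error by
more than 1e-10 (on top of the configured `min_impurity_decrease`,
default 0) to be admitted; this guards against float-noise splits of
constant leaves. Default `min_leaf` is 2 for the standalone tree and
the AdaBoost base tree, and 1 for forest/GBDT base trees, following the
convention that bagged and boosted trees are grown deeper.

**GBDT.** F₀ = mean(y); round m fits a CART tree to the residuals
y − Fₘ₋₁(X) and Fₘ = Fₘ₋₁ + ν·hₘ with learning rate ν = 0.1 over 100
rounds, subsampling disabled by default. Because each tree minimizes
squared error on the current residuals and ν ≤ 1, the training MSE is
nonincreasing in m; the per-round MSE path is stored on the model and
asserted in the tests.

**Random forest / extra trees.** 100 trees, averaged. The
random-forest variant draws a bootstrap resample per tree and uses
exhaustive split search; the extra-trees variant fits on the full
sample with one uniformly random threshold per candidate feature. No
feature subsampling by default (`mtry` = all 8 features; the feature
space is small and the learners are compared against reference
libraries at the same setting). Both are deterministic given the seed.

**AdaBoost.R2.** Linear-loss variant with weighted resampling: each
round resamples n points with probability proportional to the weights,
fits the base tree, scales absolute errors by their maximum to get
per-sample losses Lᵢ and the weighted average loss L̄; β = L̄/(1 − L̄)
updates the weights (wᵢ ← wᵢ·β^(lr·(1−Lᵢ))) and the learner enters with
weight lr·log(1/β). A round with L̄ ≥ 0.5 stops boosting (kept only if
it is the first); a perfect round (max error < 1e-10) dominates the
ensemble and stops. One deliberate determinism choice: when the weights
are exactly uniform — always true in round 1 — the identity sample is
used instead of a resample, so a one-round ensemble reduces exactly to
its base tree. Prediction is the weighted median of the learners'
predictions, the standard aggregation for this variant.

**KNN.** Mean age of the k = 5 nearest training subjects by Euclidean
distance on the encoded features; ties at the k-th distance break by
training-set order (stable radix ordering), which is documented
behaviour rather than an accident.

Models serialize to versioned JSON (structure, thresholds, leaf values,
weights) with 17 significant digits, which round-trips IEEE doubles
exactly; a reloaded model reproduces bit-identical predictions.

## Evaluation battery

Per subject, the age deviation is AD = DA − CA; positive means
overestimation. Summary reports give mean (sd) of CA, DA and AD per
method and sex, the paired t-test of DA against CA
(t = mean(AD)/(sd(AD)/√n), df = n − 1, two-sided, with the three
conventional significance tiers and the raw p), and MAE restricted to
CA below a cap (18 or 16 years — CA-based filtering). Learner reports
give MSE = mean(AD²), RMSE = √MSE, MAE, and
R² = 1 − Σ AD²/Σ (CA − mean CA)², the coefficient of determination of
predictions against truth, the standard regression-report convention.
All standard deviations use the n − 1 denominator. Cohen's kappa is
unweighted by default (a linear-weighted variant is available behind a
flag, appropriate for ordinal stages). Per-age-group MAE uses the
half-open one-year bins; empty bins are omitted, not reported as zero.

## The synthetic cohort generator

The study population behind the built-in tables is not publicly
deposited, so the package includes a generator whose cohorts have known
ground truth and the reference size/age structure (n = 1477, 833
female / 644 male, one-year bins over 2.00–17.99 with the reference
per-bin counts; ages uniform within bins, since only bin counts are
known).

Mechanism, per subject:

1. a shared developmental tempo offset δ ~ Normal(0, `offset_sd`);
2. a developmental profile: with probability `lag_prob` the posterior
   tooth field (34–37) lags the anterior field (31–33) by `lag_years`;
3. per tooth, independent jitter ε ~ Normal(0, `jitter_sd`);
4. the attained stage is the highest stage s whose attainment age
   τₛ is at most the tooth's effective age (age + δ + ε − lag), never
   below the tooth's first in-range stage, capped at H.

The attainment ages τ are spaced along a fast-early, slow-late power
curve per tooth (crown stages pass quickly, root completion drags),
with anterior teeth and the first molar completing around 9–11 years
and the second molar around 16; female trajectories run 0.35 years
earlier than male. Stages completed before age 2 have undefined τ, and
subjects are never observed below the first in-range stage — the
generative meaning of a dashed early cell, and the reason synthetic
cohorts never hit absent cells of the built-in tables.

Defaults (version 1, `inst/extdata/maturation_params_v1.csv`):
`offset_sd` = 0.20 y, `jitter_sd` = 0.25 y, `lag_years` = 3.5,
`lag_prob` = 0.5. These are synthetic calibration constants, not
population estimates, chosen once so that (a) a per-cell refit score
model operates in the 0.5–1.1-year MAE band that comparative studies
report for calibrated linear score models, and (b) gradient boosting
improves on the linear model out of sample — the qualitative ordering
such studies find.

**Why the asynchrony mixture exists.** Under a pure threshold-crossing
model (steps 1, 3, 4 only), the conditional mean of age given the full
stage pattern turns out to be almost exactly additive across teeth:
large-sample pattern-lookup estimates beat the best additive fit by at
most a few hundredths of a year across a wide range of spacings and
noise models. In such data an additive per-cell score model is
near-optimal, and no tree ensemble can reliably beat it at cohort
scale. Real staged-tooth data is richer than this — the literature's
boosting gains imply joint-pattern information that additive scores
cannot capture. The two-profile mixture restores exactly that: the
anterior/posterior discrepancy identifies a subject's profile, and the
correct reading of the posterior stages depends on it — an interaction
no additive score table can represent, but a shallow tree interaction
learns easily. The lag magnitude is deliberately large so that the
effect is detectable at n ≈ 1500; it should be read as "joint-pattern
information of the strength real data evidently carries", not as an
anatomical estimate of asynchrony prevalence.

`generate_from_score_table()` reuses the stage mechanism but *sets*
CA = Σ scores + Normal(0, `noise_sd`), so the cohort exactly satisfies
the additive model — the fixture for refit-recovery tests. Its ages may
fall outside the 2–18 screening range; it is a regression fixture, not
a screened cohort. Patterns hitting an absent cell of the supplied
table are redrawn (bounded retries) or raise an error, per flag.

**What the generator does not emulate** — and hence what passing tests
do and do not show about real data: no rater misgrading (stages are
read off the latent process without error, so kappa checks use
separately simulated ratings); no secular or ethnic heterogeneity; ages
uniform within bins rather than following a within-bin density; tooth
agenesis/missing teeth absent by default; and the true form of the
joint-pattern information in real cohorts is unknown — the mixture is
one plausible shape of it. Results on synthetic cohorts validate the
*machinery* (estimators, refitting, learners, metrics, determinism),
not population-specific accuracy claims.

## Pipeline and reproducibility

`run_study()` mirrors the usual study design: score models are
evaluated on the full cohort (as calibration tables are in practice),
learners on a seeded 3:1 train/test split, trained on the training
split only — test metrics never touch training rows, and the split
membership is recorded on the result. One global seed fans out to
stage-specific derived seeds (seed·1000 + a fixed per-stage offset,
kept below 2³¹), so cohort generation, splitting and each learner's
randomness are independently reproducible. Reports are written as CSV
plus a JSON manifest with file checksums; two runs with the same seed
produce byte-identical metric reports (timings live only in the
manifest). The training-set size is round-half-up of n·ratio; the
ratio defaults to 3:1 but is a parameter, since reported split sizes
in the literature do not always match the stated ratio.

Problem sizes in the packaged test suite are chosen to exercise every
code path at desk scale: oracle comparisons on a 1000-subject cohort,
ensemble identities on 200 points, the study-ordering replication on
ten full-size (n = 1477) cohorts, metric property checks on 1000
random draws. The full suite runs in well under five minutes on one
core.

## Known limitations

- The package does not ship Willems/Demirjian original tables; users
  must supply them, and any comparison labelled "willems"/"demirjian"
  is only as good as the supplied files.
- The per-cell refit reports the minimum-norm representative of an
  under-determined table; individual cell values should not be
  over-interpreted (sums across teeth are what is identified).
- Score-table estimation requires every attained stage to have a
  defined cell; cohorts far from a table's source population can hit
  absent cells, which is surfaced as an error rather than imputed.
- The ensemble learners implement the classic algorithms at fixed
  published hyperparameters; they are not tuned, and no uncertainty
  quantification (bootstrap CIs, conformal intervals) is provided.
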