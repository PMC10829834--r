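---
title: "Methods: a two-view gut microbiome aging clock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a two-view gut microbiome aging clock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A gut microbiome aging clock is a regression model that predicts a
person's chronological age from their stool metagenome, and whose
prediction is read as a *biological* age (gAge): a systematically high
prediction suggests an "older-than-years" gut ecosystem. `gutclock`
builds such clocks from two feature modalities ("views") of the same
metagenome — species relative abundances (MetaPhlAn-style merged tables)
and metabolic-pathway relative abundances (HUMAnN-style tables) — and
interprets them with accumulated local effects (ALE) to extract
directional marker features. The downstream layer relates gAge and its
age-independent residual to frailty and disease phenotypes.

# The model

## Two-view stacking with unpaired samples

Each view is Z-score standardized (per feature, on that view's training
samples) and a zoo of heterogeneous base regressors is fitted per view:
by default `lr`, `lasso`, `ridge`, `enet` (glmnet; lambda by internal
5-fold cross-validation), `tree` (CART), `rf` (ranger, 150 trees) and
`gbt` (xgboost, 80 rounds, depth 3, learning rate 0.1). The registry also
offers `knn`, `svml`, `svmr` and `bridge` (Bayesian ridge via evidence
maximization); the default subset was chosen for diversity across model
families at a runtime that keeps repeated cross-validation practical on a
single core. One boosted-tree learner represents the gradient-boosting
family.

The stacking layer is deliberately literal: every base model of every
view contributes one out-of-fold prediction column for the *paired*
samples (those carrying both views), and an unregularized ordinary least
squares fit with intercept on those columns learns the meta-weights.
Per-view meta-weights are fitted alongside from the same columns, giving
single-view clocks used for comparisons and as an explicit single-view
prediction fallback.

The central modeling decision is how unpaired samples enter: a sample
carrying only the pathway view joins the training pool of every
*pathway* base model, but never the meta fit and never an evaluation
fold. This is what lets the clock exploit heterogeneous public data in
which the two annotation layers rarely cover identical sample sets, and
it is the mechanism probed by `unpaired_experiment()`: paired samples
held fixed, pathway-only samples added along a grid, with the fold split
held identical across grid points so differences are attributable to the
added samples alone.

Evaluation (`evaluate_cv()`) splits only the paired samples into outer
folds (default scheme 10 x 5; the heavier studies in the tests and the
acceptance script use a single 5-fold pass, which is the problem size
that keeps a full run in minutes). R-squared is 1 - SSE/SST on held-out
samples and may be negative; MAE is in years.

## Confounder filtering

Geography confounds age in pooled public cohorts: some regions are
sampled only by age-restricted studies. After removing non-westernized
samples and mapping countries to regions, `recursive_cohort_elimination()`
repeats: fit two heterogeneous models (linear regression and a random
forest) of age on one-hot region labels; if the larger cross-validated
R-squared is below the threshold (default 0.001), stop; otherwise remove
the single cohort whose exclusion minimizes that criterion (ties broken
toward the smaller cohort, retaining more data). The greedy rule is this
package's choice — the elimination order is otherwise under-determined —
and the criterion aggregates the two models by maximum so that *all*
models must fall below the threshold. Negative cross-validated R-squared
values are not clamped.

## ALE interpretation and markers

First-order ALE is computed on the ensemble's full prediction path
(standardization, base models, meta layer), never on base models
separately. For one feature: empirical quantiles (default 40 intervals,
duplicate edges collapsed so a zero-inflated feature's zero mass is one
bin) define intervals; the local effect of an interval is the mean
prediction difference when the feature moves from the interval's lower
to upper edge with everything else held at each in-interval sample's own
values; local effects are accumulated and centered so the sample-weighted
mean is zero. A sample's effect is the centered curve interpolated at its
own value, and the "average effect" of a feature is the mean absolute
per-sample effect (matching a beeswarm-of-samples presentation; a
grid-mean mode is available).

A feature is a candidate age marker when its average effect exceeds
0.083 years — one month of predicted-age deviation — and it is present in
at least 1% of samples. Direction is the sign of the least-squares slope
of per-sample effect on feature value; a feature whose accumulated curve
rises and falls, with the minority movement carrying at least 25% of the
sample-weighted absolute movement, is labelled nonmonotone (the pattern
reported for leucine degradation: accelerating at low abundance,
mitigating at high). Note that the *centered* curve of any monotone
effect crosses zero, so reversal must be judged on local-effect signs,
not on curve signs.

## Residuals and associations

The prediction residual is predicted age minus the OLS fit of predicted
on chronological age; by construction it has exactly zero mean and zero
Pearson correlation with chronological age, so it isolates the
age-independent component of the clock. Associations use Spearman
correlation with Benjamini-Hochberg adjustment within each report,
Wilcoxon/Kruskal-Wallis for group contrasts, PERMANOVA (`vegan::adonis2`,
sequential sums of squares, confounders entered first, covariates present
in under half the samples dropped) for community-level effects, and
gradient-boosted classifiers/regressors on marker features for
discrimination tasks.

# The synthetic generator

Real inputs at the scale of the public corpus are out of reach for tests,
so `simulate_profiles()` generates data with the statistical structure
the analysis assumes, plus known ground truth:

* log-normal latent abundances with feature-specific baselines; zeros by
  independent Bernoulli masking (default rate 0.3); row closure to sum 1;
* per view, `n_markers_per_view` (default 20) marker features whose
  log-abundance changes by `effect_size` (default 0.03) per year of age,
  with a random sign per marker; markers sit at reduced baseline
  abundance, as the reported marker taxa do — this also keeps the
  compositional closure from leaking marker signal into bulk features,
  which would otherwise make "marker vs non-marker" ill-defined;
* a sparse random loading of species latents into pathway latents, so the
  views share signal without being redundant;
* cohorts with per-feature log-offsets; each cohort belongs to a country,
  countries cluster into regions. With `confound_strength > 0`,
  `n_confounded_cohorts` cohorts are their own region's only study and
  draw ages from a narrow window placed along the age range — the
  canonical region-age confound;
* a frailty latent `z(age) + frailty_loading * z(marker deviation) +
  noise`, where the marker deviation is the direction-weighted mean of
  the markers' age-independent noise: exactly the component a clock's
  residual can pick up; disease labels are logistic draws on marker
  noise with a mild age term;
* ages uniform on [18, 107] by default; `elderly_config()` restricts to
  [60, 100].

Defaults (400 paired samples, 120 species, 60 pathways, noise SD 2) give
a clock with 5-fold cross-validated R-squared around 0.5 and clear
headroom for the unpaired-data effect — the qualitative regime of pooled
public metagenomes. What the generator does *not* emulate: phylogenetic
correlation between taxa, realistic rank-abundance shapes, batch effects
beyond additive cohort offsets, and non-linear age trajectories; passing
tests therefore demonstrate correctness of the machinery under the
assumed structure, not performance on any real cohort.

# Numerical choices

* Shannon entropy in natural log (base configurable); richness counts
  strictly positive entries.
* Abundances stored as fractions summing to 1; readers convert from
  percent and renormalize (idempotent).
* Prevalence/abundance feature filtering returns an un-renormalized
  sub-composition, documented as such; the default is no filtering.
* PERMANOVA permutations default to 999 (free permutations of sample
  labels); permutation count and seed are recorded.
* Rank-deficient meta fits set the collinear coefficients to zero and
  record them in the model manifest; failed base learners are dropped
  with a warning and recorded.
* All randomness flows from explicit integer seeds through a documented
  derivation (`derive_seed`), so every stage is independently
  reproducible; the pipeline writes a resolved-config snapshot with a
  content hash.
* Standardization parameters are estimated from training samples only;
  constant features get unit scale and a flag.

# Known limitations

* At a few hundred training samples, flexible learners attribute small
  spurious ALE effects (on the order of `residual SD / sqrt(n)`, i.e.
  tenths of a year) to noise features. The one-month marker threshold is
  calibrated for corpus-scale studies; at desk scale marker *recall* is
  excellent but marker *precision* against planted truth is poor, and
  raising the threshold or using a sparse-linear-only zoo trades one for
  the other. Treat desk-scale marker lists as rankings, not as
  fixed-threshold discoveries.
* For the same reason, predicted gAge correlates *less* with a frailty
  latent than chronological age does whenever clock noise outweighs the
  latent's marker loading; the residual association is the robust
  desk-scale signal.
* The UMAP embedding is wired through the external `umap-learn` backend
  (via the `python` on the PATH) and is deterministic only per backend
  version.
* No hyperparameter search is performed; zoo settings are fixed,
  documented defaults.
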