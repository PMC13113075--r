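---
title: "Methods: hierarchical variance partitioning and subject-wise validation of vocal distress encoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical variance partitioning and subject-wise validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical model behind `vocpartition`, the
choices made where the design was genuinely open, what the synthetic-data
generator does and does not emulate, and the package's numerical
conventions.

## The data model

One row per 20 s vocal sample, nested as animal → growth phase → distress
condition → 60 s recording → sample (three samples per recording). Factors
are closed sets: four phases (farrowing, nursery, growing, finishing), six
conditions (normal, pain, hunger, thirst, cold, heat), two sexes. Not every
condition occurs in every phase: heat stress is absent in farrowing and
nursery, thirst in farrowing, and cold in growing and finishing. Ten
acoustic traits are carried (energy, duration, amplitude extrema, intensity,
pitch, formants F1–F4); **only pitch may be missing** — pitch tracking fails
in unvoiced or noisy segments, whereas the remaining descriptors are defined
for every sample. Tables with holes elsewhere are rejected at load so that
downstream stages can assume completeness.

Phase is stored as an ordered factor for reporting but enters all models as
an unordered categorical, since the shifts across phases are not assumed
monotone.

## Mixed model and variance decomposition

For each trait we fit, by REML (`lme4`),

y = β0 + β_sex + β_phase + β_condition + u_animal + u_recording + ε,

with independent Gaussian random intercepts for animal and for recording
nested in animal. The recording intercept exists to absorb the shared state
of the three samples cut from one 60 s test; omitting it would count that
shared variation as evidence three times over (pseudo-replication).
Analyses are trait-wise on observed cases, so pitch models use fewer rows
than the complete traits.

Quantities reported per trait:

* **ICC(animal)** = σ²_Animal / (σ²_Animal + σ²_Recording + σ²) — the
  recording term is included in the denominator whenever it is in the model.
* **Marginal/conditional R²** (Nakagawa form). The fixed-effect variance is
  the *population* variance (n denominator) of the fitted fixed-effect
  linear predictor over the analysis rows — the convention for this
  statistic — so R²m = var_f / (var_f + σ²_Animal + σ²_Recording + σ²) and
  R²c adds the random components to the numerator.
* **Drop-one ΔR²** per block (sex, phase, distress): R²m(full) − R²m(full
  minus block). Full and reduced fits are separate optimizations, so tiny
  negative differences can occur; these are clamped to zero and flagged
  rather than silently reported, because a negative "unique contribution"
  has no interpretation. Block p-values come from ML likelihood-ratio tests
  of the same comparisons, and BH-FDR is applied across the whole family of
  trait × block tests, not per trait.
* **Interaction selection**: the distress × phase term is fitted by ML (not
  REML, which is not comparable across fixed-effect structures) and retained
  only if the LRT has p < 0.05 *and* the AIC decreases. Structurally empty
  phase–condition cells make some interaction contrasts inestimable; the
  model is then fitted on the estimable subset and a design warning is set.
* **Residual ICC**: a companion estimate computed by removing the fixed
  effects with an ordinary linear model and fitting an intercept-only
  animal-intercept model to the residuals. It is not identical to the
  model-based ICC (the two-stage fit ignores uncertainty in the fixed
  effects) but agrees with it in ordering across traits, which is what it
  is used for.

Skewed traits (duration, energy) are log-transformed before modelling by
default; the switch is per-call (`log_transform`). Convergence failures are
raised as errors, never swallowed; singular fits (a variance estimated at
zero) are legitimate and allowed, since "no animal effect" is a hypothesis
of interest.

An independent oracle, the one-way balanced ANOVA method-of-moments
estimator (σ̂² = MS_within, σ̂²_Animal = (MS_between − MS_within)/n₀),
cross-checks the REML fit on balanced intercept-only designs, where the two
are mathematically equal.

## Subject-wise cross-validation

Folds are built over *animals*, never rows: all samples of an animal fall in
exactly one fold. A greedy heuristic assigns animals (largest first) to the
fold that minimises the squared per-class count excess, under a hard cap on
animals per fold — stratification can only be approximate under the
grouping constraint. Record-wise folds are available solely to demonstrate
the optimism they induce.

Within each training fold: numeric imputation by the training median,
categorical by the training mode, z-scaling (for the multinomial logistic
model) by training mean/SD; constant features are dropped with a warning.
Tree ensembles train unscaled. The fold object freezes these statistics so
the identical transformation is applied to held-out and permuted data.

Models, with fixed documented defaults (nested tuning is out of scope at
this problem size): multinomial logistic regression (`nnet::multinom`,
weight decay 0.01 on standardized features, balanced case weights), random
forest (`ranger`, 500 trees, probability forests), gradient boosting
(`xgboost`, 150 rounds, η = 0.1, depth 4). Probability argmax ties break by
the fixed class order (normal, pain, hunger, thirst, cold, heat) for
determinism. Metrics: balanced accuracy (mean per-class recall), macro-F1
(mean per-class F1, F1 := 0 when precision + recall = 0), per-class
precision/recall/F1/support, raw and row-normalized confusion matrices.
Feature specifications mirror the study's sensitivity variants: full
(acoustics + sex + phase), acoustics-only, pitch-excluded; complete-case
analysis is the same pipeline on the observed-pitch subset.

## Confusability and uncertainty

From pooled out-of-fold predictions: directional confusion C(a→b) (row
normalized), symmetric confusability S(a,b) = ½[C(a→b) + C(b→a)], and
per-sample entropy (natural log, so the 6-class maximum is ln 6 ≈ 1.792)
and margin (top minus second probability), summarized as median and IQR per
class and recomputed within each growth phase. Strata with fewer than two
represented classes are flagged, not computed.

Overlap clustering uses average-linkage agglomerative clustering on the
dissimilarity 1 − S (bounded because S ∈ [0,1]; the diagonal is distance
0). The number of clusters is chosen at the largest gap in the merge-height
sequence, *including* the gap from zero to the first merge — so a
zero-overlap map yields all singletons, and ties resolve toward the higher
cut. Stability is the mean adjusted Rand index between per-fold clusterings
and the pooled clustering; two identical degenerate partitions (for which
the ARI is 0/0) count as 1.

Pairwise class comparisons of entropy/margin, where needed, use
Mann–Whitney tests with BH adjustment — a deliberately assumption-light
choice for skewed, bounded quantities.

## Permutation importance

Within each grouped test fold, one raw column at a time is permuted among
the held-out rows, the frozen preprocessing and model are re-applied, and
Δ = baseline macro-F1 − permuted macro-F1 is averaged over 10 repeats
(default). Because sex and phase are single factor columns, their encoded
dummies are necessarily permuted jointly — permuting one-hot columns
independently would create impossible covariate patterns. Fold values are
aggregated as the mean with empirical 2.5/97.5 percentiles across folds;
negative importances are reported as-is. Ranking stability is the mean
pairwise Kendall τ between fold rankings.

## Pitch-missingness model

Missingness is modelled as pitch-missing ~ phase + condition (logistic;
references farrowing and normal). In realistic data a reference phase can
have exactly zero missingness, which makes the MLE diverge (complete
separation). The default estimator is therefore Firth's bias-reduced
logistic regression (hat-diagonal-adjusted scoring, implemented in the
package), which keeps all odds ratios finite; plain `glm` MLE is available
as an option, and the output always carries a separation flag. Confidence
intervals are Wald intervals at the penalized estimate. Because the
estimator choice materially changes the odds ratios under separation, these
ORs are reported with their method and flag, and are treated as descriptive.

## The synthetic-data generator

The generator emulates exactly the structure the analysis assumes: the
nested design with phase-dependent condition availability (40 animals ×
19 phase–condition cells × 3 samples = 2280 rows by default), per-trait
fixed effects, animal and recording random intercepts, optional
distress × phase interaction effects, log-normal generation for the skewed
traits (energy, duration, pitch), and logistic MNAR pitch missingness
driven by phase and condition (near zero in farrowing, steep in finishing,
elevated under heat/hunger/pain, depressed under thirst/cold). An optional
row-dropout rate emulates the slightly unbalanced cell counts seen in real
collections, whose cause (discarded samples vs. extra recordings) the
source material leaves open.

Default effect sizes were chosen once to *qualitatively* mirror the known
phenomenology — pain raises intensity and F2, cold lengthens calls, heat
shortens calls and raises pitch, duration shrinks with age, pitch moves
non-monotonically — and are not fits to any dataset. What the generator
deliberately does **not** emulate: value-dependent missingness (missingness
depends on design factors only, not on the latent pitch value),
non-Gaussian residuals beyond the log-normal option, call-type structure,
temporal autocorrelation within recordings beyond the shared intercept, and
farm/breed heterogeneity. Tests passing on this generator therefore show
that the *pipeline* is correct under its stated assumptions, not that real
pig data satisfy those assumptions.

One canned scenario, `signature_scenario_config()`, produces the regime
where record-wise validation flatters a model: condition effects scaled to
15% and animal/recording signature SDs tripled (formants switch to
log-normal generation there so inflated signature variance cannot produce
non-positive frequencies). The leakage mechanism is the shared recording
intercept — three samples of one recording carry one label — plus stable
animal baselines; grouped folds remove both routes.

## Numerical conventions and test scale

* All generator randomness derives from one integer seed, consumed in fixed
  design order; identical seeds give bit-identical tables. Learner seeds
  derive from the CV seed per fold.
* CSV round-trips preserve values to printed precision (15 significant
  digits); missing pitch is an empty field.
* Cohen's d uses the pooled-SD form with n−1 SDs and no small-sample
  correction, computed on observed values; this reproduces the published
  effect sizes from the published summary inputs to their printed precision
  (two printed values differ by 0.01–0.015 because the source computed them
  on unrounded data).
* The test suite exercises the study-scale design (40 animals, 2280 rows)
  where a criterion concerns estimator behaviour at that scale (parameter
  recovery over 20 replicates, interaction-selection size/power over 20
  replicates, leakage over 10 replicates at 20 animals), and smaller designs
  (6–12 animals) for structural and contract checks; these sizes are the
  package's chosen trade-off between Monte-Carlo resolution and a test run
  measured in minutes.
* REML convergence follows `lme4` defaults with derivative checks disabled
  for speed; non-convergence errors out, singular fits pass through.

## Known limitations

The variance partition assumes Gaussian traits after optional log
transform; counts or heavily censored traits would need a generalized
model (out of scope). The residual-ICC estimator is a two-stage
approximation used only for ordering. Odds ratios under separation depend
on the penalty and should not be compared across estimators. The
confusability layer describes one fitted model's errors; it is not a
model-free distance between conditions.
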