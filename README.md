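# vocpartition

Hierarchical analysis of distress encoding in pig vocalizations: variance
partitioning of acoustic traits, subject-wise (animal-grouped)
cross-validated distress classification, and a confusability/uncertainty
layer — for welfare scientists and precision-livestock researchers working
with tabular acoustic features.

## The problem

Pig vocal samples are nested: each animal is recorded across growth phases
(farrowing, nursery, growing, finishing) under distress conditions (normal,
pain, hunger, thirst, cold, heat stress), each 60 s recording split into
three 20 s samples. An acoustic trait y for animal *i*, phase *j*, condition
*k*, sample *m* is modelled as

```
y_ijkm = β0 + β1·Sex_i + β2_j·Phase + β3_k·Distress + u_i + r_(i,rec) + ε_ijkm
u_i ~ N(0, σ²_Animal),  r ~ N(0, σ²_Recording),  ε ~ N(0, σ²)
```

From the REML fit the package reports:

- **ICC** for animal identity: `σ²_Animal / (σ²_Animal + σ²_Recording + σ²)`
  — the strength of stable individual "voice signatures";
- **Nakagawa R²**: marginal (fixed effects only) and conditional (fixed +
  random), with the animal contribution as R²c − R²m;
- **drop-one ΔR²** per fixed block (distress, phase, sex): the loss in
  marginal R² when the block is removed, with BH-FDR over the family of
  trait × block likelihood-ratio tests;
- **distress × phase interaction selection** by ML likelihood-ratio test
  plus AIC.

Because individual signatures inflate naive cross-validation, classification
is evaluated **subject-wise**: folds group all samples of an animal together,
so models are always tested on unseen animals. Imputation (training-fold
median/mode) and z-scaling are fitted strictly within each training fold.
The confusability layer summarises error structure via the directional
confusion matrix C(a→b), the symmetric index S(a,b) = ½[C(a→b) + C(b→a)],
per-sample prediction entropy −Σ p log p and margin p(1) − p(2),
phase-stratified overlap maps, average-linkage overlap clustering with
fold-stability (adjusted Rand), and grouped-fold permutation importance
(Δ macro-F1).

A synthetic-data generator reproduces the full design — phase-dependent
condition availability, animal/recording random intercepts per trait,
log-normal skewed traits, and logistic missing-not-at-random pitch driven by
phase and condition — so the whole pipeline is testable without the study's
raw data.

## Worked example

```r
library(vocpartition)

cfg  <- generator_config(n_animals = 40, seed = 17)
tab  <- generate_dataset(cfg)                         # 2280 samples
vp   <- variance_partition(tab, traits = c("intensity", "duration"))
vp$partition[, c("trait", "icc", "r2_marginal", "r2_conditional",
                 "delta_r2_distress", "delta_r2_phase", "delta_r2_sex")]
#>       trait   icc r2_marginal r2_conditional delta_r2_distress delta_r2_phase delta_r2_sex
#> 1 intensity 0.053       0.335          0.429             0.328        0.00367      0.00271
#> 2  duration 0.043       0.473          0.495             0.303        0.03002      0.00000

plan <- make_grouped_folds(tab, k = 5, seed = 17)     # animal-grouped folds
cv   <- run_cv(tab, plan, models = "rf", seed = 17)$rf
round(c(balanced_accuracy = cv$balanced_accuracy, macro_f1 = cv$macro_f1), 3)
#> balanced_accuracy          macro_f1
#>             0.580             0.573
cv$per_class
#>    class precision recall    f1 support
#> 1 normal     0.446  0.460 0.453     480
#> 2   pain     0.818  0.910 0.862     480
#> 3 hunger     0.443  0.481 0.461     480
#> 4 thirst     0.430  0.272 0.333     360
#> 5   cold     0.665  0.679 0.672     240
#> 6   heat     0.639  0.679 0.659     240
```

Distress dominates the explained variance of intensity (ΔR² ≈ 0.33 against
≈ 0.004 for phase and ≈ 0.003 for sex), while a few percent of variance sits
in stable animal identity (R²c − R²m). Under subject-wise validation pain is
by far the most separable condition (recall 0.91); the overlap map
concentrates the errors among the non-pain states:

```r
round(overlap_summary(cv$truth, cv$pred, cv$prob)$symmetric, 3)
#>        normal  pain hunger thirst  cold  heat
#> normal     NA 0.016  0.226  0.255 0.065 0.091
#> pain    0.016    NA  0.059  0.024 0.040 0.049
#> ...
```

The largest symmetric confusabilities are normal–thirst (0.255) and
normal–hunger (0.226): baseline calls blur into mild resource-restriction
states, while pain stays isolated.

The same analyses run from one config via `run_pipeline()` (list or YAML),
which writes CSV tables, pooled fold-wise predictions and a JSON manifest
with seeds and checksums. The published count/summary tables ship in
`inst/extdata/`; `reconstruct_reference_table()` rebuilds a moment-matched
synthetic table (N = 2221) from them for count, missingness and effect-size
checks.

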