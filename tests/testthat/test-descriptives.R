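test_that("summarize_traits accounting is exact", {
  tab <- generate_dataset(small_cfg(n_animals = 6L, seed = 8L))
  sm <- summarize_traits(tab, "condition")
  pitch <- sm[sm$trait == "pitch", ]
  expect_identical(sum(pitch$n), nrow(tab))
  expect_equal(pitch$pct_missing,
               round(100 * (pitch$n - pitch$n_observed) / pitch$n, 1))
  # non-pitch traits are complete
  expect_true(all(sm$n[sm$trait != "pitch"] ==
                    sm$n_observed[sm$trait != "pitch"]))
  # constant trait in a single-level grouping has SD 0
  one <- as.data.frame(tiny_table())
  one$intensity <- 70
  sm1 <- summarize_traits(voc_table(one), "condition")
  expect_identical(sm1$sd[sm1$trait == "intensity"], 0)
})

test_that("cohens_d is antisymmetric, affine-invariant and errors sensibly", {
  tab <- generate_dataset(small_cfg(n_animals = 6L, seed = 8L))
  d_ab <- cohens_d(tab, "intensity", "pain", "normal")$d
  d_ba <- cohens_d(tab, "intensity", "normal", "pain")$d
  expect_equal(d_ab, -d_ba)
  # affine rescaling leaves d unchanged
  sc <- as.data.frame(tab)
  sc$intensity <- 3 * sc$intensity + 11
  expect_equal(cohens_d(voc_table(sc), "intensity", "pain", "normal")$d, d_ab,
               tolerance = 1e-12)
  expect_error(cohens_d(tab, "nope", "pain", "normal"), "unknown trait")
  # equal means give d = 0 even with unequal SDs
  eq <- as.data.frame(tiny_table())
  eq$condition <- rep(c("normal", "pain"), each = 3)
  eq$recording_id <- rep(c("r1", "r2"), each = 3)
  eq$intensity <- c(69, 70, 71, 68, 70, 72)
  expect_equal(cohens_d(voc_table(eq), "intensity", "pain", "normal")$d, 0)
})

test_that("the reconstructed reference table reproduces the published summaries", {
  ref <- reconstruct_reference_table()
  rep <- validate_design(ref)
  expect_identical(rep$n_total, 2221L)
  expect_equal(rep$pct_pitch_missing, 10.9)
  heat <- ref[ref$condition == "heat", ]
  expect_equal(round(100 * mean(is.na(heat$pitch)), 1), 34.5)
  expect_equal(round(cohens_d(ref, "intensity", "pain", "normal")$d, 2), 1.58)
  expect_equal(round(cohens_d(ref, "duration", "pain", "normal")$d, 2), 1.13)
  expect_equal(round(cohens_d(ref, "f2", "pain", "normal")$d, 2), 1.34)
  expect_equal(cohens_d(ref, "duration", "cold", "normal")$d, 1.26,
               tolerance = 0.01)
  expect_equal(round(cohens_d(ref, "pitch", "heat", "normal")$d, 2), 1.03)
  expect_equal(cohens_d(ref, "duration", "heat", "normal")$d, -0.61,
               tolerance = 0.03)
  # observed-n bookkeeping for pitch
  es <- cohens_d(ref, "pitch", "heat", "normal")
  expect_identical(es$n_a, 146L)
  expect_identical(es$n_b, 440L)
})

test_that("missingness model recovers null and non-null logits", {
  zero_p <- stats::setNames(rep(0, 4), voc_levels()$phase)
  zero_c <- stats::setNames(rep(0, 6), voc_levels()$condition)
  null_cfg <- generator_config(
    n_animals = 30L,
    missingness = list(intercept = -1, phase = zero_p, condition = zero_c),
    seed = 31L)
  fit <- fit_missingness_model(generate_dataset(null_cfg))
  expect_true(all(fit$estimates$ci_low <= 1 & fit$estimates$ci_high >= 1))
  expect_false(fit$separation)

  eff_cfg <- generator_config(
    n_animals = 40L,
    missingness = list(intercept = -2,
                       phase = stats::setNames(c(0, 0, 0, 2),
                                               voc_levels()$phase),
                       condition = zero_c),
    seed = 32L)
  fit2 <- fit_missingness_model(generate_dataset(eff_cfg))
  or_fin <- fit2$estimates$odds_ratio[fit2$estimates$term == "phasefinishing"]
  expect_lt(abs(log(or_fin) - 2), 0.5)
})

test_that("complete separation is flagged yet yields finite odds ratios", {
  # farrowing (the reference phase) has structurally zero missingness
  sep_cfg <- generator_config(
    n_animals = 30L,
    missingness = list(intercept = -30,
                       phase = stats::setNames(c(0, 28.5, 29, 29.5),
                                               voc_levels()$phase),
                       condition = stats::setNames(rep(0, 6),
                                                   voc_levels()$condition)),
    seed = 33L)
  tab <- generate_dataset(sep_cfg)
  expect_identical(sum(is.na(tab$pitch[tab$phase == "farrowing"])), 0L)
  fit <- fit_missingness_model(tab)
  expect_true(fit$separation)
  expect_true(all(is.finite(fit$estimates$odds_ratio)))
  # unpenalized MLE also runs and flags it
  fit_mle <- fit_missingness_model(tab, method = "mle")
  expect_true(fit_mle$separation)

  allobs <- generate_dataset(generator_config(
    n_animals = 4L,
    missingness = list(intercept = -1e9,
                       phase = stats::setNames(rep(0, 4), voc_levels()$phase),
                       condition = stats::setNames(rep(0, 6),
                                                   voc_levels()$condition)),
    seed = 1L))
  expect_error(fit_missingness_model(allobs), "degenerate outcome")
})
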