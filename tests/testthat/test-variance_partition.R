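test_that("ICC arithmetic follows the variance-component definitions", {
  expect_equal(icc(list(sigma2_animal = 1, sigma2_recording = NA,
                        sigma2_resid = 3)), 0.25)
  expect_equal(icc(list(sigma2_animal = 0, sigma2_recording = NA,
                        sigma2_resid = 5)), 0)
  expect_equal(icc(list(sigma2_animal = 1, sigma2_recording = 1,
                        sigma2_resid = 2)), 0.25)
  expect_error(icc(list(sigma2_animal = 0, sigma2_recording = 0,
                        sigma2_resid = 0)), "undefined ICC")
})

test_that("ICC is invariant to trait location and scale", {
  tab <- generate_dataset(oneway_cfg(seed = 13L))
  m0 <- fit_lmm(tab, "intensity", fixed = character(0), random = "animal")
  shifted <- as.data.frame(tab); shifted$intensity <- shifted$intensity + 100
  scaled <- as.data.frame(tab); scaled$intensity <- scaled$intensity * 7
  m1 <- fit_lmm(voc_table(shifted), "intensity", fixed = character(0),
                random = "animal")
  m2 <- fit_lmm(voc_table(scaled), "intensity", fixed = character(0),
                random = "animal")
  expect_equal(icc(m1$components), icc(m0$components), tolerance = 1e-6)
  expect_equal(icc(m2$components), icc(m0$components), tolerance = 1e-6)
})

test_that("method-of-moments oracle matches hand ANOVA and guards balance", {
  df <- data.frame(animal_id = c("a", "a", "b", "b"), y = c(0, 0, 2, 2))
  or <- mom_variance_oracle(df, "y")
  expect_equal(or$sigma2_resid, 0)
  expect_equal(or$sigma2_animal, 2)   # MS_between = 4, n0 = 2
  allsame <- data.frame(animal_id = c("a", "a", "b", "b"), y = rep(5, 4))
  or2 <- mom_variance_oracle(allsame, "y")
  expect_equal(or2$sigma2_animal, 0)
  expect_equal(or2$sigma2_resid, 0)
  expect_error(mom_variance_oracle(df[-1, ], "y"), "balanced")
})

test_that("REML equals the moments oracle on balanced one-way data", {
  tab <- generate_dataset(oneway_cfg(n_animals = 24L, recs = 3L, seed = 17L))
  or <- mom_variance_oracle(tab, "intensity")
  m <- fit_lmm(tab, "intensity", fixed = character(0), random = "animal")
  expect_equal(m$components$sigma2_animal, or$sigma2_animal,
               tolerance = 1e-6)
  expect_equal(m$components$sigma2_resid, or$sigma2_resid, tolerance = 1e-6)
})

test_that("Nakagawa R2 identities hold in degenerate settings", {
  # no fixed effects: var_fixed = 0 so R2m = 0 exactly
  tab <- generate_dataset(oneway_cfg(seed = 19L))
  m <- fit_lmm(tab, "intensity", fixed = character(0), random = "animal")
  r2 <- nakagawa_r2(m)
  expect_identical(r2$r2_marginal, 0)
  expect_gt(r2$r2_conditional, 0)
  expect_lte(r2$r2_conditional, 1)

  # zero simulated random variation: the fit is singular and R2m = R2c
  lvp <- stats::setNames(c(0, 1, 2, 3), voc_levels()$phase)
  cfg <- generator_config(
    n_animals = 10L,
    traits = list(intensity = list(phase = lvp, sd_animal = 0,
                                   sd_recording = 0, sd_resid = 1)),
    seed = 23L)
  tab2 <- generate_dataset(cfg)
  m2 <- fit_lmm(tab2, "intensity", fixed = "phase", random = "animal")
  r22 <- nakagawa_r2(m2)
  expect_equal(r22$r2_marginal, r22$r2_conditional, tolerance = 1e-6)
  expect_true(r22$r2_conditional >= r22$r2_marginal)
})

test_that("Nakagawa R2 recovers the generating closed form", {
  # single phase, all six conditions, condition effects with population
  # variance 2; sigma2_animal = 1, sigma2_resid = 1 -> R2m = 0.5, R2c = 0.75
  g <- sqrt(3)
  cond <- stats::setNames(c(-g, -g, 0, 0, g, g), voc_levels()$condition)
  cfg <- generator_config(
    n_animals = 40L,
    availability = list(farrowing = voc_levels()$condition,
                        nursery = voc_levels()$condition,
                        growing = voc_levels()$condition,
                        finishing = voc_levels()$condition),
    traits = list(intensity = list(intercept = 70, sex = 0,
                                   phase = stats::setNames(rep(0, 4),
                                                           voc_levels()$phase),
                                   condition = cond, sd_animal = 1,
                                   sd_recording = 0, sd_resid = 1)),
    seed = 29L)
  tab <- voc_table(simulate_traits(build_design(cfg), cfg))
  m <- fit_lmm(tab, "intensity", fixed = "distress", random = "animal")
  r2 <- nakagawa_r2(m)
  expect_equal(r2$r2_marginal, 0.5, tolerance = 0.05)
  expect_equal(r2$r2_conditional, 0.75, tolerance = 0.05)
})

test_that("drop-one delta-R2 isolates the generating block", {
  # only distress carries signal; sex and phase effects are zero
  zero_p <- stats::setNames(rep(0, 4), voc_levels()$phase)
  cfg <- generator_config(
    n_animals = 25L,
    traits = list(intensity = list(sex = 0, phase = zero_p,
                                   sd_animal = 1, sd_recording = 1,
                                   sd_resid = 4)),
    seed = 37L)
  tab <- generate_dataset(cfg)
  dd <- drop_one_delta_r2(tab, "intensity", lrt = FALSE)
  r2_full <- attr(dd, "r2_full")$r2_marginal
  expect_equal(dd$delta_r2[dd$block == "distress"], r2_full,
               tolerance = 0.02)
  expect_lt(dd$delta_r2[dd$block == "sex"], 0.01)
  expect_lt(dd$delta_r2[dd$block == "phase"], 0.01)
  expect_true(all(dd$delta_r2 >= 0))
  expect_error(drop_one_delta_r2(tab, "intensity", blocks = "weight"),
               "unknown fixed-effect block")
})

test_that("BH adjustment matches the step-up procedure", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("fit_lmm rejects unusable inputs", {
  tab <- generate_dataset(small_cfg(n_animals = 4L, seed = 41L))
  one_animal <- voc_table(
    as.data.frame(tab)[tab$animal_id == levels(tab$animal_id)[1], ])
  expect_error(fit_lmm(one_animal, "intensity"), "fewer than 2 animals")
  one_phase <- voc_table(as.data.frame(tab)[tab$phase == "nursery", ])
  expect_error(fit_lmm(one_phase, "intensity", fixed = "phase"),
               "constant")
  expect_error(fit_lmm(tab, "loudness"), "unknown trait")
})

test_that("residual ICC tracks the model-based ICC ordering across traits", {
  cfg <- generator_config(
    n_animals = 30L,
    traits = list(intensity = list(sd_animal = 3, sd_recording = 0.5,
                                   sd_resid = 4),
                  f2 = list(sd_animal = 20, sd_recording = 40,
                            sd_resid = 230)),
    seed = 43L)
  tab <- generate_dataset(cfg)
  icc_model <- vapply(c("intensity", "f2"), function(tr)
    icc(fit_lmm(tab, tr)$components), numeric(1))
  icc_resid <- vapply(c("intensity", "f2"), function(tr)
    residual_icc(tab, tr), numeric(1))
  expect_identical(order(icc_model), order(icc_resid))
})

test_that("the partition table is internally consistent", {
  tab <- generate_dataset(small_cfg(n_animals = 10L, seed = 47L))
  vp <- variance_partition(tab, traits = c("intensity", "duration"))
  p <- vp$partition
  expect_true(all(p$r2_conditional >= p$r2_marginal))
  expect_true(all(p$r2_conditional <= 1 & p$r2_marginal >= 0))
  expect_true(all(p$icc >= 0 & p$icc <= 1))
  expect_equal(p$animal_partial_r2, p$r2_conditional - p$r2_marginal)
  expect_true(all(vp$tests$q >= vp$tests$p))
  expect_identical(nrow(vp$tests), 6L)
})
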