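test_that("grouped fold plans honour the hard grouping constraint", {
  tab <- generate_dataset(generator_config(n_animals = 40L, seed = 51L))
  plan <- make_grouped_folds(tab, k = 5, seed = 51L)
  expect_identical(sort(unique(unname(plan$assignments))), 1:5)
  expect_true(all(table(plan$assignments) == 8L))
  # every animal in exactly one fold
  expect_identical(sort(names(plan$assignments)),
                   sort(levels(tab$animal_id)))
  # leave-one-animal-out
  small <- generate_dataset(small_cfg(n_animals = 6L, seed = 51L))
  loao <- make_grouped_folds(small, k = 6, seed = 1L)
  expect_identical(sort(unname(loao$assignments)), 1:6)
  expect_error(make_grouped_folds(small, k = 7), "exceeds")
  # determinism
  expect_identical(make_grouped_folds(tab, k = 5, seed = 3L)$assignments,
                   make_grouped_folds(tab, k = 5, seed = 3L)$assignments)
})

test_that("stratified plans balance class counts at least as well as random", {
  # dropout makes animals heterogeneous so stratification can matter
  tab <- generate_dataset(small_cfg(n_animals = 20L, seed = 53L,
                                    dropout_rate = 0.4))
  dev <- function(plan) {
    fold <- unname(plan$assignments[as.character(tab$animal_id)])
    overall <- prop.table(table(tab$condition))
    worst <- 0
    for (f in seq_len(plan$k)) {
      p <- prop.table(table(tab$condition[fold == f]))
      worst <- max(worst, max(abs(p - overall)))
    }
    worst
  }
  strat <- dev(make_grouped_folds(tab, k = 4, seed = 7L))
  rand <- dev(make_grouped_folds(tab, k = 4, seed = 7L, stratify_by = NULL))
  expect_lte(strat, rand)
})

test_that("within-fold preprocessing never touches the test fold", {
  tab <- generate_dataset(small_cfg(n_animals = 8L, seed = 55L))
  plan <- make_grouped_folds(tab, k = 4, seed = 55L)
  fold <- unname(plan$assignments[as.character(tab$animal_id)])
  train <- tab[fold != 1, ]
  test <- tab[fold == 1, ]
  fit <- fit_fold(train, test, model = "logit")
  # imputation statistic comes from the training fold only
  expect_equal(unname(fit$medians["pitch"]),
               stats::median(train$pitch, na.rm = TRUE))
  expect_false(isTRUE(all.equal(fit$medians[["pitch"]],
                                stats::median(test$pitch, na.rm = TRUE))))
  # a test row with missing pitch is scored as if pitch = train median
  na_row <- test[which(is.na(test$pitch))[1], ]
  filled <- na_row; filled$pitch <- fit$medians[["pitch"]]
  expect_equal(predict(fit, na_row), predict(fit, filled))
  # scaling statistics also come from the training rows
  expect_equal(unname(fit$centers["intensity"]), mean(train$intensity))
})

test_that("fit_fold rejects grouped-CV contract violations", {
  tab <- generate_dataset(small_cfg(n_animals = 6L, seed = 57L))
  expect_error(fit_fold(tab, tab[1:3, ], model = "logit"), "share animals")
  train <- tab[tab$animal_id != levels(tab$animal_id)[1] &
                 tab$condition != "heat", ]
  test <- tab[tab$animal_id == levels(tab$animal_id)[1], ]
  expect_error(fit_fold(train, test, model = "logit"), "stratified")
})

test_that("constant training features are dropped with a warning", {
  df <- as.data.frame(generate_dataset(small_cfg(n_animals = 6L, seed = 59L)))
  df$f4 <- 4000
  tab <- voc_table(df)
  plan <- make_grouped_folds(tab, k = 3, seed = 1L)
  fold <- unname(plan$assignments[as.character(tab$animal_id)])
  expect_warning(
    fit <- fit_fold(tab[fold != 1, ], tab[fold == 1, ], model = "logit"),
    "zero-variance")
  expect_false("f4" %in% fit$numeric)
})

test_that("metrics match hand computations", {
  perfect <- rep(voc_levels()$condition, each = 4)
  m <- cv_metrics(perfect, perfect)
  expect_equal(m$balanced_accuracy, 1)
  expect_equal(m$macro_f1, 1)
  # two-class confusion [[8,2],[4,6]]
  truth <- c(rep("normal", 10), rep("pain", 10))
  pred <- c(rep("normal", 8), rep("pain", 2), rep("normal", 4),
            rep("pain", 6))
  m2 <- cv_metrics(truth, pred)
  expect_equal(m2$balanced_accuracy, 0.7)
  f1_n <- 2 * (8 / 12) * 0.8 / ((8 / 12) + 0.8)
  f1_p <- 2 * (6 / 8) * 0.6 / ((6 / 8) + 0.6)
  expect_equal(m2$macro_f1, mean(c(f1_n, f1_p)))
  # constant predictor over balanced classes sits at chance
  truth6 <- rep(voc_levels()$condition, each = 5)
  pred6 <- rep("normal", 30)
  expect_equal(cv_metrics(truth6, pred6)$balanced_accuracy, 1 / 6)
  expect_error(cv_metrics(c("normal", "sad"), c("normal", "normal")),
               "canonical class set")
})

test_that("pooled CV output is complete, coherent and deterministic", {
  tab <- generate_dataset(small_cfg(n_animals = 10L, seed = 61L))
  plan <- make_grouped_folds(tab, k = 5, seed = 61L)
  cv <- run_cv(tab, plan, models = c("rf", "logit"), seed = 61L)
  for (r in cv) {
    expect_identical(sort(r$row_id), seq_len(nrow(tab)))
    expect_equal(unname(rowSums(r$prob)), rep(1, nrow(tab)), tolerance = 1e-9)
    # confusion marginals equal class supports
    expect_equal(unname(rowSums(r$confusion_raw)),
                 unname(r$per_class$support))
    sup <- rowSums(r$confusion_raw) > 0
    expect_equal(unname(rowSums(r$confusion_row_normalized)[sup]),
                 rep(1, sum(sup)))
    # no animal straddles folds
    for (f in unique(r$fold)) {
      te <- unique(tab$animal_id[r$row_id[r$fold == f]])
      tr <- unique(tab$animal_id[r$row_id[r$fold != f]])
      expect_length(intersect(te, tr), 0L)
    }
  }
  cv2 <- run_cv(tab, plan, models = "rf", seed = 61L)
  expect_identical(cv$rf$macro_f1, cv2$rf$macro_f1)
  expect_identical(cv$rf$pred, cv2$rf$pred)
})

test_that("feature specs and complete-case handling behave as documented", {
  tab <- generate_dataset(small_cfg(n_animals = 8L, seed = 63L))
  expect_false("pitch" %in% feature_spec("nopitch")$numeric)
  expect_length(feature_spec("acoustics")$factors, 0L)
  cc <- complete_case(tab)
  expect_false(anyNA(cc$pitch))
  expect_identical(nrow(cc), sum(!is.na(tab$pitch)))
})

test_that("excluding an informative pitch does not help the classifier", {
  # pitch carries condition signal under the defaults; median over seeds
  gaps <- vapply(1:3, function(s) {
    tab <- generate_dataset(small_cfg(n_animals = 10L, seed = 70L + s))
    plan <- make_grouped_folds(tab, k = 5, seed = s)
    full <- run_cv(tab, plan, models = "rf", features = "full",
                   seed = s)$rf$macro_f1
    nop <- run_cv(tab, plan, models = "rf", features = "nopitch",
                  seed = s)$rf$macro_f1
    full - nop
  }, numeric(1))
  expect_gte(stats::median(gaps), 0)
})
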