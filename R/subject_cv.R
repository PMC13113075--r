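## Subject-wise (animal-grouped) cross-validated distress classification
## with leakage-free within-fold preprocessing.

#' Resolve a feature specification
#'
#' `"full"` uses all acoustic traits plus sex and growth phase,
#' `"acoustics"` the traits alone, `"nopitch"` the full set without pitch
#' (the pitch-excluded sensitivity analysis).
#'
#' @param spec One of `"full"`, `"acoustics"`, `"nopitch"`.
#' @return List with `numeric` (trait names) and `factors` (covariate names).
#' @export
feature_spec <- function(spec = c("full", "acoustics", "nopitch")) {
  spec <- match.arg(spec)
  traits <- voc_levels()$trait
  switch(spec,
         full = list(numeric = traits, factors = c("sex", "phase")),
         acoustics = list(numeric = traits, factors = character(0)),
         nopitch = list(numeric = setdiff(traits, "pitch"),
                        factors = c("sex", "phase")))
}

#' Restrict a table to samples with observed pitch
#'
#' Complete-case sensitivity variant: drops rows with missing pitch.
#'
#' @param table A [voc_table()].
#' @return A [voc_table()] of the complete cases.
#' @export
complete_case <- function(table) {
  stopifnot(inherits(table, "voc_table"))
  voc_table(as.data.frame(table)[!is.na(table$pitch), , drop = FALSE])
}

#' Build a cross-validation fold plan
#'
#' With `group_by = "animal_id"` (the default), animals are partitioned into
#' `k` folds so that no animal's samples ever straddle training and test
#' sets; a greedy heuristic balances per-fold class counts subject to that
#' hard constraint when `stratify_by` is given. With `group_by = NULL` the
#' plan is record-wise (rows assigned to folds individually) — useful only
#' to demonstrate the optimism such leakage induces.
#'
#' @param table A [voc_table()].
#' @param k Number of folds (default 5).
#' @param seed Integer seed; the plan is deterministic given it.
#' @param stratify_by Factor to balance across folds (default `"condition"`)
#'   or `NULL` for unstratified assignment.
#' @param group_by `"animal_id"` or `NULL` for record-wise folds.
#' @return A `voc_fold_plan`: list with `k`, `group_by`, `assignments`
#'   (named animal -> fold map, or per-row fold vector), `seed`.
#' @export
make_grouped_folds <- function(table, k = 5L, seed = 1L,
                               stratify_by = "condition",
                               group_by = "animal_id") {
  stopifnot(inherits(table, "voc_table"))
  k <- as.integer(k)
  if (is.null(group_by)) {
    n <- nrow(table)
    if (k > n) stop("k exceeds the number of rows", call. = FALSE)
    fold <- integer(n)
    .with_seed(seed, {
      if (is.null(stratify_by)) {
        fold[sample(n)] <- rep_len(seq_len(k), n)
      } else {
        for (lev in levels(table[[stratify_by]])) {
          idx <- which(table[[stratify_by]] == lev)
          fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
        }
      }
    })
    return(structure(list(k = k, group_by = NULL, assignments = fold,
                          seed = seed), class = "voc_fold_plan"))
  }
  animals <- levels(droplevels(table$animal_id))
  n_a <- length(animals)
  if (k > n_a) stop("k exceeds the number of animals", call. = FALSE)
  ord <- .with_seed(seed, sample(animals))
  if (is.null(stratify_by)) {
    assign <- stats::setNames(rep_len(seq_len(k), n_a), ord)
  } else {
    strat <- table[[stratify_by]]
    m <- table(factor(table$animal_id, levels = ord), strat)
    ord <- ord[order(-rowSums(m))]          # big animals placed first
    m <- m[ord, , drop = FALSE]
    cap <- ceiling(n_a / k)
    fold_counts <- matrix(0, k, ncol(m))
    fold_sizes <- integer(k)
    assign <- stats::setNames(integer(n_a), ord)
    for (i in seq_len(n_a)) {
      open <- which(fold_sizes < cap)
      cost <- vapply(open, function(f)
        sum((fold_counts[f, ] + m[i, ])^2), numeric(1))
      best <- open[order(cost, fold_sizes[open], open)][1]
      assign[ord[i]] <- best
      fold_counts[best, ] <- fold_counts[best, ] + m[i, ]
      fold_sizes[best] <- fold_sizes[best] + 1L
    }
  }
  structure(list(k = k, group_by = "animal_id", assignments = assign,
                 seed = seed), class = "voc_fold_plan")
}

## ---- within-fold preprocessing + model fit --------------------------------

.mode_of <- function(x) names(which.max(table(x)))

#' Fit one cross-validation fold
#'
#' Fits all preprocessing statistics on the training rows only: numeric
#' imputation uses the training-fold median, categorical imputation the
#' training-fold mode, and z-scaling (for the scale-sensitive multinomial
#' logistic model) uses training means and SDs. Tree ensembles are trained
#' unscaled. Constant training features are dropped with a warning. The
#' multinomial logistic model uses balanced class weights.
#'
#' @param train,test Row subsets of a [voc_table()] with disjoint animal
#'   sets.
#' @param model `"rf"` (random forest), `"logit"` (multinomial logistic) or
#'   `"gbm"` (gradient boosting).
#' @param features A [feature_spec()] list.
#' @param seed Integer seed for the stochastic learners.
#' @return A `voc_fold_fit` (use [predict()] to get class probabilities),
#'   with the fitted model and all training-fold preprocessing statistics.
#' @export
fit_fold <- function(train, test, model = c("rf", "logit", "gbm"),
                     features = feature_spec("full"), seed = 1L) {
  model <- match.arg(model)
  if (length(intersect(unique(train$animal_id), unique(test$animal_id))) > 0L)
    stop("training and test folds share animals", call. = FALSE)
  classes <- voc_levels()$condition
  absent <- setdiff(unique(as.character(test$condition)),
                    unique(as.character(train$condition)))
  if (length(absent) > 0L)
    stop("class(es) absent from the training fold: ",
         paste(absent, collapse = ", "),
         "; use a stratified fold plan", call. = FALSE)

  num <- features$numeric
  medians <- vapply(num, function(v) stats::median(train[[v]], na.rm = TRUE),
                    numeric(1))
  imp <- function(df) {
    for (v in num) {
      x <- df[[v]]; x[is.na(x)] <- medians[[v]]; df[[v]] <- x
    }
    for (v in features$factors) {
      x <- df[[v]]
      if (anyNA(x)) x[is.na(x)] <- .mode_of(train[[v]][!is.na(train[[v]])])
      df[[v]] <- x
    }
    df
  }
  tr <- imp(as.data.frame(train))
  sds <- vapply(num, function(v) stats::sd(tr[[v]]), numeric(1))
  dropped <- num[sds == 0]
  if (length(dropped) > 0L) {
    warning("dropping zero-variance feature(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
    num <- setdiff(num, dropped)
  }
  centers <- vapply(num, function(v) mean(tr[[v]]), numeric(1))
  scales <- vapply(num, function(v) stats::sd(tr[[v]]), numeric(1))

  fit <- list(model_type = model, features = features, numeric = num,
              factors = features$factors, medians = medians,
              centers = centers, scales = scales, dropped = dropped,
              classes = classes, seed = seed)
  cols <- c(num, features$factors)
  y <- factor(as.character(tr$condition), levels = classes)

  if (model == "logit") {
    d <- tr[, cols, drop = FALSE]
    for (v in num) d[[v]] <- (d[[v]] - centers[[v]]) / scales[[v]]
    d$.y <- y
    tab <- table(y)
    w <- as.numeric(length(y) / (sum(tab > 0) * tab[as.character(y)]))
    fit$model <- .with_seed(seed, nnet::multinom(
      .y ~ ., data = d, weights = w, decay = 0.01, maxit = 300,
      trace = FALSE, MaxNWts = 5000))
  } else if (model == "rf") {
    d <- tr[, cols, drop = FALSE]
    d$.y <- y
    fit$model <- ranger::ranger(.y ~ ., data = d, probability = TRUE,
                                num.trees = 500, seed = seed,
                                num.threads = 1)
  } else {
    X <- stats::model.matrix(~ . - 1, data = tr[, cols, drop = FALSE])
    fit$xgb_cols <- colnames(X)
    .with_seed(seed, {
      fit$model <- xgboost::xgb.train(
        params = list(objective = "multi:softprob",
                      num_class = length(classes), eta = 0.1, max_depth = 4,
                      nthread = 1, seed = seed),
        data = xgboost::xgb.DMatrix(X, label = as.integer(y) - 1L),
        nrounds = 150)
    })
  }
  class(fit) <- "voc_fold_fit"
  fit
}

#' Predict class probabilities from a fitted fold
#'
#' Applies the stored training-fold preprocessing (imputation, scaling) to
#' new raw rows, then the fold's model. Probability rows sum to 1 over the
#' six canonical classes.
#'
#' @param object A `voc_fold_fit`.
#' @param newdata Raw rows (same columns as the analysis table).
#' @param ... Unused.
#' @return Matrix (n x 6) of class probabilities, columns in canonical
#'   class order.
#' @export
predict.voc_fold_fit <- function(object, newdata, ...) {
  num <- object$numeric
  d <- as.data.frame(newdata)
  for (v in object$features$numeric) {
    x <- d[[v]]; x[is.na(x)] <- object$medians[[v]]; d[[v]] <- x
  }
  d <- d[, c(num, object$factors), drop = FALSE]
  if (object$model_type == "logit") {
    for (v in num)
      d[[v]] <- (d[[v]] - object$centers[[v]]) / object$scales[[v]]
    pr <- stats::predict(object$model, newdata = d, type = "probs")
    if (is.null(dim(pr))) pr <- matrix(pr, nrow = 1,
                                       dimnames = list(NULL, names(pr)))
  } else if (object$model_type == "rf") {
    pr <- stats::predict(object$model, data = d,
                         num.threads = 1)$predictions
  } else {
    X <- stats::model.matrix(~ . - 1, data = d)
    miss <- setdiff(object$xgb_cols, colnames(X))
    if (length(miss) > 0L) {
      X <- cbind(X, matrix(0, nrow(X), length(miss),
                           dimnames = list(NULL, miss)))
    }
    X <- X[, object$xgb_cols, drop = FALSE]
    pr <- stats::predict(object$model, xgboost::xgb.DMatrix(X))
    if (is.null(dim(pr)))
      pr <- matrix(pr, ncol = length(object$classes), byrow = TRUE)
    dimnames(pr) <- list(NULL, object$classes)
  }
  out <- matrix(0, nrow(pr), length(object$classes),
                dimnames = list(NULL, object$classes))
  out[, colnames(pr)] <- pr
  out / rowSums(out)
}

.argmax_class <- function(prob, classes) {
  # ties broken by fixed (canonical) class order
  factor(classes[max.col(prob, ties.method = "first")], levels = classes)
}

#' Classification metrics
#'
#' Balanced accuracy (unweighted mean of per-class recalls), macro-F1
#' (unweighted mean of per-class F1, with F1 = 0 when precision + recall =
#' 0), and per-class precision/recall/F1/support. Classes without support
#' are excluded from the macro averages.
#'
#' @param truth,pred Factors (or characters) over the canonical condition
#'   classes.
#' @return List: `balanced_accuracy`, `macro_f1`, `per_class` data frame.
#' @export
cv_metrics <- function(truth, pred) {
  classes <- voc_levels()$condition
  bad <- setdiff(unique(c(as.character(truth), as.character(pred))), classes)
  if (length(bad) > 0L)
    stop("labels outside the canonical class set: ",
         paste(bad, collapse = ", "), call. = FALSE)
  truth <- factor(as.character(truth), levels = classes)
  pred <- factor(as.character(pred), levels = classes)
  cm <- table(truth, pred)
  support <- rowSums(cm)
  recall <- ifelse(support > 0, diag(cm) / support, NA_real_)
  predn <- colSums(cm)
  precision <- ifelse(predn > 0, diag(cm) / predn, 0)
  f1 <- ifelse(precision + recall > 0, 2 * precision * recall /
                 (precision + recall), 0)
  keep <- support > 0
  list(balanced_accuracy = mean(recall[keep]),
       macro_f1 = mean(f1[keep]),
       per_class = data.frame(class = classes, precision = as.numeric(precision),
                              recall = as.numeric(recall),
                              f1 = as.numeric(f1),
                              support = as.numeric(support),
                              stringsAsFactors = FALSE))
}

#' Run cross-validated classification
#'
#' Executes the fold plan for one or more models and pools out-of-fold
#' predictions. Every sample appears exactly once in the pooled
#' predictions; all preprocessing is fitted within each training fold.
#'
#' @param table A [voc_table()] (already restricted via [complete_case()]
#'   for the complete-case variant).
#' @param plan A [make_grouped_folds()] plan built on the same table.
#' @param models Subset of `c("rf", "logit", "gbm")`.
#' @param features Feature specification name (see [feature_spec()]).
#' @param seed Base seed for the learners (per-fold seeds derive from it).
#' @param keep_fits Keep the per-fold fitted models (needed for
#'   [permutation_importance()]).
#' @return Named list (one `voc_cv_result` per model): pooled `truth`,
#'   `pred`, `prob`, per-row `fold` and `row_id`, `balanced_accuracy`,
#'   `macro_f1`, `per_class`, `confusion_raw`, `confusion_row_normalized`,
#'   `per_fold` metrics, and `fits` when requested.
#' @export
run_cv <- function(table, plan, models = c("rf", "logit", "gbm"),
                   features = "full", seed = 1L, keep_fits = FALSE) {
  stopifnot(inherits(table, "voc_table"), inherits(plan, "voc_fold_plan"))
  models <- match.arg(models, several.ok = TRUE)
  fs <- feature_spec(features)
  classes <- voc_levels()$condition
  if (is.null(plan$group_by)) {
    if (length(plan$assignments) != nrow(table))
      stop("record-wise plan does not match the table", call. = FALSE)
    row_fold <- plan$assignments
  } else {
    row_fold <- unname(plan$assignments[as.character(table$animal_id)])
    if (anyNA(row_fold))
      stop("plan is missing animals present in the table", call. = FALSE)
  }
  out <- list()
  for (mod in models) {
    truth <- character(0); pred <- character(0)
    prob <- NULL; fold_id <- integer(0); row_id <- integer(0)
    per_fold <- list(); fits <- list()
    for (f in seq_len(plan$k)) {
      te_idx <- which(row_fold == f)
      tr_idx <- which(row_fold != f)
      train <- table[tr_idx, , drop = FALSE]
      test <- table[te_idx, , drop = FALSE]
      if (is.null(plan$group_by)) {
        # record-wise comparison plan: bypass the grouped-fit animal check
        fit <- local({
          tmp <- train
          fit_fold_nogroup(tmp, test, mod, fs, seed + f)
        })
      } else {
        fit <- fit_fold(train, test, mod, fs, seed = seed + f)
      }
      pr <- predict(fit, test)
      pc <- .argmax_class(pr, classes)
      truth <- c(truth, as.character(test$condition))
      pred <- c(pred, as.character(pc))
      prob <- rbind(prob, pr)
      fold_id <- c(fold_id, rep(f, length(te_idx)))
      row_id <- c(row_id, te_idx)
      mtr <- cv_metrics(test$condition, pc)
      per_fold[[f]] <- data.frame(fold = f,
                                  balanced_accuracy = mtr$balanced_accuracy,
                                  macro_f1 = mtr$macro_f1)
      if (keep_fits)
        fits[[f]] <- list(fit = fit, test_idx = te_idx)
    }
    truth <- factor(truth, levels = classes)
    pred <- factor(pred, levels = classes)
    mtr <- cv_metrics(truth, pred)
    cm <- table(truth, pred)
    cmn <- cm / pmax(rowSums(cm), 1)
    res <- list(model_name = mod, plan = plan, features = features,
                truth = truth, pred = pred, prob = prob, fold = fold_id,
                row_id = row_id,
                balanced_accuracy = mtr$balanced_accuracy,
                macro_f1 = mtr$macro_f1, per_class = mtr$per_class,
                confusion_raw = unclass(cm),
                confusion_row_normalized = unclass(cmn),
                per_fold = do.call(rbind, per_fold))
    if (keep_fits) res$fits <- fits
    class(res) <- "voc_cv_result"
    out[[mod]] <- res
  }
  out
}

# record-wise variant used only for the leakage comparison: identical
# preprocessing and models, but without the disjoint-animal precondition.
fit_fold_nogroup <- function(train, test, model, features, seed) {
  tr2 <- train
  te2 <- test
  # temporarily relabel test animals so the grouped check in fit_fold passes
  te2$animal_id <- factor(paste0(".rw.", as.character(te2$animal_id)))
  fit_fold(tr2, te2, model, features, seed)
}
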