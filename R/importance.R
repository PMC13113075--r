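## Grouped-fold permutation importance with fold-percentile intervals.

#' Permutation importance under grouped cross-validation
#'
#' For each feature and each fold: permute that feature's raw column within
#' the fold's held-out rows (a categorical covariate is a single factor
#' column, so its encoded dummies are permuted jointly by construction),
#' re-apply the fold's frozen preprocessing and model, and take
#' delta = baseline macro-F1 - permuted macro-F1. Repeats are averaged
#' within a fold; folds are aggregated as the mean and the empirical 2.5th
#' and 97.5th percentiles of the fold distribution. Negative importances
#' are reported as-is. Ranking stability across folds is summarized as the
#' mean pairwise Kendall tau between fold-wise importance rankings.
#'
#' @param cv A `voc_cv_result` from [run_cv()] with `keep_fits = TRUE`.
#' @param table The table the CV was run on.
#' @param features Features to permute; default all features of the CV's
#'   feature spec (numeric traits plus factor covariates).
#' @param n_repeats Permutations per feature per fold (default 10).
#' @param seed Integer seed.
#' @return List: `importance` (data frame rank, feature,
#'   mean_delta_macro_f1, ci_2_5, ci_97_5, n_repeats), `per_fold` (feature x
#'   fold matrix), `kendall_tau` (mean pairwise fold-ranking agreement).
#' @export
permutation_importance <- function(cv, table, features = NULL,
                                   n_repeats = 10L, seed = 1L) {
  stopifnot(inherits(cv, "voc_cv_result"))
  if (is.null(cv$fits))
    stop("run_cv must be called with keep_fits = TRUE", call. = FALSE)
  if (n_repeats < 1L) stop("n_repeats must be >= 1", call. = FALSE)
  fs <- feature_spec(cv$features)
  all_feats <- c(fs$numeric, fs$factors)
  if (is.null(features)) features <- all_feats
  bad <- setdiff(features, all_feats)
  if (length(bad) > 0L)
    stop("feature(s) not in the model: ", paste(bad, collapse = ", "),
         call. = FALSE)
  classes <- voc_levels()$condition
  nfold <- length(cv$fits)
  per_fold <- matrix(NA_real_, length(features), nfold,
                     dimnames = list(features, NULL))
  .with_seed(seed, {
    for (f in seq_len(nfold)) {
      fit <- cv$fits[[f]]$fit
      test <- table[cv$fits[[f]]$test_idx, , drop = FALSE]
      base_pred <- .argmax_class(predict(fit, test), classes)
      base_f1 <- cv_metrics(test$condition, base_pred)$macro_f1
      for (ft in features) {
        deltas <- numeric(n_repeats)
        for (r in seq_len(n_repeats)) {
          perm <- test
          perm[[ft]] <- perm[[ft]][sample(nrow(perm))]
          pp <- .argmax_class(predict(fit, perm), classes)
          deltas[r] <- base_f1 - cv_metrics(test$condition, pp)$macro_f1
        }
        per_fold[ft, f] <- mean(deltas)
      }
    }
  })
  imp <- data.frame(
    feature = features,
    mean_delta_macro_f1 = rowMeans(per_fold),
    ci_2_5 = apply(per_fold, 1, stats::quantile, probs = 0.025),
    ci_97_5 = apply(per_fold, 1, stats::quantile, probs = 0.975),
    n_repeats = n_repeats, stringsAsFactors = FALSE)
  imp <- imp[order(-imp$mean_delta_macro_f1), , drop = FALSE]
  imp <- cbind(rank = seq_len(nrow(imp)), imp)
  rownames(imp) <- NULL
  tau <- NA_real_
  if (nfold >= 2L && length(features) >= 2L) {
    ranks <- apply(-per_fold, 2, rank)
    pairs <- utils::combn(nfold, 2)
    tau <- mean(apply(pairs, 2, function(ij)
      stats::cor(ranks[, ij[1]], ranks[, ij[2]], method = "kendall")))
  }
  list(importance = imp, per_fold = per_fold, kendall_tau = tau)
}
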