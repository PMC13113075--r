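## Confusability / overlap layer: directional and symmetric confusion,
## prediction entropy and margin, phase stratification, overlap clustering
## and fold stability.

#' Directional (row-normalized) confusion matrix
#'
#' C(a -> b) = #(true a, predicted b) / #(true a). Rows of supported
#' classes sum to 1; zero-support rows are NA and flagged.
#'
#' @param truth,pred Labels over the canonical condition classes.
#' @return K x K matrix with attribute `zero_support` (class names).
#' @export
directional_confusion <- function(truth, pred) {
  if (length(truth) == 0L) stop("empty input", call. = FALSE)
  classes <- voc_levels()$condition
  truth <- factor(as.character(truth), levels = classes)
  pred <- factor(as.character(pred), levels = classes)
  cm <- table(truth, pred)
  support <- rowSums(cm)
  C <- unclass(cm) / ifelse(support > 0, support, NA_real_)
  attr(C, "zero_support") <- classes[support == 0]
  C
}

#' Symmetric confusability index
#'
#' S(a, b) = (C(a -> b) + C(b -> a)) / 2, the undirected overlap between
#' two classes; the diagonal is set NA (self-overlap is not defined).
#'
#' @param C Square directional confusion matrix.
#' @return Symmetric K x K matrix with NA diagonal.
#' @export
symmetric_index <- function(C) {
  if (!is.matrix(C) || nrow(C) != ncol(C))
    stop("C must be a square matrix", call. = FALSE)
  S <- (C + t(C)) / 2
  diag(S) <- NA_real_
  nm <- rownames(C)
  dimnames(S) <- list(nm, nm)
  attr(S, "zero_support") <- NULL
  S
}

#' Prediction entropy
#'
#' Shannon entropy (natural log) of a class-probability vector, with
#' 0 log 0 = 0. Maximal (log K) for the uniform distribution, 0 for a
#' one-hot vector. Accepts a matrix (one row per sample).
#'
#' @param p Probability vector summing to 1 (tolerance 1e-6), or a matrix
#'   of such rows.
#' @return Entropy value(s) in \[0, log K\].
#' @export
prediction_entropy <- function(p) {
  if (is.matrix(p)) return(apply(p, 1, prediction_entropy))
  if (abs(sum(p) - 1) > 1e-6)
    stop("probabilities must sum to 1", call. = FALSE)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Prediction margin
#'
#' Gap between the highest and second-highest predicted probabilities;
#' 0 for a top-2 tie (e.g. uniform), 1 for a one-hot vector. Accepts a
#' matrix (one row per sample).
#'
#' @param p Probability vector (length >= 2) or matrix of rows.
#' @return Margin value(s) in \[0, 1\].
#' @export
prediction_margin <- function(p) {
  if (is.matrix(p)) return(apply(p, 1, prediction_margin))
  if (length(p) < 2L) stop("margin needs at least 2 classes", call. = FALSE)
  s <- sort(p, decreasing = TRUE)
  s[1] - s[2]
}

.summary_by_class <- function(values, truth) {
  classes <- voc_levels()$condition
  do.call(rbind, lapply(classes, function(cl) {
    v <- values[truth == cl]
    if (length(v) == 0L)
      return(data.frame(class = cl, n = 0L, median = NA_real_,
                        iqr = NA_real_))
    data.frame(class = cl, n = length(v), median = stats::median(v),
               iqr = stats::IQR(v), stringsAsFactors = FALSE)
  }))
}

#' Overlap summary from pooled out-of-fold predictions
#'
#' Directional and symmetric confusability matrices plus per-class median
#' and IQR of prediction entropy and margin.
#'
#' @param truth,pred Pooled labels.
#' @param prob Pooled probability matrix (n x K).
#' @return List of class `voc_overlap`: `directional`, `symmetric`,
#'   `entropy_by_class`, `margin_by_class`, `entropy`, `margin`, `n`.
#' @export
overlap_summary <- function(truth, pred, prob) {
  C <- directional_confusion(truth, pred)
  H <- prediction_entropy(prob)
  M <- prediction_margin(prob)
  structure(list(directional = C, symmetric = symmetric_index(C),
                 entropy_by_class = .summary_by_class(H, truth),
                 margin_by_class = .summary_by_class(M, truth),
                 entropy = H, margin = M, n = length(truth)),
            class = "voc_overlap")
}

#' Phase-stratified overlap summaries
#'
#' Restricts the pooled out-of-fold predictions of a CV result to each
#' stratum of a design factor and recomputes the overlap summary. Strata
#' with fewer than two represented true classes are flagged and skipped.
#'
#' @param cv A `voc_cv_result` from [run_cv()].
#' @param table The table the CV was run on.
#' @param stratum Stratifying factor (default `"phase"`).
#' @return List: `strata` (named list of [overlap_summary()] results),
#'   `skipped` (stratum names with < 2 classes), `overall`.
#' @export
stratified_overlap <- function(cv, table, stratum = "phase") {
  stopifnot(inherits(cv, "voc_cv_result"))
  fac <- table[[stratum]][cv$row_id]
  strata <- list(); skipped <- character(0)
  for (lev in levels(table[[stratum]])) {
    sel <- which(fac == lev)
    if (length(sel) == 0L) next
    if (length(unique(as.character(cv$truth[sel]))) < 2L) {
      skipped <- c(skipped, lev)
      next
    }
    strata[[lev]] <- overlap_summary(cv$truth[sel], cv$pred[sel],
                                     cv$prob[sel, , drop = FALSE])
  }
  list(strata = strata, skipped = skipped,
       overall = overlap_summary(cv$truth, cv$pred, cv$prob))
}

.cut_by_height_gap <- function(hc, K) {
  h <- hc$height
  gaps <- c(h[1], diff(h))
  i <- max(which(gaps == max(gaps)))   # ties resolved toward the top
  k <- if (i == 1L) K else K - (i - 1L)
  stats::cutree(hc, k = k)
}

#' Cluster the class overlap map
#'
#' Average-linkage agglomerative clustering of the symmetric confusability
#' matrix on the dissimilarity 1 - S (NA off-diagonals treated as full
#' dissimilarity). The number of clusters is chosen at the largest gap in
#' the merge heights (including the gap from zero to the first merge, so a
#' zero-overlap map yields all singletons). Stability is the mean adjusted
#' Rand index between per-fold clusterings and the pooled clustering.
#'
#' @param S Symmetric K x K confusability matrix (pooled).
#' @param fold_S Optional list of per-fold S matrices.
#' @return List: `clusters` (named membership vector), `k`, `merge_heights`,
#'   `stability` (NA when no fold matrices are given), `hclust`.
#' @export
cluster_overlap <- function(S, fold_S = NULL) {
  K <- nrow(S)
  if (K < 3L) {
    message("fewer than 3 classes: overlap clustering skipped")
    return(list(clusters = NULL, k = NA_integer_, stability = NA_real_))
  }
  to_dist <- function(Smat) {
    D <- 1 - Smat
    D[is.na(D)] <- 1
    diag(D) <- 0
    stats::as.dist(D)
  }
  hc <- stats::hclust(to_dist(S), method = "average")
  cl <- .cut_by_height_gap(hc, K)
  stability <- NA_real_
  if (!is.null(fold_S) && length(fold_S) > 0L) {
    ari_safe <- function(a, b) {
      # ARI is 0/0 for two degenerate partitions; identical partitions get 1
      canon <- function(x) as.integer(factor(x, levels = unique(x)))
      if (identical(canon(a), canon(b))) return(1)
      v <- mclust::adjustedRandIndex(a, b)
      if (is.nan(v)) 0 else v
    }
    ari <- vapply(fold_S, function(Sf) {
      hf <- stats::hclust(to_dist(Sf), method = "average")
      ari_safe(.cut_by_height_gap(hf, K), cl)
    }, numeric(1))
    stability <- mean(ari)
  }
  list(clusters = cl, k = length(unique(cl)),
       merge_heights = hc$height, stability = stability, hclust = hc)
}

#' Per-fold symmetric confusability matrices
#'
#' @param cv A `voc_cv_result`.
#' @return List of S matrices, one per fold with >= 2 represented classes.
#' @export
fold_symmetric_matrices <- function(cv) {
  stopifnot(inherits(cv, "voc_cv_result"))
  out <- list()
  for (f in sort(unique(cv$fold))) {
    sel <- cv$fold == f
    if (length(unique(as.character(cv$truth[sel]))) < 2L) next
    out[[as.character(f)]] <-
      symmetric_index(directional_confusion(cv$truth[sel], cv$pred[sel]))
  }
  out
}
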