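#' ROC AUC by the Mann-Whitney formulation
#'
#' The area under the ROC curve computed as the fraction of
#' (positive, negative) score pairs in which the positive scores higher, with
#' ties counted one half. This equals the trapezoidal area under the
#' empirical ROC curve and estimates the probability that a random
#' interacting pair outscores a random non-interacting one.
#'
#' @param scores numeric decision values.
#' @param labels `+1`/`-1` labels, same length; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @examples
#' roc_auc(c(0.9, 0.8, 0.4, 0.3), c(1, -1, 1, -1)) # 0.75
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  if (!all(labels %in% c(-1, 1))) stop("labels must be +1 or -1")
  npos <- sum(labels == 1); nneg <- sum(labels == -1)
  if (npos == 0 || nneg == 0)
    stop("AUC needs at least one positive and one negative")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Distribution-free confidence interval for an AUC
#'
#' Normal-approximation interval `auc +/- z * sigma`, clipped to `[0, 1]`,
#' with the Hanley-McNeil distribution-free variance estimate
#' `sigma^2 = (A(1-A) + (n_pos-1)(P_xxy - A^2) + (n_neg-1)(P_xyy - A^2)) /
#' (n_pos n_neg)` where `P_xxy = A / (2 - A)` and `P_xyy = 2 A^2 / (1 + A)`.
#' The variance shrinks as the class counts grow, so the interval width goes
#' to 0 in the large-sample limit at a fixed error rate.
#'
#' @param auc point estimate in `[0, 1]`.
#' @param n_pos,n_neg positive / negative example counts.
#' @param n_errors number of classification errors at the `f >= 0` threshold;
#'   accepted for interface compatibility with error-based variance
#'   estimators (an extension point) and not used by the default estimator.
#' @param level confidence level in (0, 1), default 0.95.
#' @return `c(lo, hi)`, clipped to `[0, 1]` and containing `auc`.
#' @export
auc_confidence_interval <- function(auc, n_pos, n_neg, n_errors = NA_integer_,
                                    level = 0.95) {
  if (!is.numeric(level) || length(level) != 1 || is.na(level) ||
      level <= 0 || level >= 1)
    stop("level must be in (0, 1)")
  if (n_pos <= 0 || n_neg <= 0) stop("class counts must be positive")
  if (auc < 0 || auc > 1) stop("auc must be in [0, 1]")
  A <- auc
  pxxy <- A / (2 - A)
  pxyy <- 2 * A^2 / (1 + A)
  v <- (A * (1 - A) + (n_pos - 1) * (pxxy - A^2) +
          (n_neg - 1) * (pxyy - A^2)) / (n_pos * n_neg)
  v <- max(v, 0)
  z <- stats::qnorm(1 - (1 - level) / 2)
  lo <- max(0, A - z * sqrt(v))
  hi <- min(1, A + z * sqrt(v))
  c(lo, hi)
}

#' Stratified k-fold cross-validation of the pairwise SVM
#'
#' Randomly partitions the labelled pairs into `k` folds, stratified by class
#' so that every fold contains both interacting and non-interacting pairs,
#' then trains on `k - 1` folds and scores the held-out fold, reporting the
#' per-fold ROC AUC and the mean over folds. Fold assignment is seeded and
#' the whole procedure is bit-reproducible for a fixed seed.
#'
#' @param k_gram a pairwise [new_gram_matrix()] over the labelled pairs.
#' @param labels `+1`/`-1` vector aligned with `k_gram$ids`.
#' @param k number of folds (default 10).
#' @param C SVM regularization (default 1).
#' @param seed integer seed for the fold assignment.
#' @return An object of class `"prk_eval"`: `fold_auc`, `mean_auc`,
#'   `ci` (from [auc_confidence_interval()]), `n_errors` (misclassifications
#'   at the `f >= 0` threshold over all held-out folds), `n_pos`, `n_neg`,
#'   `k`, `seed`.
#' @export
cross_validate <- function(k_gram, labels, k = 10L, C = 1, seed) {
  stopifnot(inherits(k_gram, "gram_matrix"))
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  n <- length(k_gram$ids)
  d <- as.numeric(labels)
  if (length(d) != n) stop("labels must align with kernel ids")
  pos <- which(d == 1); neg <- which(d == -1)
  if (length(pos) < k || length(neg) < k)
    stop("stratification infeasible: need at least k members of each class")
  folds <- integer(n)
  with_seed(seed, {
    folds[pos] <- rep_len(seq_len(k), length(pos))[sample.int(length(pos))]
    folds[neg] <- rep_len(seq_len(k), length(neg))[sample.int(length(neg))]
  })
  K <- k_gram$values
  fold_auc <- numeric(k)
  n_err <- 0L
  for (i in seq_len(k)) {
    te <- folds == i; tr <- !te
    ktr <- new_gram_matrix(K[tr, tr, drop = FALSE], k_gram$ids[tr],
                           normalized = k_gram$normalized)
    m <- train_svm(ktr, d[tr], C = C)
    sc <- decide(m, K[te, tr, drop = FALSE])
    fold_auc[i] <- roc_auc(sc, d[te])
    n_err <- n_err + sum(classify(sc) != d[te])
  }
  mean_auc <- mean(fold_auc)
  structure(list(fold_auc = fold_auc, mean_auc = mean_auc,
                 ci = auc_confidence_interval(mean_auc, length(pos),
                                              length(neg), n_err),
                 n_errors = n_err, n_pos = length(pos), n_neg = length(neg),
                 k = k, seed = seed),
            class = "prk_eval")
}

#' @export
print.prk_eval <- function(x, ...) {
  cat(sprintf("<prk_eval: %d-fold CV, mean AUC %.3f [%.3f, %.3f], %d errors>\n",
              x$k, x$mean_auc, x$ci[1], x$ci[2], x$n_errors))
  cat("fold AUCs:", paste(sprintf("%.3f", x$fold_auc), collapse = " "), "\n")
  invisible(x)
}

#' Disagreement counts between two classifiers
#'
#' Counts the discordant outcomes on a shared test set: `n_fs` is the number
#' of items where classifier A failed and classifier B succeeded, `n_sf` the
#' reverse.
#'
#' @param preds_a,preds_b `+1`/`-1` predictions of the two classifiers.
#' @param truth `+1`/`-1` true labels.
#' @return `c(n_fs = ..., n_sf = ...)`.
#' @export
disagreement_counts <- function(preds_a, preds_b, truth) {
  if (length(preds_a) != length(preds_b) ||
      length(preds_a) != length(truth))
    stop("prediction and truth vectors must have equal length")
  a_ok <- preds_a == truth
  b_ok <- preds_b == truth
  c(n_fs = sum(!a_ok & b_ok), n_sf = sum(a_ok & !b_ok))
}

#' McNemar z score for paired classifier comparison
#'
#' Signed statistic `z = (n_fs - n_sf) / sqrt(n_fs + n_sf)` on the two
#' discordant counts: `z = 0` means the classifiers perform alike, and a
#' positive `z` means classifier B (the one that succeeded in the `n_fs`
#' cases) performs better. The continuity-corrected variant
#' `sign(n_fs - n_sf) * (|n_fs - n_sf| - 1) / sqrt(n_fs + n_sf)` is available
#' behind a flag.
#'
#' @param n_fs count of items where A failed and B succeeded.
#' @param n_sf count of items where A succeeded and B failed.
#' @param correct logical; apply the continuity correction (default `FALSE`).
#' @return The signed z score.
#' @examples
#' mcnemar_z(8, 2) # 6 / sqrt(10)
#' @export
mcnemar_z <- function(n_fs, n_sf, correct = FALSE) {
  if (n_fs < 0 || n_sf < 0) stop("counts must be nonnegative")
  if (n_fs == 0 && n_sf == 0)
    stop("both disagreement counts are zero; McNemar z is undefined")
  d <- n_fs - n_sf
  if (correct) sign(d) * max(0, abs(d) - 1) / sqrt(n_fs + n_sf)
  else d / sqrt(n_fs + n_sf)
}
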