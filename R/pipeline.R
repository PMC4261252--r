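#' Rectangular block of pairwise kernel values
#'
#' Evaluates the chosen pairwise kernel between every pair in `pairs1` (rows)
#' and every pair in `pairs2` (columns) — the kernel rows needed to score new
#' gene pairs against the training pairs of a fitted model.
#'
#' @param pairs1,pairs2 [pairwise_points()] frames (coerced if plain
#'   data.frames with columns `x`, `y`).
#' @param type one of [PRK_TYPES].
#' @param u a `prk_base` object.
#' @return Numeric matrix of dimension `nrow(pairs1) x nrow(pairs2)` with
#'   pair ids as dimnames.
#' @export
prk_cross_block <- function(pairs1, pairs2, type = PRK_TYPES, u) {
  type <- match.arg(type)
  fix <- function(p) {
    if (!inherits(p, "pairwise_points")) pairwise_points(p$x, p$y) else p
  }
  pairs1 <- fix(pairs1); pairs2 <- fix(pairs2)
  x1 <- pairs1$x; y1 <- pairs1$y
  x2 <- pairs2$x; y2 <- pairs2$y
  A <- base_block(u, x1, x2)
  B <- base_block(u, y1, y2)
  C <- base_block(u, x1, y2)
  D <- base_block(u, y1, x2)
  K <- prk_combine(type, A, B, C, D,
                   dyy = outer(y1, y2, "=="), dxx = outer(x1, x2, "=="),
                   dyx = outer(y1, x2, "=="), dxy = outer(x1, y2, "=="))
  dimnames(K) <- list(pairs1$pair_id, pairs2$pair_id)
  K
}

#' Score new gene pairs with a trained pairwise SVM
#'
#' Computes the kernel rows of the query pairs against the model's training
#' pairs and applies the decision function; pairs with `f >= 0` are predicted
#' interacting.
#'
#' @param m a `prk_model` from [train_svm()].
#' @param query a [pairwise_points()] frame of pairs to classify.
#' @param train_pairs the training pairs (same order as `m$ids`).
#' @param type one of [PRK_TYPES].
#' @param u a `prk_base` holding the base kernel over all gene ids involved.
#' @return data.frame with columns `x`, `y`, `score`, `label`.
#' @export
predict_pairs <- function(m, query, train_pairs, type = PRK_TYPES, u) {
  type <- match.arg(type)
  if (!inherits(query, "pairwise_points"))
    query <- pairwise_points(query$x, query$y)
  if (!inherits(train_pairs, "pairwise_points"))
    train_pairs <- pairwise_points(train_pairs$x, train_pairs$y)
  if (!identical(train_pairs$pair_id, m$ids))
    stop("training pairs do not match the model's training pair ids")
  rows <- prk_cross_block(query, train_pairs, type, u)
  sc <- decide(m, rows)
  data.frame(x = query$x, y = query$y, score = sc, label = classify(sc),
             stringsAsFactors = FALSE)
}

#' Cross-validated AUC of planted-motif benchmarks
#'
#' End-to-end study on synthetic data: for each seed, generate a
#' planted-motif benchmark, build the (cosine-normalized) 3-gram base Gram
#' matrix, assemble a balanced training set (sampled interacting pairs plus
#' degree-matched non-interacting pairs), build the pairwise Gram matrix for
#' each requested kernel type, and run stratified k-fold cross-validation.
#'
#' @param types pairwise kernel types to evaluate (subset of [PRK_TYPES]).
#' @param seeds integer vector of seeds; one full study per seed.
#' @param n_pos,n_neg numbers of interacting / non-interacting training
#'   pairs.
#' @param spec an [ngram_spec()].
#' @param k folds (default 10).
#' @param C SVM regularization (default 1).
#' @param center_base double-center the base Gram matrix with
#'   [center_gram()] before the pairwise construction (default `TRUE`; see
#'   that function for why spectrum kernels need it).
#' @param ... passed to [synthetic_config()] (e.g. `motif_copies = 0` for the
#'   no-signal control); the per-study `seed` argument is supplied from
#'   `seeds`.
#' @return data.frame with one row per `(type, seed)`: `type`, `seed`,
#'   `mean_auc`, `n_errors`.
#' @export
planted_signal_study <- function(types = c("tensor", "metric", "cartesian",
                                           "direct_sum"),
                                 seeds = 1:10, n_pos = 100L, n_neg = 100L,
                                 spec = ngram_spec(), k = 10L, C = 1,
                                 center_base = TRUE, ...) {
  types <- match.arg(types, PRK_TYPES, several.ok = TRUE)
  out <- list()
  for (seed in seeds) {
    cfg <- synthetic_config(..., seed = seed)
    sim <- generate_synthetic(cfg)
    base <- gram_matrix(sim$sequences, spec, normalize = TRUE)
    if (center_base) base <- center_gram(base)
    u <- base_kernel_gram(base)
    g <- sim$graph
    if (n_pos > nrow(g$edges))
      stop("n_pos exceeds the ", nrow(g$edges), " planted interacting pairs")
    pos_idx <- with_seed(seed, sample.int(nrow(g$edges), n_pos))
    pos <- pairwise_points(g$edges$a[pos_idx], g$edges$b[pos_idx], 1L)
    neg <- balanced_negative_sample(g, n_neg, seed = seed)
    pairs <- rbind(pos, neg)
    class(pairs) <- c("pairwise_points", "data.frame")
    labels <- pairs$label
    for (type in types) {
      kp <- pairwise_gram(pairs, type, u)
      ev <- cross_validate(kp, labels, k = k, C = C, seed = seed)
      out[[length(out) + 1L]] <- data.frame(
        type = type, seed = seed, mean_auc = ev$mean_auc,
        n_errors = ev$n_errors, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
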