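#' Train a pairwise SVM on a precomputed Gram matrix
#'
#' Solves the soft-margin SVM dual
#' `max_a sum(a) - 0.5 * t(a * d) K (a * d)` subject to `0 <= a <= C` and
#' `sum(a * d) = 0`, on a precomputed (pairwise) kernel matrix, and recovers
#' the offset `b` from the Karush-Kuhn-Tucker conditions. The quadratic
#' program is solved with the interior-point solver [kernlab::ipop()], which
#' is reliable on the low-rank Gram matrices that n-gram kernels produce.
#'
#' @param k a [new_gram_matrix()] (symmetric positive semidefinite up to
#'   tolerance) over the training pair ids.
#' @param labels vector of `+1`/`-1`, aligned with `k$ids` (or a named vector
#'   in any order).
#' @param C soft-margin regularization, `C > 0` (default 1).
#' @param kernel_spec optional character tag recording how the kernel was
#'   built (stored in the model for provenance).
#' @return An object of class `"prk_model"`: support coefficients `alpha`
#'   (in `[0, C]`), signed coefficients `beta = alpha * d`, offset `b`,
#'   training `ids`, `labels`, `C` and `kernel_spec`. The decision function is
#'   `f(q) = sum_p beta_p K(q, p) + b` (see [decide()]).
#' @export
train_svm <- function(k, labels, C = 1, kernel_spec = NULL) {
  stopifnot(inherits(k, "gram_matrix"))
  if (C <= 0) stop("C must be positive")
  n <- length(k$ids)
  if (!is.null(names(labels))) {
    if (!setequal(names(labels), k$ids))
      stop("label names do not match kernel ids")
    labels <- labels[k$ids]
  }
  if (length(labels) != n) stop("labels must align with kernel ids")
  d <- as.numeric(labels)
  if (!all(d %in% c(-1, 1))) stop("labels must be +1 or -1")
  if (length(unique(d)) < 2L) stop("need both classes to train")
  K <- k$values
  if (max(abs(K - t(K))) > 1e-8 * max(1, max(abs(K))))
    stop("kernel matrix is not symmetric")
  H <- (d %*% t(d)) * K
  # interior-point solve; exactly duplicated training pairs make H singular,
  # so escalate the ridge until the linear algebra goes through
  ip <- NULL
  for (ridge in 10^c(-8, -6, -4) * max(diag(H), 1)) {
    ip <- tryCatch(
      {
        utils::capture.output(
          res <- kernlab::ipop(c = matrix(rep(-1, n)),
                               H = H + diag(n) * ridge,
                               A = t(d), b = 0,
                               l = matrix(rep(0, n)), u = matrix(rep(C, n)),
                               r = 0, sigf = 8, maxiter = 80))
        res
      },
      error = function(e) NULL)
    if (!is.null(ip)) break
  }
  if (is.null(ip))
    stop("quadratic-program solve failed on this kernel matrix")
  alpha <- pmin(pmax(as.vector(kernlab::primal(ip)), 0), C)
  beta <- alpha * d
  # offset from KKT: interior SVs satisfy d_i * (K beta + b) = 1
  f0 <- as.vector(K %*% beta)
  tol_a <- 1e-6 * C
  interior <- alpha > tol_a & alpha < C - tol_a
  b <- if (any(interior)) {
    mean(d[interior] - f0[interior])
  } else {
    # no interior SV: take the midpoint of the feasible KKT interval,
    # [max over (alpha_i = C, d = +1) or (alpha_i = 0, d = -1) of d_i - f_i,
    #  min over (alpha_i = 0, d = +1) or (alpha_i = C, d = -1) of d_i - f_i]
    lo_idx <- (alpha >= C - tol_a & d == 1) | (alpha <= tol_a & d == -1)
    hi_idx <- (alpha <= tol_a & d == 1) | (alpha >= C - tol_a & d == -1)
    lo <- if (any(lo_idx)) max(d[lo_idx] - f0[lo_idx]) else -Inf
    hi <- if (any(hi_idx)) min(d[hi_idx] - f0[hi_idx]) else Inf
    if (is.finite(lo) && is.finite(hi)) (lo + hi) / 2
    else if (is.finite(lo)) lo else if (is.finite(hi)) hi else 0
  }
  structure(list(alpha = stats::setNames(alpha, k$ids),
                 beta = stats::setNames(beta, k$ids),
                 b = as.numeric(b),
                 ids = k$ids, labels = d, C = C,
                 kernel_spec = if (is.null(kernel_spec)) "precomputed"
                               else kernel_spec),
            class = "prk_model")
}

#' @export
print.prk_model <- function(x, ...) {
  cat(sprintf("<prk_model: %d training pairs, %d support vectors, C = %g, b = %.6g>\n",
              length(x$ids), sum(x$alpha > 1e-6 * x$C), x$C, x$b))
  invisible(x)
}

#' Decision function and classification rule
#'
#' `decide()` evaluates `f = sum_p alpha_p d_p K(query, p) + b` for a query
#' pair given its row of kernel values against all training pairs;
#' `classify()` applies the sign rule: a pair is predicted interacting (`+1`)
#' exactly when `f >= 0` (a tie at 0 is classified `+1`).
#'
#' @param m a `prk_model` from [train_svm()].
#' @param k_row numeric vector (or matrix with one column per training pair)
#'   of kernel values of the query pair(s) against the training pairs, in
#'   training order (or with matching names).
#' @return `decide()`: numeric score(s); `classify()`: `+1`/`-1` integer(s).
#' @export
decide <- function(m, k_row) {
  stopifnot(inherits(m, "prk_model"))
  if (is.matrix(k_row)) {
    if (ncol(k_row) != length(m$ids))
      stop("kernel row length ", ncol(k_row), " does not match ",
           length(m$ids), " training pairs")
    if (!is.null(colnames(k_row))) k_row <- k_row[, m$ids, drop = FALSE]
    return(as.vector(k_row %*% m$beta) + m$b)
  }
  if (length(k_row) != length(m$ids))
    stop("kernel row length ", length(k_row), " does not match ",
         length(m$ids), " training pairs")
  if (!is.null(names(k_row))) k_row <- k_row[m$ids]
  sum(m$beta * as.numeric(k_row)) + m$b
}

#' @param score numeric decision value(s) from [decide()].
#' @rdname decide
#' @export
classify <- function(score) {
  ifelse(score >= 0, 1L, -1L)
}

#' Serialize / restore a trained model
#'
#' Writes the learned parameters (per-pair `alpha`, signed `beta`, offset
#' `b`, `C`, kernel tag, labels) as a JSON document, and reads them back.
#' @param m a `prk_model`.
#' @param path file path.
#' @return `write_model_json()`: `path` invisibly; `read_model_json()`: a
#'   `prk_model`.
#' @export
write_model_json <- function(m, path) {
  stopifnot(inherits(m, "prk_model"))
  doc <- list(kernel_spec = m$kernel_spec, C = m$C, b = m$b,
              ids = m$ids, labels = m$labels,
              alpha = as.numeric(m$alpha))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  alpha <- stats::setNames(as.numeric(doc$alpha), doc$ids)
  d <- as.numeric(doc$labels)
  structure(list(alpha = alpha, beta = alpha * d, b = as.numeric(doc$b),
                 ids = doc$ids, labels = d, C = as.numeric(doc$C),
                 kernel_spec = doc$kernel_spec),
            class = "prk_model")
}
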