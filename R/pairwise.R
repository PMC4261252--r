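#' Pairwise kernel types
#'
#' The closed set of pairwise rational kernel constructions supported: direct
#' sum, tensor product (Kronecker), metric learning, and Cartesian.
#' @export
PRK_TYPES <- c("direct_sum", "tensor", "metric", "cartesian")

#' Pairwise points (gene pairs with optional labels)
#'
#' Builds the canonical representation of a set of unordered gene pairs with
#' optional interaction labels. Pairs are undirected edges, so the two ids of
#' each pair are stored in lexicographic order; the pair identifier is
#' `"a|b"` in that order.
#'
#' @param x,y character vectors of gene ids (recycled to common length).
#' @param label optional vector of labels in `{+1, -1}` (`NA` allowed).
#' @return A data.frame of class `"pairwise_points"` with columns `x`, `y`,
#'   `label` and `pair_id`.
#' @export
pairwise_points <- function(x, y, label = NA_integer_) {
  x <- as.character(x); y <- as.character(y)
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  label <- rep_len(as.integer(label), n)
  if (any(!is.na(label) & !label %in% c(-1L, 1L)))
    stop("labels must be +1 or -1")
  a <- pmin(x, y); b <- pmax(x, y)
  out <- data.frame(x = a, y = b, label = label,
                    pair_id = paste(a, b, sep = "|"),
                    stringsAsFactors = FALSE)
  class(out) <- c("pairwise_points", "data.frame")
  out
}

#' Base kernels for pairwise constructions
#'
#' A base kernel supplies the symmetric gene-by-gene similarity `U(a, b)` that
#' a pairwise kernel is built from. Two backings are supported:
#'
#' * `base_kernel_gram(g)` wraps a precomputed [new_gram_matrix()] (e.g. an
#'   n-gram Gram matrix, or a phylogenetic / domain-content kernel loaded
#'   from TSV);
#' * `base_kernel_ngram(seqs, ...)` holds sequences plus an n-gram spec and
#'   evaluates `U` on demand, either from sparse count vectors (default) or
#'   by full transducer composition (`method = "transducer"`, the literal
#'   rational-kernel evaluation path), caching each unordered gene pair so a
#'   base value is computed at most once.
#'
#' @param g a [new_gram_matrix()].
#' @return An object of class `"prk_base"`.
#' @rdname base_kernel
#' @export
base_kernel_gram <- function(g) {
  stopifnot(inherits(g, "gram_matrix"))
  structure(list(kind = "gram", gram = g, ids = g$ids), class = "prk_base")
}

#' @param seqs named character vector of gene sequences.
#' @param spec an [ngram_spec()].
#' @param normalize cosine-normalize the base kernel (default `TRUE`).
#' @param method `"counts"` or `"transducer"` evaluation route.
#' @rdname base_kernel
#' @export
base_kernel_ngram <- function(seqs, spec = ngram_spec(), normalize = TRUE,
                              method = c("counts", "transducer")) {
  method <- match.arg(method)
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    stop("sequences must be named by gene id")
  if (method == "counts") {
    g <- gram_matrix(seqs, spec, normalize = normalize)
    out <- base_kernel_gram(g)
    out$seqs <- seqs; out$spec <- spec
    return(out)
  }
  structure(list(kind = "transducer", seqs = seqs, spec = spec,
                 normalize = normalize,
                 u = pds_kernel_from(ngram_transducer(spec)),
                 cache = new.env(parent = emptyenv()),
                 ids = names(seqs)),
            class = "prk_base")
}

#' @export
print.prk_base <- function(x, ...) {
  cat(sprintf("<prk_base: %s backing, %d genes>\n", x$kind, length(x$ids)))
  invisible(x)
}

raw_base_value <- function(u, a, b) {
  key <- paste(sort(c(a, b)), collapse = "|")
  hit <- get0(key, envir = u$cache)
  if (!is.null(hit)) return(hit)
  v <- wfst_value(u$u, clean_seq(u$seqs[[a]]), clean_seq(u$seqs[[b]]))
  assign(key, v, envir = u$cache)
  v
}

#' Evaluate a base kernel on a pair of gene ids
#'
#' @param u a `prk_base` object.
#' @param a,b gene identifiers known to `u`.
#' @return `U(a, b)` as a single number.
#' @export
base_value <- function(u, a, b) {
  stopifnot(inherits(u, "prk_base"))
  for (id in c(a, b))
    if (!id %in% u$ids) stop("unknown gene id: ", id)
  if (u$kind == "gram") return(u$gram$values[a, b])
  if (u$normalize) {
    num <- raw_base_value(u, a, b)
    da <- raw_base_value(u, a, a); db <- raw_base_value(u, b, b)
    if (da <= 0 || db <= 0) return(0)
    if (a == b) return(1)
    num / sqrt(da * db)
  } else {
    raw_base_value(u, a, b)
  }
}

# submatrix of base values for id vectors i (rows) and j (cols)
base_block <- function(u, i, j) {
  unknown <- setdiff(unique(c(i, j)), u$ids)
  if (length(unknown)) stop("unknown gene id: ", unknown[[1]])
  if (u$kind == "gram") return(u$gram$values[i, j, drop = FALSE])
  out <- matrix(0, length(i), length(j), dimnames = list(i, j))
  for (r in seq_along(i)) for (cc in seq_along(j))
    out[r, cc] <- base_value(u, i[[r]], j[[cc]])
  out
}

prk_combine <- function(type, A, B, C, D, dyy, dxx, dyx, dxy) {
  switch(type,
    direct_sum = A + B + D + C,
    tensor     = A * B + C * D,
    metric     = (A - C - D + B)^2,
    cartesian  = A * dyy + dxx * B + C * dyx + dxy * D,
    stop("unknown pairwise kernel type: ", type))
}

#' Pairwise rational kernel value between two gene pairs
#'
#' Evaluates one of the four pairwise kernels between the pairs
#' `p1 = (x1, y1)` and `p2 = (x2, y2)`, from base kernel values
#' `U(., .)` (at most four base evaluations):
#'
#' * direct sum: `U(x1,x2) + U(y1,y2) + U(y1,x2) + U(x1,y2)`
#' * tensor: `U(x1,x2) * U(y1,y2) + U(x1,y2) * U(y1,x2)`
#' * metric: `(U(x1,x2) - U(x1,y2) - U(y1,x2) + U(y1,y2))^2`
#' * cartesian: `U(x1,x2) d(y1,y2) + d(x1,x2) U(y1,y2) +
#'   U(x1,y2) d(y1,x2) + d(x1,y2) U(y1,x2)`
#'
#' where `d(a, b)` is 1 when the gene *identifiers* are equal and 0 otherwise
#' (two genes with identical sequence but different ids are not equal).
#' Pairs are canonicalized to lexicographic id order first, so the kernel is
#' well-defined on unordered pairs.
#'
#' @param type one of [PRK_TYPES].
#' @param u a `prk_base` object (see [base_kernel_gram()]).
#' @param p1,p2 gene pairs: length-2 character vectors `c(x, y)` or single
#'   rows of a [pairwise_points()] frame.
#' @return A single number.
#' @examples
#' g <- gram_matrix(c(g1 = "ACGTTT", g2 = "ACGAAA", g3 = "TTTCCC", g4 = "ACGTTT"))
#' u <- base_kernel_gram(g)
#' prk_value("tensor", u, c("g1", "g2"), c("g3", "g4"))
#' @export
prk_value <- function(type = PRK_TYPES, u, p1, p2) {
  type <- match.arg(type)
  as_pair <- function(p) {
    if (inherits(p, "data.frame")) p <- c(p$x[[1]], p$y[[1]])
    sort(as.character(p))
  }
  p1 <- as_pair(p1); p2 <- as_pair(p2)
  x1 <- p1[[1]]; y1 <- p1[[2]]; x2 <- p2[[1]]; y2 <- p2[[2]]
  A <- base_value(u, x1, x2) # U(x1, x2)
  B <- base_value(u, y1, y2) # U(y1, y2)
  C <- base_value(u, x1, y2) # U(x1, y2)
  D <- base_value(u, y1, x2) # U(y1, x2)
  prk_combine(type, A, B, C, D,
              dyy = as.numeric(y1 == y2), dxx = as.numeric(x1 == x2),
              dyx = as.numeric(y1 == x2), dxy = as.numeric(x1 == y2))
}

#' Pairwise Gram matrix over a set of gene pairs
#'
#' Assembles the symmetric matrix of pairwise kernel values over all pairs of
#' pairs. Base kernel values are computed once per unordered gene pair (block
#' evaluation with caching), and the four formulas are applied in vectorized
#' form.
#'
#' @param pairs a [pairwise_points()] frame (or something coercible: a
#'   data.frame with columns `x` and `y`); at least 2 pairs.
#' @param type one of [PRK_TYPES].
#' @param u a `prk_base` object.
#' @param normalize_pairwise optionally cosine-normalize the resulting
#'   pairwise matrix itself (default `FALSE`: normalization is applied at the
#'   base-kernel level).
#' @return A [new_gram_matrix()] whose ids are the `"a|b"` pair identifiers.
#' @export
pairwise_gram <- function(pairs, type = PRK_TYPES, u,
                          normalize_pairwise = FALSE) {
  type <- match.arg(type)
  if (!inherits(pairs, "pairwise_points"))
    pairs <- pairwise_points(pairs$x, pairs$y,
                             if ("label" %in% names(pairs)) pairs$label else NA)
  if (nrow(pairs) < 2L) stop("need at least 2 pairs")
  x <- pairs$x; y <- pairs$y
  A <- base_block(u, x, x)
  B <- base_block(u, y, y)
  C <- base_block(u, x, y)
  D <- base_block(u, y, x)
  K <- prk_combine(type, A, B, C, D,
                   dyy = outer(y, y, "=="), dxx = outer(x, x, "=="),
                   dyx = outer(y, x, "=="), dxy = outer(x, y, "=="))
  K <- (K + t(K)) / 2 # remove numerical asymmetry from the block products
  g <- new_gram_matrix(K, pairs$pair_id, normalized = FALSE)
  if (normalize_pairwise) normalize_gram(g) else g
}
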