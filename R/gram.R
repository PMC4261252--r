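#' Gram matrix container
#'
#' A symmetric matrix of kernel values with row/column identifiers, as used
#' both for base (sequence-level) kernels and for pairwise kernels over pairs
#' of genes.
#'
#' @param values square numeric matrix; dimnames are set from `ids`.
#' @param ids character identifiers, one per row/column. Defaults to existing
#'   row names.
#' @param normalized logical flag: `TRUE` when the matrix has been cosine
#'   normalized (unit diagonal).
#' @return An object of class `"gram_matrix"`.
#' @seealso [gram_matrix()], [normalize_gram()], [combine_kernels()],
#'   [read_gram_tsv()], [write_gram_tsv()]
#' @export
new_gram_matrix <- function(values, ids = rownames(values), normalized = FALSE) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values))
    stop("gram matrix must be square")
  if (is.null(ids) || length(ids) != nrow(values))
    stop("ids must match matrix dimension")
  ids <- as.character(ids)
  if (anyDuplicated(ids))
    stop("duplicate id: ", ids[duplicated(ids)][[1]])
  dimnames(values) <- list(ids, ids)
  if (nrow(values) > 0 &&
      max(abs(values - t(values))) > 1e-9 * max(1, max(abs(values))))
    stop("gram matrix is not symmetric within tolerance")
  structure(list(ids = ids, values = values, normalized = isTRUE(normalized)),
            class = "gram_matrix")
}

#' @export
print.gram_matrix <- function(x, ...) {
  cat(sprintf("<gram_matrix: %d x %d%s>\n", nrow(x$values), ncol(x$values),
              if (x$normalized) ", normalized" else ""))
  if (nrow(x$values) <= 8) print(x$values) else {
    print(x$values[1:5, 1:5])
    cat("...\n")
  }
  invisible(x)
}

#' @export
dim.gram_matrix <- function(x) dim(x$values)

#' Cosine normalization of a Gram matrix
#'
#' Rescales `K(i, j)` to `K(i, j) / sqrt(K(i, i) K(j, j))`, the standard
#' remedy for longer sequences containing more n-grams and hence inflated raw
#' similarities. `0/0` is defined as 0 (sequences with an empty n-gram
#' profile).
#'
#' @param g a [new_gram_matrix()] object.
#' @return A normalized `gram_matrix` with unit diagonal (where defined).
#' @export
normalize_gram <- function(g) {
  stopifnot(inherits(g, "gram_matrix"))
  d <- sqrt(diag(g$values))
  denom <- outer(d, d)
  vals <- ifelse(denom > 0, g$values / denom, 0)
  # exact unit diagonal where the raw diagonal was positive
  diag(vals)[d > 0] <- 1
  new_gram_matrix(vals, g$ids, normalized = TRUE)
}

#' Double-centering of a Gram matrix
#'
#' Centers the implicit feature embedding at its mean:
#' `K <- H K H` with `H = I - 11'/n`. Spectrum (n-gram count) kernels on
#' random background sequence concentrate around a large positive constant
#' (two random sequences of equal length always share many n-grams), and
#' pairwise constructions built on products of such values inherit an almost
#' rank-one component that dominates the Gram spectrum and starves a
#' box-constrained SVM of expressiveness. Removing the mean component is the
#' standard remedy (the metric-learning pairwise kernel is algebraically
#' invariant to it, which is why it alone does not need this). Centering
#' destroys the unit diagonal, so the result is flagged unnormalized.
#'
#' @param g a [new_gram_matrix()] object.
#' @return A centered `gram_matrix` over the same ids.
#' @export
center_gram <- function(g) {
  stopifnot(inherits(g, "gram_matrix"))
  n <- nrow(g$values)
  rm_ <- rowMeans(g$values)
  mm <- mean(g$values)
  vals <- g$values - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + mm
  vals <- (vals + t(vals)) / 2
  new_gram_matrix(vals, g$ids, normalized = FALSE)
}

#' Weighted sum of two Gram matrices
#'
#' Computes `w1 * K1 + w2 * K2` over identically ordered identifiers; positive
#' semidefiniteness is preserved for nonnegative weights, so sums of PDS
#' kernels (e.g. a pairwise rational kernel plus a precomputed phylogenetic or
#' domain-content kernel) remain valid SVM kernels.
#'
#' @param k1,k2 [new_gram_matrix()] objects with identical id ordering.
#' @param w1,w2 nonnegative weights (default 1 and 1).
#' @return A `gram_matrix`.
#' @export
combine_kernels <- function(k1, k2, w1 = 1, w2 = 1) {
  stopifnot(inherits(k1, "gram_matrix"), inherits(k2, "gram_matrix"))
  if (length(k1$ids) != length(k2$ids) || any(k1$ids != k2$ids)) {
    bad <- if (length(k1$ids) != length(k2$ids)) "(different sizes)" else {
      i <- which(k1$ids != k2$ids)[1]
      paste0(k1$ids[i], " vs ", k2$ids[i])
    }
    stop("id mismatch between gram matrices: ", bad)
  }
  vals <- w1 * k1$values + w2 * k2$values
  new_gram_matrix(vals, k1$ids,
                  normalized = all(abs(diag(vals) - 1) < 1e-9))
}

#' Write a Gram matrix as TSV
#'
#' Full square matrix; first row and first column carry the identifiers,
#' values printed at 12 significant digits.
#' @param g a `gram_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gram_tsv <- function(g, path) {
  stopifnot(inherits(g, "gram_matrix"))
  vals <- matrix(sprintf("%.12g", g$values), nrow = nrow(g$values))
  tab <- cbind(g$ids, vals)
  header <- paste(c("id", g$ids), collapse = "\t")
  lines <- c(header, apply(tab, 1, paste, collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a Gram matrix from TSV
#'
#' Inverse of [write_gram_tsv()]; also used to load precomputed base kernels
#' (e.g. phylogenetic or PFAM-domain kernels) supplied as matrices.
#' @param path TSV file written in the [write_gram_tsv()] layout.
#' @param normalized flag recorded on the returned object; defaults to
#'   detecting a unit diagonal.
#' @return A `gram_matrix`.
#' @export
read_gram_tsv <- function(path, normalized = NULL) {
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  ids <- as.character(tab[[1]])
  vals <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  colnames(vals) <- colnames(tab)[-1]
  if (!identical(colnames(vals), ids))
    stop("row and column identifiers disagree in ", path)
  if (is.null(normalized))
    normalized <- nrow(vals) > 0 && all(abs(diag(vals) - 1) < 1e-9)
  new_gram_matrix(vals, ids, normalized = normalized)
}
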