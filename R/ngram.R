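#' n-gram kernel specification
#'
#' Fixes the subsequence length `n` and the symbol alphabet for the n-gram
#' (spectrum / k-mer) kernel machinery. The default, `n = 3` over the
#' nucleotide alphabet, is the configuration used throughout the package's
#' metabolic-network experiments.
#'
#' @param n positive integer subsequence length.
#' @param alphabet non-empty character vector of single symbols.
#' @return An object of class `"ngram_spec"`.
#' @export
ngram_spec <- function(n = 3L, alphabet = c("A", "C", "G", "T")) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be a positive integer")
  alphabet <- as.character(alphabet)
  if (length(alphabet) == 0L) stop("alphabet must be non-empty")
  if (any(nchar(alphabet) != 1L)) stop("alphabet symbols must be single characters")
  structure(list(n = n, alphabet = alphabet), class = "ngram_spec")
}

#' @export
print.ngram_spec <- function(x, ...) {
  cat(sprintf("<ngram_spec: n = %d, alphabet = {%s}>\n",
              x$n, paste(x$alphabet, collapse = ",")))
  invisible(x)
}

#' The n-gram counting transducer
#'
#' Builds the transducer `T_n` with `T_n(x, z) = c_x(z)`, the number of
#' (possibly overlapping) occurrences of `z` in `x`, for every `z` of length
#' `n` (and 0 otherwise). The machine has states `0..n`; states `0` and `n`
#' carry `(sigma : eps)` self-loops for every symbol (skipping a prefix and a
#' suffix of `x`), and state `i` advances to `i + 1` on `(sigma : sigma)`.
#' Each accepting path thus reads all of `x` and emits exactly one length-`n`
#' window of it.
#'
#' @param spec an [ngram_spec()].
#' @return A [wfst] object.
#' @examples
#' t3 <- ngram_transducer(ngram_spec(3))
#' wfst_value(t3, "ACTCTCT", "TCT") # 2
#' @export
ngram_transducer <- function(spec = ngram_spec()) {
  stopifnot(inherits(spec, "ngram_spec"))
  n <- spec$n
  ab <- spec$alphabet
  states <- as.character(0:n)
  loops <- data.frame(
    src = rep(c("0", as.character(n)), each = length(ab)),
    ilab = rep(ab, times = 2L),
    olab = EPS,
    weight = 1,
    dst = rep(c("0", as.character(n)), each = length(ab)),
    stringsAsFactors = FALSE)
  steps <- data.frame(
    src = rep(as.character(0:(n - 1L)), each = length(ab)),
    ilab = rep(ab, times = n),
    olab = rep(ab, times = n),
    weight = 1,
    dst = rep(as.character(1:n), each = length(ab)),
    stringsAsFactors = FALSE)
  wfst(rbind(loops, steps),
       initial = c("0" = 1),
       final = stats::setNames(1, as.character(n)),
       input_alphabet = ab, output_alphabet = ab, states = states)
}

clean_seq <- function(x) toupper(x)

# named vector of n-gram counts of x; windows containing symbols outside the
# alphabet are skipped (with a warning), so foreign symbols such as N never
# inflate similarities
seq_ngram_counts <- function(x, spec = ngram_spec()) {
  x <- clean_seq(x)
  n <- spec$n
  L <- nchar(x)
  if (L < n) return(stats::setNames(integer(0), character(0)))
  starts <- seq_len(L - n + 1L)
  wins <- substring(x, starts, starts + n - 1L)
  ok <- !grepl(paste0("[^", paste(spec$alphabet, collapse = ""), "]"), wins)
  if (any(!ok))
    warning(sum(!ok), " n-gram window(s) containing symbols outside the ",
            "alphabet were skipped")
  tab <- table(wins[ok])
  stats::setNames(as.integer(tab), names(tab))
}

#' Count occurrences of an n-gram in a sequence
#'
#' Counts the (possibly overlapping) occurrences of `z` in `x`. The default
#' fast path is a direct sliding-window scan; `method = "transducer"`
#' evaluates the counting transducer `T_n` on `(x, z)` by composition and
#' path summation. The two routes agree exactly (this is asserted by the test
#' suite, and is the defining property of `T_n`).
#'
#' @param x sequence (string).
#' @param z the n-gram to count; must have `nchar(z) == spec$n`.
#' @param spec an [ngram_spec()].
#' @param method `"window"` (default) or `"transducer"`.
#' @return Integer count (as a number for the transducer route).
#' @examples
#' ngram_count("GCTAAATTGGACAAATCTCAATGAAATTGTCTTGG", "TCT") # 2
#' @export
ngram_count <- function(x, z, spec = ngram_spec(),
                        method = c("window", "transducer")) {
  method <- match.arg(method)
  x <- clean_seq(x); z <- clean_seq(z)
  if (nchar(z) != spec$n)
    stop("length of z (", nchar(z), ") must equal spec n (", spec$n, ")")
  if (method == "window") {
    counts <- suppressWarnings(seq_ngram_counts(x, spec))
    cnt <- counts[z]
    return(if (is.na(cnt)) 0L else as.integer(cnt))
  }
  tn <- ngram_transducer(spec)
  wfst_value(tn, x, z)
}

#' Count of an n-gram in a weighted automaton
#'
#' For an acyclic weighted automaton `A` (a finite weighted language),
#' computes `sum_u c_u(z) * A(u)`: the occurrence count of `z` in each string
#' of the language, weighted by the automaton value of the string. Evaluated
#' as the path sum of `A o T_n o M_z`. For `A` the output projection of a
#' linear acceptor of `x`, this equals `ngram_count(x, z)`.
#'
#' @param a a [wacc] object; must be acyclic.
#' @param z the n-gram; `nchar(z) == spec$n`.
#' @param spec an [ngram_spec()].
#' @return A single number.
#' @export
automaton_ngram_count <- function(a, z, spec = ngram_spec()) {
  stopifnot(inherits(a, "wacc"))
  z <- clean_seq(z)
  if (nchar(z) != spec$n)
    stop("length of z (", nchar(z), ") must equal spec n (", spec$n, ")")
  if (!is_acyclic(a))
    stop("automaton is cyclic; the weighted n-gram count requires a finite language")
  tn <- ngram_transducer(spec)
  mz <- linear_acceptor(z, alphabet = spec$alphabet)
  path_sum(wfst_compose(wfst_compose(as_wfst(a), tn), mz))
}

#' PDS rational kernel from an arbitrary transducer
#'
#' Composes a transducer with its inverse: `U = T o T^-1`. By the standard
#' construction, the kernel `k(x, y) = U(x, y)` realized by such a `U` is
#' positive definite symmetric, hence safe for SVM training; in particular
#' `U_n = T_n o T_n^-1` realizes the n-gram kernel.
#'
#' @param t a [wfst] object composable with its inverse.
#' @return The composed [wfst] `U`.
#' @export
pds_kernel_from <- function(t) {
  wfst_compose(t, wfst_inverse(t))
}

#' n-gram kernel between two sequences
#'
#' Computes `k_n(x, y) = sum_{|z| = n} c_x(z) * c_y(z)`, the inner product of
#' the n-gram count profiles of `x` and `y`. The default route extracts the
#' sparse count vectors (each accepting path of `M_x o T_n` emits one window
#' `z`) and takes their dot product; `method = "transducer"` evaluates the
#' rational kernel `U_n = T_n o T_n^-1` on `(x, y)` by composition and path
#' summation. The two routes agree to within numerical tolerance.
#'
#' @param x,y sequences over `spec$alphabet` (uppercased before counting).
#' @param spec an [ngram_spec()].
#' @param method `"counts"` (default, linear-time) or `"transducer"`.
#' @return A single nonnegative number.
#' @examples
#' ngram_kernel("TCTCT", "TCTCT") # 5 = 2^2 (TCT) + 1 (CTC)
#' @export
ngram_kernel <- function(x, y, spec = ngram_spec(),
                         method = c("counts", "transducer")) {
  method <- match.arg(method)
  if (method == "counts") {
    cx <- seq_ngram_counts(x, spec)
    cy <- seq_ngram_counts(y, spec)
    shared <- intersect(names(cx), names(cy))
    return(sum(as.numeric(cx[shared]) * as.numeric(cy[shared])))
  }
  u <- pds_kernel_from(ngram_transducer(spec))
  wfst_value(u, clean_seq(x), clean_seq(y))
}

#' Base Gram matrix of n-gram kernel values
#'
#' Computes the matrix of pairwise n-gram kernel values over a collection of
#' sequences, each represented (conceptually) as a trivial weighted automaton.
#' With `normalize = TRUE` (the default) the matrix is cosine normalized, so
#' that longer sequences do not score higher merely by containing more
#' n-grams.
#'
#' @param seqs named character vector of sequences (names are the gene ids).
#' @param spec an [ngram_spec()].
#' @param normalize logical; apply [normalize_gram()].
#' @return A [new_gram_matrix()] object over the sequence names.
#' @examples
#' g <- gram_matrix(c(a = "ACGTACGT", b = "TTTACGTA"))
#' diag(g$values) # unit diagonal after normalization
#' @export
gram_matrix <- function(seqs, spec = ngram_spec(), normalize = TRUE) {
  if (length(seqs) == 0L) stop("empty sequence collection")
  ids <- names(seqs)
  if (is.null(ids) || any(ids == ""))
    ids <- as.character(seq_along(seqs))
  counts <- lapply(seqs, seq_ngram_counts, spec = spec)
  grams <- sort(unique(unlist(lapply(counts, names))))
  C <- matrix(0, nrow = length(grams), ncol = length(seqs),
              dimnames = list(grams, ids))
  for (j in seq_along(counts)) {
    cj <- counts[[j]]
    if (length(cj)) C[names(cj), j] <- as.numeric(cj)
  }
  K <- crossprod(C)
  g <- new_gram_matrix(K, ids, normalized = FALSE)
  if (normalize) normalize_gram(g) else g
}
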