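#' Epsilon label
#'
#' The reserved label for the empty symbol on a transition tape, spelled
#' `"<eps>"` in the textual machine format.
#' @export
EPS <- "<eps>"

.SEP <- "\x1f" # separator for composite state keys; never occurs in ids

#' Weighted finite-state transducers
#'
#' A weighted finite-state transducer (WFST) over the real `(+, x)` semiring:
#' a set of states, weighted transitions carrying an input and an output label
#' (either of which may be the empty symbol [EPS]), and initial/final weight
#' functions whose supports play the role of initial and final state sets.
#' A WFST `T` assigns to every pair of strings `(x, y)` the sum over accepting
#' paths with input `x` and output `y` of the product of the initial weight,
#' the transition weights, and the final weight.
#'
#' @param transitions data.frame with columns `src`, `ilab`, `olab`, `weight`,
#'   `dst`. Labels are single symbols or [EPS]; states are arbitrary strings.
#' @param initial named numeric vector of initial weights (support = initial
#'   states).
#' @param final named numeric vector of final weights (support = final states).
#' @param input_alphabet,output_alphabet character vectors of symbols. When
#'   `NULL`, inferred from the non-epsilon labels used.
#' @param states character vector of states. When `NULL`, inferred from
#'   transition endpoints and initial/final supports.
#' @return An object of class `"wfst"`.
#' @seealso [linear_acceptor()], [wfst_compose()], [wfst_inverse()],
#'   [project_output()], [path_sum()], [wfst_value()]
#' @examples
#' t <- wfst(
#'   data.frame(src = "0", ilab = "G", olab = "C", weight = 2, dst = "1"),
#'   initial = c("0" = 1), final = c("1" = 1)
#' )
#' wfst_value(t, "G", "C")
#' @export
wfst <- function(transitions, initial, final,
                 input_alphabet = NULL, output_alphabet = NULL,
                 states = NULL) {
  transitions <- as.data.frame(transitions, stringsAsFactors = FALSE)
  if (nrow(transitions) == 0L) {
    transitions <- data.frame(src = character(), ilab = character(),
                              olab = character(), weight = numeric(),
                              dst = character(), stringsAsFactors = FALSE)
  }
  needed <- c("src", "ilab", "olab", "weight", "dst")
  if (!all(needed %in% names(transitions)))
    stop("transitions must have columns: ", paste(needed, collapse = ", "))
  transitions <- transitions[needed]
  for (cc in c("src", "ilab", "olab", "dst"))
    transitions[[cc]] <- as.character(transitions[[cc]])
  transitions$weight <- as.numeric(transitions$weight)
  if (is.null(states))
    states <- unique(c(transitions$src, transitions$dst,
                       names(initial), names(final)))
  if (is.null(input_alphabet))
    input_alphabet <- setdiff(unique(transitions$ilab), EPS)
  if (is.null(output_alphabet))
    output_alphabet <- setdiff(unique(transitions$olab), EPS)
  m <- structure(
    list(transitions = transitions,
         initial = initial[initial != 0],
         final = final[final != 0],
         input_alphabet = input_alphabet,
         output_alphabet = output_alphabet,
         states = states),
    class = "wfst")
  validate_wfst(m)
  m
}

validate_wfst <- function(m) {
  tr <- m$transitions
  bad <- setdiff(c(tr$src, tr$dst, names(m$initial), names(m$final)), m$states)
  if (length(bad))
    stop("transition endpoint not in state set: ", bad[[1]])
  bad_in <- setdiff(setdiff(unique(tr$ilab), EPS), m$input_alphabet)
  if (length(bad_in))
    stop("input label outside alphabet: ", bad_in[[1]])
  bad_out <- setdiff(setdiff(unique(tr$olab), EPS), m$output_alphabet)
  if (length(bad_out))
    stop("output label outside alphabet: ", bad_out[[1]])
  invisible(m)
}

#' @export
print.wfst <- function(x, ...) {
  cat(sprintf("<wfst: %d states, %d transitions, %d initial, %d final>\n",
              length(x$states), nrow(x$transitions),
              length(x$initial), length(x$final)))
  invisible(x)
}

#' Weighted automata
#'
#' A weighted automaton: a WFST without output labels. Represented with
#' transition columns `src`, `lab`, `weight`, `dst`.
#'
#' @param transitions data.frame with columns `src`, `lab`, `weight`, `dst`.
#' @param initial,final named numeric weight vectors.
#' @param alphabet symbol set; inferred from labels when `NULL`.
#' @param states state set; inferred when `NULL`.
#' @return An object of class `"wacc"`.
#' @seealso [project_output()], [wa_value()]
#' @export
wacc <- function(transitions, initial, final, alphabet = NULL, states = NULL) {
  transitions <- as.data.frame(transitions, stringsAsFactors = FALSE)
  if (nrow(transitions) == 0L) {
    transitions <- data.frame(src = character(), lab = character(),
                              weight = numeric(), dst = character(),
                              stringsAsFactors = FALSE)
  }
  needed <- c("src", "lab", "weight", "dst")
  if (!all(needed %in% names(transitions)))
    stop("transitions must have columns: ", paste(needed, collapse = ", "))
  transitions <- transitions[needed]
  if (is.null(states))
    states <- unique(c(transitions$src, transitions$dst,
                       names(initial), names(final)))
  if (is.null(alphabet))
    alphabet <- setdiff(unique(transitions$lab), EPS)
  structure(
    list(transitions = transitions,
         initial = initial[initial != 0],
         final = final[final != 0],
         alphabet = alphabet,
         states = states),
    class = "wacc")
}

#' @export
print.wacc <- function(x, ...) {
  cat(sprintf("<wacc: %d states, %d transitions>\n",
              length(x$states), nrow(x$transitions)))
  invisible(x)
}

#' Identity transducer view of a weighted automaton
#'
#' Lifts an automaton to a transducer whose transitions carry the automaton
#' label on both tapes (epsilon stays epsilon on both).
#' @param a a [wacc] object.
#' @return A [wfst] object.
#' @export
as_wfst <- function(a) {
  stopifnot(inherits(a, "wacc"))
  tr <- a$transitions
  wfst(data.frame(src = tr$src, ilab = tr$lab, olab = tr$lab,
                  weight = tr$weight, dst = tr$dst,
                  stringsAsFactors = FALSE),
       initial = a$initial, final = a$final,
       input_alphabet = a$alphabet, output_alphabet = a$alphabet,
       states = a$states)
}

#' Trivial linear acceptor of a string
#'
#' Builds the trivial weighted transducer `M_x` for a string `x`: a chain of
#' `|x| + 1` states whose i-th transition carries `(x_i : x_i)` with weight 1,
#' with unit initial and final weights. `M_x` assigns value 1 to the pair
#' `(x, x)` and 0 to every other pair, which makes it the plug-in
#' representation of a sequence in rational-kernel evaluation.
#'
#' @param x a single string (split into characters) or a character vector of
#'   symbols; may be empty.
#' @param alphabet declared symbol set; defaults to the symbols of `x`.
#' @return A [wfst] object with `|x| + 1` states named `"0" ... "|x|"`.
#' @examples
#' m <- linear_acceptor("GGC")
#' wfst_value(m, "GGC", "GGC") # 1
#' @export
linear_acceptor <- function(x, alphabet = NULL) {
  syms <- if (length(x) == 1L) strsplit(x, "")[[1]] else as.character(x)
  if (is.null(alphabet)) alphabet <- unique(syms)
  bad <- setdiff(syms, alphabet)
  if (length(bad))
    stop("symbol outside declared alphabet: ", bad[[1]])
  n <- length(syms)
  states <- as.character(seq_len(n + 1L) - 1L)
  tr <- if (n > 0L) {
    data.frame(src = states[seq_len(n)], ilab = syms, olab = syms,
               weight = 1, dst = states[seq_len(n) + 1L],
               stringsAsFactors = FALSE)
  } else {
    data.frame(src = character(), ilab = character(), olab = character(),
               weight = numeric(), dst = character(), stringsAsFactors = FALSE)
  }
  ini <- c(1); names(ini) <- states[[1L]]
  fin <- c(1); names(fin) <- states[[n + 1L]]
  wfst(tr, ini, fin, input_alphabet = alphabet, output_alphabet = alphabet,
       states = states)
}

#' Transducer inverse
#'
#' Swaps the input and output tape of every transition, so that
#' `inverse(T)(y, x) = T(x, y)` for all string pairs.
#'
#' @param t a [wfst] object.
#' @return The inverse [wfst].
#' @export
wfst_inverse <- function(t) {
  stopifnot(inherits(t, "wfst"))
  tr <- t$transitions
  wfst(data.frame(src = tr$src, ilab = tr$olab, olab = tr$ilab,
                  weight = tr$weight, dst = tr$dst, stringsAsFactors = FALSE),
       initial = t$initial, final = t$final,
       input_alphabet = t$output_alphabet,
       output_alphabet = t$input_alphabet,
       states = t$states)
}

# Composition with the standard epsilon filter.
#
# A composed state is (q1, q2, f) with filter state f in {0,1,2}. Between two
# synchronized (non-epsilon) moves, a path may take epsilon-output moves of t1
# and epsilon-input moves of t2; without a filter every interleaving of those
# two blocks would be counted, breaking (T1 o T2)(x,y) = sum_z T1(x,z) T2(z,y).
# The filter forces the unique order "all t1-epsilon moves first, then all
# t2-epsilon moves": t1 epsilon moves are allowed from f in {0,1} (-> 1),
# t2 epsilon moves from any f (-> 2), synchronized moves from any f (-> 0).

#' Transducer composition
#'
#' Computes `T1 o T2` with `(T1 o T2)(x, y) = sum_z T1(x, z) * T2(z, y)`,
#' using an epsilon-filter construction so that paths in which both machines
#' move on the shared tape with epsilon are counted exactly once.
#'
#' @param t1,t2 [wfst] objects; the output alphabet of `t1` must equal the
#'   input alphabet of `t2`.
#' @return The composed [wfst] (states reachable from the initial pairs only).
#' @examples
#' m <- linear_acceptor("GC")
#' mm <- wfst_compose(m, wfst_inverse(m))
#' path_sum(mm) # 1
#' @export
wfst_compose <- function(t1, t2) {
  stopifnot(inherits(t1, "wfst"), inherits(t2, "wfst"))
  if (!setequal(t1$output_alphabet, t2$input_alphabet))
    stop("alphabet mismatch: output alphabet of t1 must equal input alphabet of t2")

  tr1 <- t1$transitions
  tr2 <- t2$transitions
  tr1m <- tr1[tr1$olab != EPS, , drop = FALSE]
  tr1e <- tr1[tr1$olab == EPS, , drop = FALSE]
  tr2m <- tr2[tr2$ilab != EPS, , drop = FALSE]
  tr2e <- tr2[tr2$ilab == EPS, , drop = FALSE]

  ini1 <- names(t1$initial); ini2 <- names(t2$initial)
  if (length(ini1) == 0L || length(ini2) == 0L) {
    return(wfst(data.frame(src = character(), ilab = character(),
                           olab = character(), weight = numeric(),
                           dst = character()),
                initial = stats::setNames(numeric(0), character(0)),
                final = stats::setNames(numeric(0), character(0)),
                input_alphabet = t1$input_alphabet,
                output_alphabet = t2$output_alphabet,
                states = "dead"))
  }
  start <- expand.grid(q1 = ini1, q2 = ini2, stringsAsFactors = FALSE)
  start$f <- 0L
  key <- function(q1, q2, f) paste(q1, q2, f, sep = .SEP)
  seen <- new.env(parent = emptyenv())
  frontier <- unique(start)
  for (k in key(frontier$q1, frontier$q2, frontier$f))
    assign(k, TRUE, envir = seen)
  out <- list()
  state_tab <- list(data.frame(q1 = frontier$q1, q2 = frontier$q2,
                               f = frontier$f,
                               key = key(frontier$q1, frontier$q2, frontier$f),
                               stringsAsFactors = FALSE))

  while (nrow(frontier) > 0L) {
    pieces <- list()
    # synchronized moves (allowed from every filter state, reset f to 0)
    if (nrow(tr1m) && nrow(tr2m)) {
      m1 <- merge(frontier, tr1m, by.x = "q1", by.y = "src")
      if (nrow(m1)) {
        m2 <- merge(m1,
                    stats::setNames(tr2m, c("q2s", "mlab", "olab2", "w2", "dst2")),
                    by.x = c("q2", "olab"), by.y = c("q2s", "mlab"))
        if (nrow(m2))
          pieces[[length(pieces) + 1L]] <- data.frame(
            src = key(m2$q1, m2$q2, m2$f),
            ilab = m2$ilab, olab = m2$olab2,
            weight = m2$weight * m2$w2,
            dst = key(m2$dst, m2$dst2, 0L),
            q1n = m2$dst, q2n = m2$dst2, fn = 0L,
            stringsAsFactors = FALSE)
      }
    }
    # t1 moves alone on an epsilon output (allowed from f in {0,1})
    if (nrow(tr1e)) {
      fe <- frontier[frontier$f != 2L, , drop = FALSE]
      if (nrow(fe)) {
        e1 <- merge(fe, tr1e, by.x = "q1", by.y = "src")
        if (nrow(e1))
          pieces[[length(pieces) + 1L]] <- data.frame(
            src = key(e1$q1, e1$q2, e1$f),
            ilab = e1$ilab, olab = EPS,
            weight = e1$weight,
            dst = key(e1$dst, e1$q2, 1L),
            q1n = e1$dst, q2n = e1$q2, fn = 1L,
            stringsAsFactors = FALSE)
      }
    }
    # t2 moves alone on an epsilon input (allowed from every filter state)
    if (nrow(tr2e)) {
      e2 <- merge(frontier, tr2e, by.x = "q2", by.y = "src")
      if (nrow(e2))
        pieces[[length(pieces) + 1L]] <- data.frame(
          src = key(e2$q1, e2$q2, e2$f),
          ilab = EPS, olab = e2$olab,
          weight = e2$weight,
          dst = key(e2$q1, e2$dst, 2L),
          q1n = e2$q1, q2n = e2$dst, fn = 2L,
          stringsAsFactors = FALSE)
    }
    if (length(pieces) == 0L) break
    new_tr <- do.call(rbind, pieces)
    out[[length(out) + 1L]] <- new_tr[c("src", "ilab", "olab", "weight", "dst")]
    nxt <- unique(new_tr[c("q1n", "q2n", "fn", "dst")])
    fresh <- !vapply(nxt$dst, function(k) exists(k, envir = seen),
                     logical(1L), USE.NAMES = FALSE)
    nxt <- nxt[fresh, , drop = FALSE]
    for (k in nxt$dst) assign(k, TRUE, envir = seen)
    if (nrow(nxt))
      state_tab[[length(state_tab) + 1L]] <-
        data.frame(q1 = nxt$q1n, q2 = nxt$q2n, f = nxt$fn, key = nxt$dst,
                   stringsAsFactors = FALSE)
    frontier <- data.frame(q1 = nxt$q1n, q2 = nxt$q2n, f = nxt$fn,
                           stringsAsFactors = FALSE)
  }

  transitions <- if (length(out)) do.call(rbind, out) else
    data.frame(src = character(), ilab = character(), olab = character(),
               weight = numeric(), dst = character(), stringsAsFactors = FALSE)
  state_tab <- do.call(rbind, state_tab)
  states <- state_tab$key

  ini_keys <- key(start$q1, start$q2, 0L)
  ini_w <- as.numeric(t1$initial[start$q1]) * as.numeric(t2$initial[start$q2])
  initial <- stats::setNames(ini_w, ini_keys)

  # final weight of (q1, q2, f) = rho1(q1) * rho2(q2), any filter state
  r1 <- t1$final[state_tab$q1]; r1[is.na(r1)] <- 0
  r2 <- t2$final[state_tab$q2]; r2[is.na(r2)] <- 0
  fw <- as.numeric(r1) * as.numeric(r2)
  final <- stats::setNames(fw, states)

  wfst(transitions, initial, final,
       input_alphabet = t1$input_alphabet,
       output_alphabet = t2$output_alphabet,
       states = states)
}

#' Output projection of a transducer
#'
#' Drops the input labels of a transducer, yielding the weighted automaton
#' `A` with `A(y) = sum_x T(x, y)`; transitions whose output label is epsilon
#' become epsilon moves.
#'
#' @param t a [wfst] object.
#' @return A [wacc] object over the output alphabet of `t`.
#' @export
project_output <- function(t) {
  stopifnot(inherits(t, "wfst"))
  tr <- t$transitions
  wacc(data.frame(src = tr$src, lab = tr$olab, weight = tr$weight,
                  dst = tr$dst, stringsAsFactors = FALSE),
       initial = t$initial, final = t$final,
       alphabet = t$output_alphabet, states = t$states)
}

machine_edges <- function(m) {
  m$transitions[c("src", "dst", "weight")]
}

# Remove states that are not on some initial -> final path.
trim_machine <- function(m) {
  tr <- machine_edges(m)
  ini <- names(m$initial); fin <- names(m$final)
  if (length(ini) == 0L || length(fin) == 0L) {
    m$transitions <- m$transitions[0, , drop = FALSE]
    m$states <- character(0)
    m$initial <- m$initial[0]; m$final <- m$final[0]
    return(m)
  }
  verts <- unique(c(m$states, ini, fin))
  g <- igraph::graph_from_data_frame(
    data.frame(from = tr$src, to = tr$dst, stringsAsFactors = FALSE),
    directed = TRUE, vertices = data.frame(name = verts))
  fwd <- unique(unlist(lapply(ini, function(v)
    names(igraph::subcomponent(g, v, mode = "out")))))
  bwd <- unique(unlist(lapply(fin, function(v)
    names(igraph::subcomponent(g, v, mode = "in")))))
  keep <- intersect(fwd, bwd)
  m$states <- keep
  m$transitions <- m$transitions[m$transitions$src %in% keep &
                                 m$transitions$dst %in% keep, , drop = FALSE]
  m$initial <- m$initial[names(m$initial) %in% keep]
  m$final <- m$final[names(m$final) %in% keep]
  m
}

#' Is a machine acyclic?
#'
#' Tests whether the transition graph of a transducer or automaton has no
#' directed cycle (epsilon moves included), by topological sorting.
#' @param m a [wfst] or [wacc] object.
#' @return `TRUE`/`FALSE`.
#' @export
is_acyclic <- function(m) {
  tr <- machine_edges(m)
  if (nrow(tr) == 0L) return(TRUE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = tr$src, to = tr$dst, stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = unique(c(m$states, tr$src, tr$dst))))
  igraph::is_dag(g)
}

cycle_state <- function(m) {
  tr <- machine_edges(m)
  loops <- tr$src[tr$src == tr$dst]
  if (length(loops)) return(loops[[1L]])
  g <- igraph::graph_from_data_frame(
    data.frame(from = tr$src, to = tr$dst, stringsAsFactors = FALSE),
    directed = TRUE, vertices = data.frame(name = m$states))
  comp <- igraph::components(g, mode = "strong")
  big <- which(comp$csize > 1L)[1L]
  names(comp$membership)[comp$membership == big][1L]
}

#' Exact sum over accepting paths
#'
#' Sums, over every accepting path of an acyclic machine, the product of the
#' initial weight, the transition weights, and the final weight. States not on
#' an initial-to-final path are trimmed first; a machine whose trimmed part
#' still has a directed cycle is rejected (this artifact only performs exact
#' summation, which requires acyclicity).
#'
#' @param m a [wfst] or [wacc] object.
#' @return A single number; 0 when no accepting path exists.
#' @examples
#' m <- linear_acceptor("GC")
#' path_sum(wfst_compose(m, wfst_inverse(m))) # 1
#' @export
path_sum <- function(m) {
  stopifnot(inherits(m, "wfst") || inherits(m, "wacc"))
  m <- trim_machine(m)
  if (length(m$states) == 0L) return(0)
  tr <- machine_edges(m)
  if (nrow(tr) == 0L) {
    # only states that are both initial and final survive trimming
    both <- intersect(names(m$initial), names(m$final))
    return(sum(as.numeric(m$initial[both]) * as.numeric(m$final[both])))
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = tr$src, to = tr$dst, stringsAsFactors = FALSE),
    directed = TRUE, vertices = data.frame(name = m$states))
  if (!igraph::is_dag(g))
    stop("machine is cyclic after trimming (state on a cycle: ",
         cycle_state(m), "); exact path summation requires acyclicity")
  ord <- names(igraph::topo_sort(g, mode = "out"))
  fwd <- stats::setNames(numeric(length(ord)), ord)
  ini <- m$initial
  fwd[names(ini)] <- as.numeric(ini)
  by_dst <- split(seq_len(nrow(tr)), tr$dst)
  for (q in ord) {
    idx <- by_dst[[q]]
    if (!is.null(idx))
      fwd[[q]] <- fwd[[q]] + sum(fwd[tr$src[idx]] * tr$weight[idx])
  }
  fin <- m$final
  sum(fwd[names(fin)] * as.numeric(fin))
}

#' Transducer value on a pair of strings
#'
#' Evaluates `T(x, y)` as the path sum of `M_x o T o M_y`, where `M_x`, `M_y`
#' are the trivial linear acceptors of `x` and `y`.
#'
#' @param t a [wfst] object.
#' @param x,y strings over the input/output alphabets of `t`.
#' @return `T(x, y)` as a single number.
#' @examples
#' m <- linear_acceptor("AC")
#' wfst_value(wfst_compose(m, wfst_inverse(m)), "AC", "AC") # 1
#' @export
wfst_value <- function(t, x, y) {
  stopifnot(inherits(t, "wfst"))
  mx <- linear_acceptor(x, alphabet = t$input_alphabet)
  my <- linear_acceptor(y, alphabet = t$output_alphabet)
  path_sum(wfst_compose(wfst_compose(mx, t), my))
}

#' Weighted automaton value on a string
#'
#' Evaluates `A(y)`, the sum over accepting paths labelled `y` of the product
#' of weights, by composing the linear acceptor of `y` with the identity
#' transducer view of `A`.
#'
#' @param a a [wacc] object.
#' @param y a string over the alphabet of `a`.
#' @return `A(y)` as a single number.
#' @export
wa_value <- function(a, y) {
  stopifnot(inherits(a, "wacc"))
  my <- linear_acceptor(y, alphabet = a$alphabet)
  path_sum(wfst_compose(my, as_wfst(a)))
}
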