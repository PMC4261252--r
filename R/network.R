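#' Metabolic network graph
#'
#' An undirected simple graph whose nodes are enzymes (or genes) and whose
#' edges are enzyme-enzyme relations: two enzymes are connected when they
#' catalyze successive reactions (the product of one reaction is a substrate
#' of the other). Edges are unordered id pairs; duplicates and reversed
#' duplicates are collapsed (with a logged count) and self-loops are not
#' allowed.
#'
#' @param edges data.frame (or 2-column matrix) whose first two columns are
#'   the edge endpoints; may be empty.
#' @param nodes optional character vector of node ids (isolated nodes are
#'   allowed); defaults to the ids appearing in `edges`.
#' @return An object of class `"metabolic_graph"` with elements `nodes`
#'   (character) and `edges` (data.frame with columns `a`, `b`,
#'   lexicographically ordered within each row).
#' @seealso [reactions_to_graph()], [label_pairs()], [count_noninteracting()],
#'   [balanced_negative_sample()]
#' @export
metabolic_graph <- function(edges = NULL, nodes = NULL) {
  if (is.null(edges) || NROW(edges) == 0L) {
    ed <- data.frame(a = character(), b = character(), stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    a0 <- as.character(edges[[1]]); b0 <- as.character(edges[[2]])
    if (any(a0 == b0))
      stop("self-loop edge not allowed: ", a0[a0 == b0][[1]])
    ed <- data.frame(a = pmin(a0, b0), b = pmax(a0, b0),
                     stringsAsFactors = FALSE)
    dup <- duplicated(paste(ed$a, ed$b, sep = "\t"))
    if (any(dup)) {
      message("collapsed ", sum(dup), " duplicate edge(s)")
      ed <- ed[!dup, , drop = FALSE]
    }
    rownames(ed) <- NULL
  }
  nodes <- unique(c(as.character(nodes), ed$a, ed$b))
  structure(list(nodes = nodes, edges = ed), class = "metabolic_graph")
}

#' @export
print.metabolic_graph <- function(x, ...) {
  cat(sprintf("<metabolic_graph: %d nodes, %d edges>\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

edge_keys <- function(g) paste(g$edges$a, g$edges$b, sep = "\t")

#' Graph from a reaction table
#'
#' Converts a list of enzyme-catalyzed reactions into the enzyme graph: an
#' edge `{e1, e2}` is drawn whenever some product of a reaction catalyzed by
#' `e1` is a substrate of a reaction catalyzed by `e2` (or vice versa), with
#' `e1 != e2` (an enzyme consuming its own product yields no self-loop).
#'
#' @param reactions data.frame with columns `enzyme`, `substrates`,
#'   `products`; the latter two are comma-separated metabolite ids (or list
#'   columns of character vectors).
#' @return A [metabolic_graph()] whose nodes are all enzymes in the table.
#' @examples
#' rx <- data.frame(enzyme = c("EC5.3.1.9", "EC2.7.1.11"),
#'                  substrates = c("G6P", "F6P"),
#'                  products = c("F6P", "F16BP"))
#' reactions_to_graph(rx)
#' @export
reactions_to_graph <- function(reactions) {
  if (NROW(reactions) == 0L) return(metabolic_graph())
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  parse_set <- function(col) {
    if (is.list(col)) lapply(col, as.character)
    else strsplit(as.character(col), ",[ ]*")
  }
  enz <- as.character(reactions$enzyme)
  subs <- parse_set(reactions$substrates)
  prods <- parse_set(reactions$products)
  if (any(lengths(subs) == 0L) || any(lengths(prods) == 0L))
    stop("each reaction needs at least one substrate and one product")
  prod_tab <- data.frame(
    enzyme = rep(enz, lengths(prods)),
    met = unlist(prods), stringsAsFactors = FALSE)
  sub_tab <- data.frame(
    enzyme = rep(enz, lengths(subs)),
    met = unlist(subs), stringsAsFactors = FALSE)
  hit <- merge(prod_tab, sub_tab, by = "met",
               suffixes = c("_producer", "_consumer"))
  hit <- hit[hit$enzyme_producer != hit$enzyme_consumer, , drop = FALSE]
  if (nrow(hit) == 0L) return(metabolic_graph(nodes = unique(enz)))
  metabolic_graph(
    suppressMessages(
      unique(data.frame(a = pmin(hit$enzyme_producer, hit$enzyme_consumer),
                        b = pmax(hit$enzyme_producer, hit$enzyme_consumer),
                        stringsAsFactors = FALSE))),
    nodes = unique(enz))
}

#' Label every node pair of a graph
#'
#' Produces the exhaustive training universe: every unordered node pair
#' labelled `+1` when it is an edge (interacting) and `-1` otherwise.
#'
#' @param g a [metabolic_graph()] with at least 2 nodes.
#' @return A [pairwise_points()] frame with `choose(n, 2)` rows.
#' @export
label_pairs <- function(g) {
  stopifnot(inherits(g, "metabolic_graph"))
  if (length(g$nodes) < 2L) stop("need at least 2 nodes")
  cmb <- utils::combn(sort(g$nodes), 2L)
  pp <- pairwise_points(cmb[1L, ], cmb[2L, ])
  pp$label <- ifelse(pp$pair_id %in% paste(g$edges$a, g$edges$b, sep = "|"),
                     1L, -1L)
  pp
}

#' Number of non-interacting pairs
#'
#' `choose(n, 2) - |edges|` for a simple graph on `n` nodes.
#' @param g a [metabolic_graph()].
#' @return Integer count.
#' @export
count_noninteracting <- function(g) {
  stopifnot(inherits(g, "metabolic_graph"))
  as.integer(choose(length(g$nodes), 2) - nrow(g$edges))
}

#' Balanced sampling of non-interacting pairs
#'
#' Draws `n_neg` distinct non-edge pairs labelled `-1` to balance a training
#' set of interacting pairs. In `"degree_matched"` mode (the default) each
#' endpoint is drawn with probability proportional to its degree in the
#' positive set, rejecting edges, self-pairs and duplicates, so that the node
#' frequency distribution of the negative set approximates that of the
#' positive set and the classifier cannot score pairs by node popularity
#' alone. `"uniform"` mode samples uniformly from all non-edges.
#'
#' @param g a [metabolic_graph()].
#' @param n_neg number of negatives, at most [count_noninteracting()]`(g)`.
#' @param seed integer seed; sampling is fully reproducible given the seed.
#' @param mode `"degree_matched"` or `"uniform"`.
#' @return A [pairwise_points()] frame of `n_neg` distinct pairs with label
#'   `-1`.
#' @export
balanced_negative_sample <- function(g, n_neg, seed,
                                     mode = c("degree_matched", "uniform")) {
  stopifnot(inherits(g, "metabolic_graph"))
  mode <- match.arg(mode)
  n_neg <- as.integer(n_neg)
  avail <- count_noninteracting(g)
  if (n_neg > avail)
    stop("requested ", n_neg, " negatives but only ", avail,
         " non-interacting pairs exist")
  if (n_neg == 0L)
    return(pairwise_points(character(0), character(0), integer(0)))
  ek <- edge_keys(g)
  with_seed(seed, {
    if (mode == "uniform") {
      cmb <- utils::combn(sort(g$nodes), 2L)
      keys <- paste(cmb[1L, ], cmb[2L, ], sep = "\t")
      pool <- which(!keys %in% ek)
      pick <- sample(pool, n_neg)
      return(pairwise_points(cmb[1L, pick], cmb[2L, pick], -1L))
    }
    deg <- table(factor(c(g$edges$a, g$edges$b), levels = g$nodes))
    w <- as.numeric(deg)
    if (sum(w) == 0) stop("degree-matched sampling requires at least one edge")
    chosen <- character(0)
    tries <- 0L
    while (length(chosen) < n_neg) {
      tries <- tries + 1L
      if (tries > 10000L)
        stop("degree-matched rejection sampling failed to find ", n_neg,
             " distinct non-edges; use mode = \"uniform\"")
      m <- max(64L, 2L * (n_neg - length(chosen)))
      i <- sample(g$nodes, m, replace = TRUE, prob = w)
      j <- sample(g$nodes, m, replace = TRUE, prob = w)
      ok <- i != j
      a <- pmin(i[ok], j[ok]); b <- pmax(i[ok], j[ok])
      key <- paste(a, b, sep = "\t")
      keep <- !key %in% ek & !duplicated(key) & !key %in% chosen
      chosen <- c(chosen, key[keep])
    }
    chosen <- chosen[seq_len(n_neg)]
    parts <- do.call(rbind, strsplit(chosen, "\t", fixed = TRUE))
    pairwise_points(parts[, 1L], parts[, 2L], -1L)
  })
}

#' Assemble a balanced labelled training set
#'
#' Convenience wrapper: all interacting pairs of the graph labelled `+1` plus
#' `n_neg` sampled non-interacting pairs labelled `-1`.
#'
#' @inheritParams balanced_negative_sample
#' @param n_neg number of negatives; defaults to one fewer than the number of
#'   positives when `NULL` is given (a balanced set of odd total size).
#' @return A [pairwise_points()] frame.
#' @export
balanced_training_pairs <- function(g, n_neg = NULL, seed,
                                    mode = c("degree_matched", "uniform")) {
  stopifnot(inherits(g, "metabolic_graph"))
  pos <- pairwise_points(g$edges$a, g$edges$b, 1L)
  if (is.null(n_neg)) n_neg <- nrow(pos) - 1L
  neg <- balanced_negative_sample(g, n_neg, seed, mode)
  out <- rbind(pos, neg)
  rownames(out) <- NULL
  class(out) <- c("pairwise_points", "data.frame")
  out
}
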