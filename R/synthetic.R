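#' Configuration of the planted-motif benchmark generator
#'
#' Describes a synthetic study in which genes are partitioned into pathway
#' modules: genes of the same module interact (edges of the planted network)
#' and share module-private sequence motifs inserted into otherwise random
#' background sequence, so that an n-gram kernel carries signal about the
#' module structure. Setting `motif_copies = 0` yields the matched no-signal
#' null model (same graph, pure background sequences).
#'
#' @param n_genes number of genes.
#' @param seq_length length of every gene sequence (insertions replace
#'   background characters, so the length is invariant).
#' @param alphabet symbol set (default nucleotides).
#' @param n_modules number of pathway modules; module sizes are as equal as
#'   possible with the remainder spread over the earliest modules.
#' @param motif_length length of each planted motif (default 6).
#' @param motifs_per_module number of private motifs per module (default 2).
#' @param motif_copies copies of each motif inserted per member gene
#'   (default 3; 0 disables the signal).
#' @param gc_bias background composition bias in `[-1, 1]`: sampling weight
#'   `1 + gc_bias` for G/C and `1 - gc_bias` for A/T (default 0, i.i.d.
#'   uniform).
#' @param seed integer seed; generation is fully reproducible.
#' @return An object of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_genes = 60L, seq_length = 300L,
                             alphabet = c("A", "C", "G", "T"),
                             n_modules = 6L, motif_length = 6L,
                             motifs_per_module = 2L, motif_copies = 3L,
                             gc_bias = 0, seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              seq_length = as.integer(seq_length),
              alphabet = as.character(alphabet),
              n_modules = as.integer(n_modules),
              motif_length = as.integer(motif_length),
              motifs_per_module = as.integer(motifs_per_module),
              motif_copies = as.integer(motif_copies),
              gc_bias = as.numeric(gc_bias),
              seed = as.integer(seed))
  if (cfg$n_modules > cfg$n_genes)
    stop("n_modules must not exceed n_genes")
  if (cfg$seq_length <= cfg$motif_length * cfg$motif_copies)
    stop("seq_length must exceed motif_length * motif_copies")
  total_ins <- cfg$motif_length * cfg$motif_copies * cfg$motifs_per_module
  if (total_ins > cfg$seq_length)
    stop("motif insertions (", total_ins, " bases) do not fit in seq_length ",
         cfg$seq_length)
  if (abs(cfg$gc_bias) > 1) stop("gc_bias must be in [-1, 1]")
  structure(cfg, class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_config: %d genes x %d bp, %d modules, ",
                     "%d motif(s) x %d copies (len %d), seed %d>\n"),
              x$n_genes, x$seq_length, x$n_modules, x$motifs_per_module,
              x$motif_copies, x$motif_length, x$seed))
  invisible(x)
}

# non-overlapping insertion start positions for `m` blocks of length `len`
# inside 1..L, by rejection
insertion_starts <- function(m, len, L, max_tries = 1000L) {
  if (m == 0L) return(integer(0))
  for (i in seq_len(max_tries)) {
    starts <- sort(sample.int(L - len + 1L, m))
    if (m == 1L || all(diff(starts) >= len)) return(starts)
  }
  stop("could not place ", m, " non-overlapping motif copies of length ",
       len, " in a sequence of length ", L)
}

#' Generate a planted-motif benchmark
#'
#' Draws the synthetic study described by a [synthetic_config()]: module
#' assignments, module-private motifs, background sequences with motif
#' insertions, and the planted interaction graph (complete within modules,
#' empty across).
#'
#' @param config a [synthetic_config()].
#' @return A list with elements `sequences` (named character vector),
#'   `graph` (a [metabolic_graph()]), `modules` (named integer vector of
#'   module assignments), `motifs` (list of character vectors per module) and
#'   `config`.
#' @examples
#' sim <- generate_synthetic(synthetic_config(n_genes = 8, n_modules = 2,
#'                                            seq_length = 120, seed = 7))
#' sim$graph
#' @export
generate_synthetic <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  with_seed(cfg$seed, {
    ids <- sprintf("g%0*d", nchar(as.character(cfg$n_genes)),
                   seq_len(cfg$n_genes))
    base_size <- cfg$n_genes %/% cfg$n_modules
    sizes <- rep(base_size, cfg$n_modules)
    rem <- cfg$n_genes %% cfg$n_modules
    if (rem > 0L) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
    modules <- stats::setNames(rep(seq_len(cfg$n_modules), sizes), ids)

    w <- ifelse(cfg$alphabet %in% c("G", "C"),
                1 + cfg$gc_bias, 1 - cfg$gc_bias)
    motifs <- lapply(seq_len(cfg$n_modules), function(mod) {
      vapply(seq_len(cfg$motifs_per_module), function(i)
        paste(sample(cfg$alphabet, cfg$motif_length, replace = TRUE),
              collapse = ""),
        character(1L))
    })

    sequences <- vapply(ids, function(id) {
      chars <- sample(cfg$alphabet, cfg$seq_length, replace = TRUE, prob = w)
      mod_motifs <- motifs[[modules[[id]]]]
      ins <- rep(mod_motifs, each = cfg$motif_copies)
      if (length(ins)) {
        starts <- insertion_starts(length(ins), cfg$motif_length,
                                   cfg$seq_length)
        # random pairing of motif copies with slots
        ins <- ins[sample.int(length(ins))]
        for (j in seq_along(ins)) {
          s <- starts[[j]]
          chars[s:(s + cfg$motif_length - 1L)] <- strsplit(ins[[j]], "")[[1]]
        }
      }
      paste(chars, collapse = "")
    }, character(1L))

    edges <- do.call(rbind, lapply(seq_len(cfg$n_modules), function(mod) {
      members <- ids[modules == mod]
      if (length(members) < 2L) return(NULL)
      cmb <- utils::combn(members, 2L)
      data.frame(a = cmb[1L, ], b = cmb[2L, ], stringsAsFactors = FALSE)
    }))
    graph <- metabolic_graph(edges, nodes = ids)

    list(sequences = sequences, graph = graph, modules = modules,
         motifs = motifs, config = cfg)
  })
}
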