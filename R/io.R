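#' Read sequences from FASTA
#'
#' Reads a FASTA file into a named character vector (record id = gene id),
#' uppercasing the sequences and preserving record order. Duplicate ids and
#' empty records are rejected with the offending record named.
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids))
    stop("duplicate FASTA id: ", ids[duplicated(ids)][[1]])
  seqs <- toupper(as.character(x))
  names(seqs) <- ids
  empty <- ids[nchar(seqs) == 0L]
  if (length(empty)) stop("empty FASTA record: ", empty[[1]])
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @param width line wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    stop("sequences must be named")
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = as.integer(width))
  invisible(path)
}

#' Read / write an edge list as TSV
#'
#' Two tab-separated columns of gene ids; a `gene_a<TAB>gene_b` header is
#' written on output and skipped on input when present.
#' @param path TSV file.
#' @return `read_edge_list()`: a [metabolic_graph()];
#'   `write_edge_list()`: `path` invisibly.
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) && identical(tolower(lines[[1]]), "gene_a\tgene_b"))
    lines <- lines[-1]
  if (length(lines) == 0L) return(metabolic_graph())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2L))
    stop("malformed edge list line: ", lines[lengths(parts) < 2L][[1]])
  metabolic_graph(data.frame(a = vapply(parts, `[[`, "", 1L),
                             b = vapply(parts, `[[`, "", 2L),
                             stringsAsFactors = FALSE))
}

#' @param g a [metabolic_graph()].
#' @rdname read_edge_list
#' @export
write_edge_list <- function(g, path) {
  stopifnot(inherits(g, "metabolic_graph"))
  writeLines(c("gene_a\tgene_b", paste(g$edges$a, g$edges$b, sep = "\t")),
             path)
  invisible(path)
}

#' Read / write labelled gene pairs as TSV
#'
#' Three tab-separated columns `gene_a`, `gene_b`, `label` with label in
#' `{+1, -1}` (written with explicit sign).
#' @param path TSV file.
#' @return `read_labeled_pairs()`: a [pairwise_points()] frame;
#'   `write_labeled_pairs()`: `path` invisibly.
#' @export
read_labeled_pairs <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("gene_a", "gene_b", "label") %in% names(tab)))
    stop("labelled pair file needs columns gene_a, gene_b, label")
  lab <- as.integer(gsub("^\\+", "", as.character(tab$label)))
  pairwise_points(tab$gene_a, tab$gene_b, lab)
}

#' @param pairs a [pairwise_points()] frame.
#' @rdname read_labeled_pairs
#' @export
write_labeled_pairs <- function(pairs, path) {
  lab <- ifelse(is.na(pairs$label), "NA",
                sprintf("%+d", as.integer(pairs$label)))
  writeLines(c("gene_a\tgene_b\tlabel",
               paste(pairs$x, pairs$y, lab, sep = "\t")),
             path)
  invisible(path)
}

#' Write predictions as TSV
#'
#' Columns `gene_a`, `gene_b`, `score`, `label` (score at 12 significant
#' digits, label with explicit sign).
#' @param pairs a [pairwise_points()] frame of query pairs.
#' @param scores numeric decision values.
#' @param labels `+1`/`-1` predicted labels.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(pairs, scores, labels, path) {
  writeLines(c("gene_a\tgene_b\tscore\tlabel",
               paste(pairs$x, pairs$y, fmt_num(scores),
                     sprintf("%+d", as.integer(labels)), sep = "\t")),
             path)
  invisible(path)
}

#' @rdname write_predictions
#' @param path TSV file written by [write_predictions()].
#' @return `read_predictions()`: data.frame with columns `gene_a`, `gene_b`,
#'   `score`, `label`.
#' @export
read_predictions <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  tab$label <- as.integer(gsub("^\\+", "", as.character(tab$label)))
  tab
}

#' Read / write a machine in the textual format
#'
#' One line per transition `src<TAB>in<TAB>out<TAB>weight<TAB>dst` with
#' epsilon spelled `<eps>`, plus `initial<TAB>state<TAB>weight` and
#' `final<TAB>state<TAB>weight` lines (in any order). Comment lines starting
#' with `#` and blank lines are ignored on input.
#'
#' @param path text file.
#' @return `read_wfst()`: a [wfst]; `write_wfst()`: `path` invisibly.
#' @export
read_wfst <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  kind <- vapply(parts, `[[`, "", 1L)
  ini <- parts[kind == "initial"]
  fin <- parts[kind == "final"]
  tra <- parts[!(kind %in% c("initial", "final"))]
  if (any(lengths(tra) != 5L))
    stop("malformed transition line in ", path)
  getcol <- function(lst, i) vapply(lst, `[[`, "", i)
  transitions <- data.frame(
    src = getcol(tra, 1L), ilab = getcol(tra, 2L), olab = getcol(tra, 3L),
    weight = as.numeric(getcol(tra, 4L)), dst = getcol(tra, 5L),
    stringsAsFactors = FALSE)
  initial <- stats::setNames(as.numeric(getcol(ini, 3L)), getcol(ini, 2L))
  final <- stats::setNames(as.numeric(getcol(fin, 3L)), getcol(fin, 2L))
  wfst(transitions, initial, final)
}

#' @param t a [wfst] object.
#' @rdname read_wfst
#' @export
write_wfst <- function(t, path) {
  stopifnot(inherits(t, "wfst"))
  tr <- t$transitions
  lines <- c(
    paste("initial", names(t$initial), fmt_num(t$initial), sep = "\t"),
    paste("final", names(t$final), fmt_num(t$final), sep = "\t"),
    paste(tr$src, tr$ilab, tr$olab, fmt_num(tr$weight), tr$dst, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
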