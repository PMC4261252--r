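#' Worked-example machines and sequences
#'
#' Small bundled fixtures used in the documentation and tests:
#'
#' * `demo_transducer()` returns a 4-state weighted transducer over `{G, C}`
#'   with exactly two accepting paths for the pair `(GGC, CCG)`, of weights
#'   `1*2*3*6*1` and `1*3*1*4*1`, so its value on that pair is 48. It is
#'   shipped in the textual machine format and exercises [read_wfst()].
#' * `demo_sequences()` returns four short nucleotide sequences
#'   (`x1`, `y1`, `x2`, `y2`) standing in for abbreviated gene sequences;
#'   `x1`, `y1` and `y2` contain the 3-gram `TCT` 2, 2 and 3 times
#'   respectively. (`x2` is carried for completeness but not used as a count
#'   fixture.)
#'
#' @return `demo_transducer()`: a [wfst]; `demo_sequences()`: a named
#'   character vector of 4 sequences.
#' @examples
#' wfst_value(demo_transducer(), "GGC", "CCG") # 48
#' ngram_count(demo_sequences()[["x1"]], "TCT") # 2
#' @export
demo_transducer <- function() {
  read_wfst(system.file("extdata", "demo_transducer.tsv", package = "prkern",
                        mustWork = TRUE))
}

#' @rdname demo_transducer
#' @export
demo_sequences <- function() {
  read_fasta(system.file("extdata", "demo_genes.fasta", package = "prkern",
                         mustWork = TRUE))
}
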