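#' Generate a random reference genome
#'
#' Draws an i.i.d. roughly uniform-composition nucleotide sequence for each
#' contig in the configuration. Deterministic for a fixed `config$seed`.
#'
#' @param config a [sim_config()].
#' @return Named character vector of upper-case sequences, one per contig.
#' @export
#' @examples
#' ref <- generate_reference(sim_config(c(chr1 = 1000L), seed = 7L))
#' nchar(ref[["chr1"]])
generate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  vapply(config$genome_spec, function(len) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

#' Write/read reference sequences as FASTA
#'
#' Thin wrappers over [Biostrings::writeXStringSet()] /
#' [Biostrings::readDNAStringSet()] keeping the package's plain named-character
#' sequence representation at the boundary.
#'
#' @param reference named character vector of sequences.
#' @param path FASTA file path.
#' @return `write_reference_fasta` returns `path` invisibly;
#'   `read_reference_fasta` a named character vector.
#' @export
write_reference_fasta <- function(reference, path) {
  xs <- Biostrings::DNAStringSet(reference)
  names(xs) <- names(reference)
  Biostrings::writeXStringSet(xs, path)
  invisible(path)
}

#' @rdname write_reference_fasta
#' @export
read_reference_fasta <- function(path) {
  xs <- Biostrings::readDNAStringSet(path)
  setNames(as.character(xs), sub("\\s.*$", "", names(xs)))
}
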