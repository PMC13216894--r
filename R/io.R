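#' Read and write genomes as FASTA
#'
#' Thin wrappers over Biostrings keeping the package's named-character genome
#' convention.
#'
#' @param path FASTA file.
#' @return `read_genome_fasta`: a [Biostrings::DNAStringSet].
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub(" .*$", "", names(x))
  x
}

#' @rdname read_genome_fasta
#' @param genome DNAStringSet or named character vector.
#' @return `write_genome_fasta`: invisibly, `path`.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(as_dnastringset(genome), path)
  invisible(path)
}
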