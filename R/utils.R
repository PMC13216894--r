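#' Reverse complement of DNA strings
#'
#' @param x character vector of sequences over `{A,C,G,T,N}` (case kept upper).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Format a count as a percentage at fixed precision
#'
#' Reporting helper used throughout run summaries: `fmt_percent(5176, 44726)`
#' renders as `11.6`.
#'
#' @param n numerator count.
#' @param total denominator count.
#' @param digits decimal places (default 1, the precision used in summaries).
#' @return numeric percentage rounded to `digits`.
#' @export
fmt_percent <- function(n, total, digits = 1) {
  stopifnot(total > 0)
  round(100 * n / total, digits)
}

# run `code` under a temporary RNG seed, restoring the caller's stream
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# accept DNAStringSet or named character; return named character
as_genome_chr <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    out <- as.character(genome)
    names(out) <- names(genome)
    genome <- out
  }
  if (!is.character(genome) || is.null(names(genome)) ||
      anyDuplicated(names(genome)) || any(!nzchar(genome)))
    stop("genome must be a DNAStringSet or named character vector with ",
         "unique identifiers and non-empty sequences")
  genome
}

as_dnastringset <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) return(genome)
  Biostrings::DNAStringSet(as_genome_chr(genome))
}

#' Shannon entropy of the trinucleotide composition of a read
#'
#' @param x character vector of sequences.
#' @return numeric vector of entropies in bits (0 for homopolymers).
#' @export
trinucleotide_entropy <- function(x) {
  vapply(x, function(s) {
    n <- nchar(s)
    if (n < 3) return(0)
    tri <- substring(s, seq_len(n - 2), seq_len(n - 2) + 2)
    p <- table(tri) / length(tri)
    -sum(p * log2(p))
  }, numeric(1), USE.NAMES = FALSE)
}

# simple deterministic checksum for run-report logging (content digest)
content_digest <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  sprintf("%d-%d", length(raw), sum(as.integer(raw)) %% 1000000007)
}

mean_phred <- function(qual) {
  vapply(qual, function(q) mean(utf8ToInt(q)) - 33, numeric(1),
         USE.NAMES = FALSE)
}
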