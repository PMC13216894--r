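#' Parameter presets for k-mer screening
#'
#' Two profiles: `"exploratory"` (k = 21, minimum count 3) for sensitive
#' counting, and `"stringent"` (k = 31, minimum count 20), which suppresses
#' sequencing error and individual polymorphism when isolating sex-enriched
#' sequence.
#'
#' @param profile `"exploratory"` or `"stringent"`.
#' @return list with `k` and `min_count`.
#' @export
kmer_preset <- function(profile = c("exploratory", "stringent")) {
  switch(match.arg(profile),
         exploratory = list(k = 21L, min_count = 3L),
         stringent = list(k = 31L, min_count = 20L))
}

#' Count canonical k-mers in a read set
#'
#' Strand-agnostic occurrence counts over the canonical form (lexicographic
#' minimum of a k-mer and its reverse complement); k-mers spanning N are
#' skipped and entries below `min_count` are dropped.  Output is sorted
#' lexicographically so tables diff cleanly.
#'
#' @param reads character vector of sequences, or a read table with
#'   `seq1`/`seq2` (both mates are counted).
#' @param k odd k-mer size, 15-31.
#' @param min_count occurrence floor (default 3).
#' @return object of class `kmer_table`: data.frame `kmer`, `count` with
#'   `k` and `min_count` attributes.
#' @export
count_kmers <- function(reads, k = 21, min_count = 3) {
  if (k %% 2 == 0 || k < 15 || k > 31)
    stop("k must be odd and between 15 and 31")
  seqs <- if (is.data.frame(reads)) c(reads$seq1, reads$seq2) else reads
  tab <- cpp_kmer_counts(seqs, as.integer(k), as.integer(min_count))
  structure(tab, k = as.integer(k), min_count = as.integer(min_count),
            class = c("kmer_table", "data.frame"))
}

#' Build a k-mer table from explicit k-mer/count pairs
#'
#' @param kmers,counts parallel vectors (k-mers are canonicalized).
#' @param min_count floor annotation.
#' @return a `kmer_table`.
#' @export
kmer_table <- function(kmers, counts, min_count = 1) {
  k <- unique(nchar(kmers))
  if (length(k) > 1) stop("all k-mers must share one length")
  if (length(k) == 0) k <- 0L
  rc <- revcomp(kmers)
  canon <- pmin(kmers, rc)
  df <- data.frame(kmer = canon, count = as.integer(counts),
                   stringsAsFactors = FALSE)
  df <- df[order(df$kmer), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, k = as.integer(k), min_count = as.integer(min_count),
            class = c("kmer_table", "data.frame"))
}

#' @export
print.kmer_table <- function(x, ...) {
  cat("kmer_table: k =", attr(x, "k"), ", min_count =", attr(x, "min_count"),
      ",", nrow(x), "k-mers\n")
  invisible(x)
}

check_same_k <- function(a, b) {
  if (!identical(attr(a, "k"), attr(b, "k")))
    stop("k-mer tables have mismatched k (", attr(a, "k"), " vs ",
         attr(b, "k"), ")")
}

#' Set subtraction between k-mer tables
#'
#' A-specific k-mers: keys of `table_a` absent from `table_b`, counts
#' preserved from `table_a`.
#'
#' @param table_a,table_b `kmer_table`s with the same k.
#' @return a `kmer_table` of A-specific entries.
#' @export
kmer_subtract <- function(table_a, table_b) {
  check_same_k(table_a, table_b)
  out <- table_a[!(table_a$kmer %in% table_b$kmer), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, k = attr(table_a, "k"),
            min_count = attr(table_a, "min_count"),
            class = c("kmer_table", "data.frame"))
}

#' Shared/specific partition of two k-mer tables
#'
#' @param table_a,table_b `kmer_table`s with the same k (conventionally
#'   female and male read sets, in that order).
#' @param labels names of the two sets for reporting.
#' @return object of class `sex_kmer_summary`: counts of A-specific,
#'   B-specific and shared k-mers, the shared fraction of the union, and the
#'   specific-count ratio (A-specific / B-specific).
#' @export
shared_stats <- function(table_a, table_b, labels = c("female", "male")) {
  check_same_k(table_a, table_b)
  shared <- sum(table_a$kmer %in% table_b$kmer)
  n_a <- nrow(table_a)
  n_b <- nrow(table_b)
  n_union <- n_a + n_b - shared
  out <- list(
    labels = labels, k = attr(table_a, "k"),
    min_count = c(attr(table_a, "min_count"), attr(table_b, "min_count")),
    n_a = n_a, n_b = n_b, n_shared = shared,
    n_a_specific = n_a - shared, n_b_specific = n_b - shared,
    shared_fraction = if (n_union > 0) shared / n_union else NA_real_,
    specific_ratio = if (n_b - shared > 0) (n_a - shared) / (n_b - shared)
      else NA_real_)
  class(out) <- "sex_kmer_summary"
  out
}

#' @export
print.sex_kmer_summary <- function(x, ...) {
  cat(sprintf(
    "sex_kmer_summary (k=%d): %s %d / %s %d; shared %d (%.1f%% of union); %s-specific %d vs %s-specific %d (ratio %.2f)\n",
    x$k, x$labels[1], x$n_a, x$labels[2], x$n_b, x$n_shared,
    100 * x$shared_fraction, x$labels[1], x$n_a_specific, x$labels[2],
    x$n_b_specific, x$specific_ratio))
  invisible(x)
}

#' Filter a k-mer table to a copy-number window
#'
#' Retains entries with occurrence counts in `[lo, hi]` inclusive; the
#' moderate-copy window (200-499 occurrences) isolates repeat-family signal
#' from single-copy background and high-copy satellites.
#'
#' @param table a `kmer_table`.
#' @param lo,hi inclusive occurrence bounds (defaults 200 and 499).
#' @return the filtered `kmer_table`.
#' @export
copy_window_filter <- function(table, lo = 200, hi = 499) {
  if (lo > hi) stop("lo must not exceed hi")
  out <- table[table$count >= lo & table$count <= hi, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, k = attr(table, "k"), min_count = attr(table, "min_count"),
            class = c("kmer_table", "data.frame"))
}

#' Cross-check the top-N specific k-mers against the other table
#'
#' Takes the `n` highest-count entries of a specific table (ties broken
#' lexicographically) and counts how many occur in the other table at all -
#' the confirmation step for sex-specific calls.
#'
#' @param specific_table a `kmer_table` (e.g. the female-specific set).
#' @param other_table the table to check against (e.g. the male table).
#' @param n how many top entries to check (default 5000; capped at the table
#'   size).
#' @return integer count of top-N entries present in `other_table`, with the
#'   checked subset as attribute `checked`.
#' @export
top_n_crosscheck <- function(specific_table, other_table, n = 5000) {
  stopifnot(n >= 1)
  ord <- order(-specific_table$count, specific_table$kmer)
  top <- specific_table[head(ord, n), , drop = FALSE]
  hits <- sum(top$kmer %in% other_table$kmer)
  attr(hits, "checked") <- nrow(top)
  hits
}

#' Write a k-mer table as sorted TSV
#'
#' @param table a `kmer_table`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_kmer_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
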