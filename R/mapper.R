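#' Build a seed index over a reference genome
#'
#' Indexes every ungapped w-mer of the reference (canonical form, so both
#' strands are retrievable) with all its occurrence positions.  w-mers
#' containing N are not indexed.
#'
#' @param genome DNAStringSet or named character vector.
#' @param w seed length (default 31; values down to 2 are accepted
#'   for toy references, 11+ recommended for real use).
#' @return an object of class `seed_index` (external pointer; rebuild rather
#'   than serialize).
#' @export
build_index <- function(genome, w = 31) {
  genome <- as_genome_chr(genome)
  ptr <- cpp_build_index(names(genome), unname(genome), as.integer(w))
  structure(list(ptr = ptr, w = as.integer(w)), class = "seed_index")
}

#' @export
print.seed_index <- function(x, ...) {
  cat("seed_index: w =", x$w, "over",
      length(cpp_index_contigs(x$ptr)), "contigs\n")
  invisible(x)
}

#' Look up a w-mer in a seed index
#'
#' @param index a [build_index()] result.
#' @param wmer query of length w; queries containing N return no hits.
#' @return data.frame with `contig` (name) and `pos` (1-based) of every
#'   occurrence of the w-mer or its reverse complement on the forward strand.
#' @export
index_lookup <- function(index, wmer) {
  hits <- cpp_index_lookup(index$ptr, wmer)
  data.frame(contig = cpp_index_contigs(index$ptr)[hits$contig],
             pos = hits$pos, stringsAsFactors = FALSE)
}

index_contig_lengths <- function(index) {
  setNames(cpp_index_contig_lengths(index$ptr), cpp_index_contigs(index$ptr))
}

#' Map paired-end reads with a minimal seed-and-extend mapper
#'
#' Every read offset is seeded in both orientations and every seeded placement
#' is extended ungapped over the full read; a placement is acceptable when its
#' mismatch count is at most `max_mismatches`.  The best placement (fewest
#' mismatches, ties broken by lowest (contig, position, strand)) is reported
#' with a three-level MAPQ: 60 when unique with a margin of at least 2
#' mismatches over the runner-up, 20 at margin 1, 0 when tied.  Reads with no
#' acceptable placement are emitted unmapped (MAPQ 0, no position).  Mate and
#' proper-pair flags are set when both mates map to the same contig in
#' forward/reverse orientation within `4 * insert_mean`.
#'
#' @param reads data.frame with `id`, `seq1`, `seq2` (see
#'   [simulate_readset()]), or a single-end data.frame with `id`, `seq`.
#' @param index a [build_index()] result over the reference.
#' @param max_mismatches maximum mismatches for an acceptable placement
#'   (default 5, about 3.3% divergence tolerance on 150-bp reads).
#' @param insert_mean expected insert size used for the proper-pair window.
#' @return a `covmark_aln` table (two rows per pair).
#' @export
map_reads <- function(reads, index, max_mismatches = 5, insert_mean = 500) {
  stopifnot(inherits(index, "seed_index"))
  contigs <- index_contig_lengths(index)
  contig_names <- names(contigs)
  paired <- !is.null(reads$seq1)
  if (!paired) {
    hit <- cpp_map_reads(index$ptr, reads$seq, as.integer(max_mismatches))
    df <- data.frame(
      qname = reads$id,
      flag = ifelse(hit$mapped, ifelse(hit$rev, FLAG_REVERSE, 0L),
                    FLAG_UNMAPPED),
      rname = ifelse(hit$mapped, contig_names[hit$contig], "*"),
      pos = ifelse(hit$mapped, hit$pos, 0L),
      mapq = hit$mapq,
      cigar = ifelse(hit$mapped, sprintf("%dM", nchar(reads$seq)), "*"),
      rnext = "*", pnext = 0L, tlen = 0L,
      seq = reads$seq, qual = strrep("I", nchar(reads$seq)),
      nm = ifelse(hit$mapped, hit$mismatches, NA_integer_),
      stringsAsFactors = FALSE)
    return(alignments(df, contigs))
  }

  h1 <- cpp_map_reads(index$ptr, reads$seq1, as.integer(max_mismatches))
  h2 <- cpp_map_reads(index$ptr, reads$seq2, as.integer(max_mismatches))
  same_contig <- h1$mapped & h2$mapped & h1$contig == h2$contig
  fr <- same_contig & (h1$rev != h2$rev)
  # FR orientation: the forward mate must start at or left of the reverse mate
  fwd_pos <- ifelse(fr, ifelse(h1$rev, h2$pos, h1$pos), NA_integer_)
  rev_pos <- ifelse(fr, ifelse(h1$rev, h1$pos, h2$pos), NA_integer_)
  span <- rev_pos - fwd_pos
  proper <- !is.na(span) & span >= 0 & span <= 4 * insert_mean
  proper[is.na(proper)] <- FALSE

  mate_row <- function(hit, other, first, rl) {
    flag <- rep(FLAG_PAIRED + if (first) FLAG_FIRST else FLAG_SECOND,
                length(hit$mapped))
    flag <- flag + ifelse(hit$mapped & hit$rev, FLAG_REVERSE, 0L) +
      ifelse(other$mapped & other$rev, FLAG_MATE_REVERSE, 0L) +
      ifelse(hit$mapped, 0L, FLAG_UNMAPPED) +
      ifelse(other$mapped, 0L, FLAG_MATE_UNMAPPED) +
      ifelse(proper, FLAG_PROPER, 0L)
    tlen <- ifelse(proper,
                   ifelse(hit$rev, -(span + rl), span + rl), 0L)
    data.frame(
      qname = reads$id, flag = as.integer(flag),
      rname = ifelse(hit$mapped, contig_names[hit$contig], "*"),
      pos = ifelse(hit$mapped, hit$pos, 0L),
      mapq = hit$mapq,
      cigar = ifelse(hit$mapped, sprintf("%dM", rl), "*"),
      rnext = ifelse(other$mapped, ifelse(same_contig, "=",
                                          contig_names[pmax(other$contig, 1L)]),
                     "*"),
      pnext = ifelse(other$mapped, other$pos, 0L),
      tlen = as.integer(tlen),
      seq = if (first) reads$seq1 else reads$seq2,
      qual = strrep("I", rl),
      nm = ifelse(hit$mapped, hit$mismatches, NA_integer_),
      stringsAsFactors = FALSE)
  }
  rl1 <- nchar(reads$seq1)
  rl2 <- nchar(reads$seq2)
  df <- rbind(mate_row(h1, h2, TRUE, rl1), mate_row(h2, h1, FALSE, rl2))
  df <- df[order(match(df$rname, c(contig_names, "*")), df$pos, df$qname), ]
  rownames(df) <- NULL
  alignments(df, contigs)
}
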