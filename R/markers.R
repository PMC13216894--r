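#' Screen for persistently low-coverage contigs
#'
#' Flags contigs whose pooled mean depth falls below `depth_max`
#' (equivalently, normalized depth below `norm_max`) and, when required,
#' whose per-sex normalized depths are also below `norm_max` - i.e.
#' underrepresentation reproducible in both individuals rather than
#' stochastic dropout.  A coverage-breadth ceiling excludes contigs that are
#' merely thinly but uniformly covered.
#'
#' @param pooled_stats [contig_stats()] of the pooled alignments.
#' @param per_sex_stats named list of per-sex [contig_stats()] tables
#'   (ignored when `require_both_sexes = FALSE`).
#' @param depth_max pooled mean-depth cutoff (default 30).
#' @param norm_max normalized-depth cutoff (default 0.4).
#' @param breadth_max breadth ceiling for flagging (default 0.9).
#' @param require_both_sexes demand sub-threshold normalized depth in every
#'   per-sex table (default TRUE).
#' @return the pooled stats rows that pass, with per-sex means and a
#'   `flagged` column on the full table as attribute `screen_table`.
#' @export
screen_low_coverage <- function(pooled_stats, per_sex_stats = NULL,
                                depth_max = 30, norm_max = 0.4,
                                breadth_max = 0.9,
                                require_both_sexes = TRUE) {
  tab <- as.data.frame(pooled_stats)
  low <- tab$mean_depth < depth_max & tab$breadth < breadth_max
  if (require_both_sexes && length(per_sex_stats) > 0) {
    for (sx in names(per_sex_stats)) {
      s <- per_sex_stats[[sx]]
      if (!identical(s$contig, tab$contig))
        stop("per-sex statistics must cover the same contigs as pooled")
      low <- low & s$normalized_depth < norm_max
      tab[[paste0(sx, "_mean")]] <- s$mean_depth
    }
  }
  tab$flagged <- low
  out <- tab[low, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "screen_table") <- tab
  out
}

#' Extract read pairs where both mates failed to map
#'
#' The conservative interpretation of "read pairs that failed to align":
#' only pairs with both mates unmapped are returned for assembly; pairs with
#' a single unmapped mate are counted but not extracted.
#'
#' @param aln a `covmark_aln` table of the paired mapping.
#' @param reads the read table that produced it.
#' @return read table subset (deterministic id order); the single-end dropout
#'   count is attached as attribute `single_end_dropouts`.
#' @export
extract_unmapped_pairs <- function(aln, reads) {
  unmapped <- has_flag(aln$flag, FLAG_UNMAPPED)
  per_id <- tapply(unmapped, aln$qname, sum)
  counts <- tapply(rep(1L, nrow(aln)), aln$qname, sum)
  orphan <- names(counts)[counts != 2L]
  if (length(orphan) > 0) {
    warning(length(orphan), " read id(s) without exactly two mates; skipped")
    per_id <- per_id[!names(per_id) %in% orphan]
  }
  both <- names(per_id)[per_id == 2L]
  out <- reads[reads$id %in% both, , drop = FALSE]
  out <- out[order(out$id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "single_end_dropouts") <- sum(per_id == 1L)
  out
}

#' Quality and complexity filter for reads
#'
#' Keeps reads whose mean Phred quality is at least `min_mean_q` and whose
#' trinucleotide Shannon entropy is at least `entropy_min` bits, removing
#' low-quality and low-complexity sequence before assembly.
#'
#' @param seqs character vector of read sequences.
#' @param quals optional quality strings (Phred+33); when NULL the quality
#'   criterion is skipped.
#' @param min_mean_q mean-quality floor (default 20).
#' @param entropy_min trinucleotide entropy floor in bits (default 2).
#' @return the surviving sequences.
#' @export
filter_reads <- function(seqs, quals = NULL, min_mean_q = 20,
                         entropy_min = 2) {
  keep <- trinucleotide_entropy(seqs) >= entropy_min
  if (!is.null(quals)) keep <- keep & mean_phred(quals) >= min_mean_q
  seqs[keep]
}

#' Assemble unmapped reads into contigs
#'
#' De Bruijn graph over canonical k-mers with an occurrence cutoff
#' (`min_kmer_count`, default 2, suppressing error k-mers); maximal
#' non-branching paths are emitted as contigs, those shorter than
#' `min_contig` are discarded, and output order is deterministic
#' (length descending, then sequence).
#'
#' @param seqs character vector of reads (both mates, already filtered).
#' @param k_asm odd assembly k-mer size below the read length (default 31).
#' @param min_contig minimum contig length to retain (default 300).
#' @param min_kmer_count k-mer coverage cutoff (default 2).
#' @return named character vector of contigs (`unmapped_contig_1`, ...).
#' @export
assemble_unmapped <- function(seqs, k_asm = 31, min_contig = 300,
                              min_kmer_count = 2) {
  if (k_asm %% 2 == 0) stop("k_asm must be odd")
  if (length(seqs) == 0) return(setNames(character(0), character(0)))
  if (k_asm >= min(nchar(seqs))) stop("k_asm must be below the read length")
  contigs <- cpp_assemble(seqs, as.integer(k_asm), as.integer(min_kmer_count))
  contigs <- contigs[nchar(contigs) >= min_contig]
  contigs <- contigs[order(-nchar(contigs), contigs)]
  setNames(contigs, if (length(contigs) > 0)
    paste0("unmapped_contig_", seq_along(contigs)) else character(0))
}

#' Reciprocally validate assembled contigs
#'
#' A contig is retained when (a) it is effectively absent from the
#' cross-species reference - at most `window_map_cap` of its tiled windows
#' map under permissive mismatch settings - and (b) it is well supported by
#' its own species' reads, i.e. back-mapped source-read mean depth reaches
#' `min_source_depth`.
#'
#' @param contigs named character vector from [assemble_unmapped()].
#' @param reference_index [build_index()] of the cross-species reference.
#' @param source_reads character vector of the reads that went into assembly.
#' @param permissive_max_mismatch mismatch allowance per window (default 10).
#' @param window window size in bp (default 150, tiled end to end plus a
#'   final flush window).
#' @param window_map_cap maximum tolerated fraction of mapping windows
#'   (default 0.1).
#' @param min_source_depth back-mapped mean depth floor (default 5).
#' @param map_max_mismatch mismatch allowance for back-mapping (default 5).
#' @return retained contigs; the full per-contig report is attribute
#'   `report`.
#' @export
reciprocal_validate <- function(contigs, reference_index, source_reads,
                                permissive_max_mismatch = 10, window = 150,
                                window_map_cap = 0.1, min_source_depth = 5,
                                map_max_mismatch = 5) {
  if (length(contigs) == 0) {
    out <- contigs
    attr(out, "report") <- data.frame(contig = character(0))
    return(out)
  }
  frac_mapped <- vapply(contigs, function(s) {
    n <- nchar(s)
    starts <- unique(c(seq(1L, max(n - window + 1L, 1L), by = window),
                       max(n - window + 1L, 1L)))
    # contigs assembled from both-unmapped pairs carry up to a read length of
    # flanking homology at each end (junction-spanning reads stay unmapped),
    # so specificity is judged on interior windows when there are enough
    if (length(starts) >= 3) starts <- starts[-c(1L, length(starts))]
    wins <- substring(s, starts, pmin(starts + window - 1L, n))
    wins <- wins[nchar(wins) >= min(window, n)]
    hits <- cpp_map_reads(reference_index$ptr, wins,
                          as.integer(permissive_max_mismatch))
    mean(hits$mapped)
  }, numeric(1))

  back_index <- build_index(contigs, w = min(31, min(nchar(contigs))))
  back <- map_reads(data.frame(id = paste0("src_", seq_along(source_reads)),
                               seq = source_reads,
                               stringsAsFactors = FALSE), back_index,
                    max_mismatches = map_max_mismatch)
  back_depth <- contig_stats(compute_depth(back))
  depth_by_contig <- setNames(back_depth$mean_depth, back_depth$contig)

  report <- data.frame(
    contig = names(contigs), length = nchar(contigs),
    window_map_fraction = unname(frac_mapped),
    source_mean_depth = unname(depth_by_contig[names(contigs)]),
    stringsAsFactors = FALSE)
  report$retained <- report$window_map_fraction <= window_map_cap &
    report$source_mean_depth >= min_source_depth
  out <- contigs[report$retained]
  attr(out, "report") <- report
  out
}

#' Validate and normalize a primer pair
#'
#' @param forward,reverse 5'->3' primer sequences over `{A,C,G,T}`,
#'   15-35 bp.
#' @param max_mismatches tolerated mismatches per binding site (3' terminal
#'   base must always match exactly).
#' @param product_range allowed amplicon length window in bp.
#' @return object of class `primer_pair`.
#' @export
primer_pair <- function(forward, reverse, max_mismatches = 2,
                        product_range = c(50, 2000)) {
  for (p in c(forward, reverse)) {
    if (!grepl("^[ACGT]+$", p)) stop("primers must be over {A,C,G,T}")
    if (nchar(p) < 15 || nchar(p) > 35)
      stop("primer length must be 15-35 bp, got ", nchar(p))
  }
  structure(list(forward = forward, reverse = reverse,
                 max_mismatches = as.integer(max_mismatches),
                 product_range = as.integer(product_range)),
            class = "primer_pair")
}

# all binding sites of one primer on one subject strand (Biostrings scan);
# returns plus-strand start/end (1-based inclusive) of each site
primer_sites <- function(primer, subject, max_mm) {
  plus <- Biostrings::matchPattern(primer, subject, max.mismatch = max_mm)
  minus <- Biostrings::matchPattern(revcomp(primer), subject,
                                    max.mismatch = max_mm)
  subj <- as.character(subject)
  n <- nchar(subj)
  base_at <- function(pos) {
    out <- rep(NA_character_, length(pos))
    ok <- pos >= 1 & pos <= n
    if (any(ok)) out[ok] <- substring(subj, pos[ok], pos[ok])
    out
  }
  ps <- BiocGenerics::start(plus); pe <- BiocGenerics::end(plus)
  ms <- BiocGenerics::start(minus); me <- BiocGenerics::end(minus)
  # 3'-terminal base must match exactly: last primer base on the plus strand,
  # first position of the reverse-complement match on the minus strand;
  # edge-overhanging matches are discarded
  pk <- ps >= 1 & pe <= n &
    base_at(pe) == substring(primer, nchar(primer), nchar(primer))
  mk <- ms >= 1 & me <= n & base_at(ms) == substring(revcomp(primer), 1, 1)
  pk[is.na(pk)] <- FALSE
  mk[is.na(mk)] <- FALSE
  rbind(
    data.frame(start = ps[pk], end = pe[pk], strand = rep("+", sum(pk)),
               stringsAsFactors = FALSE),
    data.frame(start = ms[mk], end = me[mk], strand = rep("-", sum(mk)),
               stringsAsFactors = FALSE))
}

#' In-silico PCR amplicon prediction
#'
#' Scans both strands of every contig for binding sites of either primer with
#' at most `max_mismatches` mismatches (3' terminal base exact) and reports
#' every convergent site pair whose product length falls inside the window.
#' Product length is (reverse-site 3' end) - (forward-site 5' start) + 1 in
#' 1-based inclusive coordinates.
#'
#' @param primers a [primer_pair()].
#' @param genome DNAStringSet or named character vector.
#' @return data.frame of predicted amplicons: contig, primer roles, site
#'   coordinates and `product_length`.
#' @export
insilico_pcr <- function(primers, genome) {
  stopifnot(inherits(primers, "primer_pair"))
  genome <- as_genome_chr(genome)
  out <- list()
  for (ctg in names(genome)) {
    subject <- Biostrings::DNAString(genome[[ctg]])
    site_block <- function(primer, role) {
      s <- primer_sites(primer, subject, primers$max_mismatches)
      s$primer <- rep(role, nrow(s))
      s
    }
    sites <- rbind(site_block(primers$forward, "forward"),
                   site_block(primers$reverse, "reverse"))
    plus <- sites[sites$strand == "+", , drop = FALSE]
    minus <- sites[sites$strand == "-", , drop = FALSE]
    if (nrow(plus) == 0 || nrow(minus) == 0) next
    grid <- expand.grid(i = seq_len(nrow(plus)), j = seq_len(nrow(minus)))
    len <- minus$end[grid$j] - plus$start[grid$i] + 1L
    ok <- len >= primers$product_range[1] & len <= primers$product_range[2] &
      minus$start[grid$j] > plus$start[grid$i]
    if (!any(ok)) next
    out[[ctg]] <- data.frame(
      contig = ctg,
      forward_primer = plus$primer[grid$i[ok]],
      reverse_primer = minus$primer[grid$j[ok]],
      forward_start = plus$start[grid$i[ok]],
      reverse_end = minus$end[grid$j[ok]],
      product_length = len[ok], stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(contig = character(0), forward_primer = character(0),
                      reverse_primer = character(0),
                      forward_start = integer(0), reverse_end = integer(0),
                      product_length = integer(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$contig, res$forward_start, res$reverse_end), , drop = FALSE]
}
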