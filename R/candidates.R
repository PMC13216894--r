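#' Assemble the candidate table from the discovery stages
#'
#' Merges the three evidence streams into one table of candidate diagnostic
#' regions: persistently low-coverage contigs, zero-coverage intervals, and
#' reciprocally validated contigs assembled from unmapped reads.
#'
#' @param low_coverage output of [screen_low_coverage()] (may be NULL).
#' @param zero_iv output of [zero_intervals()] on the pooled profile
#'   (may be NULL).
#' @param unmapped_contigs retained contigs from [reciprocal_validate()]
#'   (may be NULL).
#' @return data.frame with `source`, `contig`, `start`, `end`, `length` and
#'   `sequence` (unmapped contigs only).
#' @export
candidate_regions <- function(low_coverage = NULL, zero_iv = NULL,
                              unmapped_contigs = NULL) {
  rows <- list()
  if (!is.null(low_coverage) && nrow(low_coverage) > 0)
    rows$low <- data.frame(source = "low_coverage_contig",
                           contig = low_coverage$contig, start = 0L,
                           end = low_coverage$length,
                           length = low_coverage$length,
                           sequence = NA_character_, stringsAsFactors = FALSE)
  if (!is.null(zero_iv) && nrow(zero_iv) > 0)
    rows$zero <- data.frame(source = "zero_interval", contig = zero_iv$contig,
                            start = zero_iv$start, end = zero_iv$end,
                            length = zero_iv$length,
                            sequence = NA_character_, stringsAsFactors = FALSE)
  if (!is.null(unmapped_contigs) && length(unmapped_contigs) > 0)
    rows$unmapped <- data.frame(source = "unmapped_contig",
                                contig = names(unmapped_contigs), start = 0L,
                                end = nchar(unmapped_contigs),
                                length = nchar(unmapped_contigs),
                                sequence = unname(unmapped_contigs),
                                stringsAsFactors = FALSE)
  if (length(rows) == 0)
    return(data.frame(source = character(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      length = integer(0), sequence = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, unname(rows))
  rownames(out) <- NULL
  out
}

# reciprocal interval overlap >= `frac` between candidate intervals and truth
# intervals on the same coordinate system (both 0-based half-open)
reciprocal_interval_hits <- function(cand, truth, frac = 0.5) {
  if (nrow(cand) == 0 || nrow(truth) == 0)
    return(list(truth_hit = logical(nrow(truth)),
                cand_hit = logical(nrow(cand))))
  ci <- IRanges::IRanges(start = cand$start + 1L, end = cand$end)
  ti <- IRanges::IRanges(start = truth$start + 1L, end = truth$end)
  ov <- IRanges::findOverlaps(ci, ti)
  qh <- S4Vectors::queryHits(ov)
  sh <- S4Vectors::subjectHits(ov)
  same <- cand$contig[qh] == truth$contig[sh]
  inter <- IRanges::width(IRanges::pintersect(ci[qh], ti[sh]))
  good <- same & inter >= frac * IRanges::width(ci[qh]) &
    inter >= frac * IRanges::width(ti[sh])
  list(truth_hit = seq_len(nrow(truth)) %in% sh[good],
       cand_hit = seq_len(nrow(cand)) %in% qh[good])
}

# one-sided fraction of each candidate interval covered by any truth interval
candidate_covered_fraction <- function(cand, truth) {
  if (nrow(cand) == 0) return(numeric(0))
  if (nrow(truth) == 0) return(rep(0, nrow(cand)))
  vapply(seq_len(nrow(cand)), function(i) {
    t <- truth[truth$contig == cand$contig[i], , drop = FALSE]
    if (nrow(t) == 0) return(0)
    ov <- pmax(0, pmin(cand$end[i], t$end) - pmax(cand$start[i], t$start))
    max(ov) / (cand$end[i] - cand$start[i])
  }, numeric(1))
}

# k-mer sets of the planted features: `core` is the feature sequence itself,
# `hood` its neighborhood in genome A (feature plus breakpoint flanks), the
# sequence context an unmapped-read contig legitimately extends into
truth_feature_kmers <- function(truth, genome_a = NULL, k = 31, margin = 300) {
  feats <- list()
  add <- function(core_seq, contig, s, e) {
    hood_seq <- core_seq
    if (!is.null(genome_a) && !is.na(contig)) {
      ga <- as_genome_chr(genome_a)
      if (contig %in% names(ga))
        hood_seq <- substr(ga[[contig]], max(1, s + 1 - margin), e + margin)
    }
    list(core = cpp_distinct_kmers(core_seq, k),
         hood = cpp_distinct_kmers(hood_seq, k))
  }
  isl <- truth$divergent_islands
  if (!is.null(isl$sequence_a))
    for (j in seq_len(nrow(isl)))
      feats[[length(feats) + 1L]] <- add(isl$sequence_a[j], isl$contig[j],
                                         isl$start_a[j], isl$end_a[j])
  else
    for (j in seq_len(nrow(isl)))
      feats[[length(feats) + 1L]] <- list(core = character(0),
                                          hood = character(0))
  ins <- truth$insertions
  for (j in seq_len(nrow(ins)))
    feats[[length(feats) + 1L]] <- add(ins$sequence[j], ins$contig[j],
                                       ins$start[j], ins$end[j])
  feats
}

#' Rank candidate regions and score recovery against planted truth
#'
#' Scores each candidate by length, cross-sex reproducibility and
#' cross-species absence.  When a truth set is supplied, recovery is also
#' reported: sensitivity is the fraction of planted features recovered by at
#' least one candidate at >= `overlap_frac` reciprocal overlap (interval
#' candidates against island intervals) or reciprocal k-mer containment
#' (sequence candidates against the feature sequence, with breakpoint-flank
#' neighborhoods when `genome_a` is given); the false-discovery proportion
#' counts candidates of which less than `overlap_frac` lies inside any
#' planted feature.
#'
#' @param candidates [candidate_regions()] table.
#' @param truth optional `truth_set` from [generate_genome_pair()].
#' @param genome_a the query genome, used to extend planted-feature sequences
#'   by `margin` bp of breakpoint flank for sequence matching.
#' @param both_sexes logical vector (recycled) marking candidates
#'   reproducible in both sexes.
#' @param cross_absent logical vector (recycled) marking candidates with
#'   confirmed cross-species absence (zero intervals and validated unmapped
#'   contigs carry this evidence by construction).
#' @param overlap_frac overlap / containment fraction (default 0.5).
#' @param margin breakpoint-flank margin in bp (default 300).
#' @return candidates with a `score` column, ranked; recovery metrics (when
#'   truth is given) in attribute `recovery`.
#' @export
prioritize_candidates <- function(candidates, truth = NULL, genome_a = NULL,
                                  both_sexes = TRUE, cross_absent = NULL,
                                  overlap_frac = 0.5, margin = 300) {
  n <- nrow(candidates)
  if (is.null(cross_absent))
    cross_absent <- candidates$source %in% c("zero_interval",
                                             "unmapped_contig")
  both_sexes <- rep_len(both_sexes, n)
  cross_absent <- rep_len(cross_absent, n)
  score <- log10(pmax(candidates$length, 1)) + 1 * both_sexes +
    2 * cross_absent
  out <- candidates
  out$score <- score
  ord <- order(-score, candidates$contig, candidates$start)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL

  if (!is.null(truth)) {
    is_seq <- candidates$source == "unmapped_contig"
    interval_cand <- candidates[!is_seq, , drop = FALSE]
    seq_cand <- candidates[is_seq, , drop = FALSE]
    isl_tab <- truth$divergent_islands
    ins_tab <- truth$insertions
    n_isl <- nrow(isl_tab)
    n_ins <- nrow(ins_tab)

    # interval route (islands live on reference coordinates)
    isl <- reciprocal_interval_hits(interval_cand, isl_tab, overlap_frac)
    interval_tp <- candidate_covered_fraction(interval_cand, isl_tab) >=
      overlap_frac

    # sequence route (k-mer containment against island/insertion sequences)
    feats <- truth_feature_kmers(truth, genome_a, margin = margin)
    feat_hit <- logical(length(feats))
    seq_tp <- logical(nrow(seq_cand))
    for (i in seq_len(nrow(seq_cand))) {
      ck <- cpp_distinct_kmers(seq_cand$sequence[i], 31L)
      if (length(ck) == 0) next
      for (f in seq_along(feats)) {
        hood <- feats[[f]]$hood
        core <- feats[[f]]$core
        if (length(hood) == 0) next
        in_hood <- mean(ck %in% hood)
        if (in_hood >= overlap_frac) seq_tp[i] <- TRUE
        if (in_hood >= overlap_frac && length(core) > 0 &&
            mean(core %in% ck) >= overlap_frac)
          feat_hit[f] <- TRUE
      }
    }
    island_hit <- isl$truth_hit | feat_hit[seq_len(n_isl)]
    insertion_hit <- if (n_ins > 0) feat_hit[n_isl + seq_len(n_ins)] else
      logical(0)
    n_truth <- n_isl + n_ins
    n_hit <- sum(island_hit) + sum(insertion_hit)
    cand_tp <- c(isl$cand_hit | interval_tp, seq_tp)
    recovery <- list(
      sensitivity = if (n_truth == 0) NA_real_ else n_hit / n_truth,
      fdr = if (n == 0) 0 else 1 - sum(cand_tp) / n,
      n_truth = n_truth, n_candidates = n,
      n_truth_recovered = n_hit,
      islands_recovered = sum(island_hit),
      insertions_recovered = sum(insertion_hit))
    attr(out, "recovery") <- recovery
  }
  out
}
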