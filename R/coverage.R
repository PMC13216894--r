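#' Per-base depth profiles from alignments
#'
#' Each mapped record with MAPQ at or above `mapq_min` adds 1 to every
#' reference position covered by its CIGAR M (or `=`/`X`) operations; unmapped
#' records and records below the threshold contribute nothing.
#'
#' @param aln a `covmark_aln` table (internal mapper output or [read_sam()]).
#' @param genome optional genome; defaults to the alignment header contigs.
#'   Alignment contigs must be a subset of genome contigs.
#' @param mapq_min minimum MAPQ (default 0 counts everything mapped).
#' @return object of class `depth_profiles`: named list of integer depth
#'   vectors, one per contig, with the threshold recorded.
#' @export
compute_depth <- function(aln, genome = NULL, mapq_min = 0) {
  contigs <- if (is.null(genome)) aln_contigs(aln) else {
    g <- as_genome_chr(genome)
    missing_ctg <- setdiff(names(aln_contigs(aln)), names(g))
    if (length(missing_ctg) > 0)
      stop("alignment contigs not in genome: ",
           paste(missing_ctg, collapse = ", "))
    setNames(nchar(g), names(g))
  }
  mapped <- !has_flag(aln$flag, FLAG_UNMAPPED)
  rname_idx <- ifelse(mapped, match(aln$rname, names(contigs)), NA_integer_)
  unknown <- mapped & is.na(rname_idx)
  if (any(unknown))
    stop("alignment record ", which(unknown)[1], " (",
         aln$qname[which(unknown)[1]], ") references unknown contig")
  prof <- cpp_depth(unname(contigs), rname_idx, aln$pos, aln$cigar, aln$mapq,
                    as.integer(mapq_min))
  names(prof) <- names(contigs)
  structure(prof, mapq_min = as.integer(mapq_min), class = "depth_profiles")
}

#' Build depth profiles directly from vectors (testing / external data)
#'
#' @param profiles named list of non-negative integer vectors.
#' @param mapq_min threshold annotation carried on the object.
#' @return a `depth_profiles` object.
#' @export
depth_profiles <- function(profiles, mapq_min = 0) {
  stopifnot(is.list(profiles), !is.null(names(profiles)))
  if (any(vapply(profiles, function(p) any(p < 0), logical(1))))
    stop("depths must be non-negative")
  structure(lapply(profiles, as.integer), mapq_min = as.integer(mapq_min),
            class = "depth_profiles")
}

#' @export
print.depth_profiles <- function(x, ...) {
  cat("depth_profiles:", length(x), "contigs, mapq_min =",
      attr(x, "mapq_min"), "\n")
  invisible(x)
}

#' Pool depth profiles positionwise
#'
#' Pooling read sets (e.g. male + female) mitigates stochastic depth
#' variation; the pooled profile is the positionwise sum.
#'
#' @param profiles list of `depth_profiles` over identical contigs and MAPQ
#'   thresholds.
#' @return a pooled `depth_profiles` object.
#' @export
pool_profiles <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  ref <- profiles[[1]]
  for (p in profiles[-1]) {
    if (!identical(names(p), names(ref)) ||
        !identical(lengths(p), lengths(ref)))
      stop("profiles to pool must cover identical contigs")
    if (!identical(attr(p, "mapq_min"), attr(ref, "mapq_min")))
      stop("profiles to pool must share the same MAPQ threshold")
  }
  pooled <- ref
  for (p in profiles[-1])
    for (ctg in names(pooled)) pooled[[ctg]] <- pooled[[ctg]] + p[[ctg]]
  structure(pooled, mapq_min = attr(ref, "mapq_min"),
            class = "depth_profiles")
}

#' Per-contig coverage statistics
#'
#' Mean depth, coverage breadth (fraction of positions with depth >= 1) and
#' depth normalized by the genome-wide length-weighted mean.
#'
#' @param profiles a `depth_profiles` object.
#' @return data.frame (class `contig_coverage`) with columns `contig`,
#'   `length`, `mean_depth`, `breadth`, `normalized_depth`; the genome-wide
#'   weighted mean is attached as attribute `weighted_mean`.
#' @export
contig_stats <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  len <- lengths(profiles)
  if (any(len == 0)) stop("zero-length contig in profiles")
  total <- vapply(profiles, function(p) sum(as.numeric(p)), numeric(1))
  covered <- vapply(profiles, function(p) sum(p >= 1L), numeric(1))
  weighted_mean <- sum(total) / sum(len)
  df <- data.frame(contig = names(profiles), length = as.integer(len),
                   mean_depth = total / len, breadth = covered / len,
                   normalized_depth = if (weighted_mean > 0)
                     (total / len) / weighted_mean else 0,
                   stringsAsFactors = FALSE, row.names = NULL)
  attr(df, "weighted_mean") <- weighted_mean
  class(df) <- c("contig_coverage", "data.frame")
  df
}

#' Extract zero-coverage intervals
#'
#' Maximal runs of consecutive positions with depth 0, retained when at least
#' `min_len` bp long.  Output uses BED semantics (0-based half-open), sorted
#' and disjoint within each contig.
#'
#' @param profiles a `depth_profiles` object (or a single integer vector).
#' @param min_len minimum interval length in bp (default 100 for the primary
#'   extraction; 500 for the restricted sweep).
#' @param contigs optional subset of contig names to scan.
#' @param merge_gap merge zero runs separated by at most this many covered
#'   bases before applying the length filter (default 0: strict maximal-run
#'   semantics).  A small gap bridges isolated stray read placements inside
#'   an otherwise uncovered region.
#' @return data.frame with `contig`, `start`, `end`, `length`
#'   (`length = end - start`, so merged intervals include bridged bases).
#' @export
zero_intervals <- function(profiles, min_len = 100, contigs = NULL,
                           merge_gap = 0) {
  stopifnot(min_len >= 1, merge_gap >= 0)
  if (!is.list(profiles)) profiles <- list(contig = profiles)
  if (!is.null(contigs)) profiles <- profiles[names(profiles) %in% contigs]
  out <- lapply(names(profiles), function(ctg) {
    r <- rle(profiles[[ctg]] == 0L)
    ends <- cumsum(r$lengths)
    zero <- r$values
    start <- (ends - r$lengths)[zero]
    end <- ends[zero]
    if (merge_gap > 0 && length(start) > 1) {
      merged_s <- start[1]; ms <- integer(0); me <- integer(0)
      cur_e <- end[1]
      for (i in seq_along(start)[-1]) {
        if (start[i] - cur_e <= merge_gap) {
          cur_e <- end[i]
        } else {
          ms <- c(ms, merged_s); me <- c(me, cur_e)
          merged_s <- start[i]; cur_e <- end[i]
        }
      }
      start <- c(ms, merged_s); end <- c(me, cur_e)
    }
    keep <- (end - start) >= min_len
    if (!any(keep)) return(NULL)
    data.frame(contig = ctg, start = start[keep], end = end[keep],
               length = (end - start)[keep], stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0)
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$contig, res$start), , drop = FALSE]
}

#' Write zero-coverage intervals as BED
#'
#' @param intervals output of [zero_intervals()].
#' @param path BED output path.
#' @return invisibly, `path`.
#' @export
write_zero_bed <- function(intervals, path) {
  write.table(intervals[, c("contig", "start", "end")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' MAPQ robustness sweep of zero-coverage statistics
#'
#' Re-evaluates coverage at several MAPQ thresholds and interval-length
#' restrictions for each read set, the robustness analysis behind the
#' zero-coverage estimates.
#'
#' @param aln_list named list of `covmark_aln` tables (e.g. male/female).
#' @param genome reference genome.
#' @param thresholds ascending MAPQ thresholds (default `c(10, 20, 30)`).
#' @param restrict_min_len interval length floors to report (default
#'   `c(1, 500)`).
#' @return data.frame with one row per (set, threshold, restriction):
#'   total zero-coverage bp, percent of reference length, interval count and
#'   weighted mean depth.
#' @export
mapq_sweep <- function(aln_list, genome, thresholds = c(10, 20, 30),
                       restrict_min_len = c(1, 500)) {
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be ascending")
  genome_len <- sum(nchar(as_genome_chr(genome)))
  rows <- list()
  for (set in names(aln_list)) {
    for (thr in thresholds) {
      prof <- compute_depth(aln_list[[set]], genome, mapq_min = thr)
      wm <- attr(contig_stats(prof), "weighted_mean")
      for (ml in restrict_min_len) {
        zi <- zero_intervals(prof, min_len = ml)
        rows[[length(rows) + 1L]] <- data.frame(
          set = set, mapq_min = thr, min_len = ml,
          zero_bp = sum(zi$length),
          zero_pct = 100 * sum(zi$length) / genome_len,
          n_intervals = nrow(zi), weighted_mean_depth = wm,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Male-to-female depth-ratio screen
#'
#' Pseudocount-stabilized scaffold-level depth ratios
#' `(male + eps) / (female + eps)`, with candidate flagging restricted to
#' scaffolds at least `min_scaffold_len` long to suppress short-contig noise.
#'
#' @param stats_m,stats_f [contig_stats()] tables for the male and female read
#'   sets over the same scaffolds.
#' @param pseudocount depth pseudocount eps > 0 (default 0.5).
#' @param min_scaffold_len flagging length floor in bp (default 50000).
#' @param hi,lo ratio cutoffs for male-/female-biased flags (defaults 2, 0.5).
#' @return data.frame with per-scaffold means, ratio and `bias` flag
#'   (`"male"`, `"female"` or `"none"`; sub-length scaffolds are never
#'   flagged).
#' @export
sex_depth_ratio <- function(stats_m, stats_f, pseudocount = 0.5,
                            min_scaffold_len = 50000, hi = 2, lo = 0.5) {
  if (pseudocount <= 0) stop("pseudocount must be positive")
  if (!identical(stats_m$contig, stats_f$contig))
    stop("male and female statistics must cover the same scaffolds")
  ratio <- (stats_m$mean_depth + pseudocount) /
    (stats_f$mean_depth + pseudocount)
  long_enough <- stats_m$length >= min_scaffold_len
  bias <- ifelse(long_enough & ratio >= hi, "male",
                 ifelse(long_enough & ratio <= lo, "female", "none"))
  data.frame(contig = stats_m$contig, length = stats_m$length,
             male_mean = stats_m$mean_depth, female_mean = stats_f$mean_depth,
             ratio = ratio, bias = bias, stringsAsFactors = FALSE)
}
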