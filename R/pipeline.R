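#' Configuration for a full pipeline run
#'
#' One place for every stage's parameters, all defaulting to the analysis'
#' anchor values: mapper seed 31 with 5 mismatches, pooled depth cutoff 30x
#' (normalized 0.4), MAPQ sweep at 10/20/30 with the 500-bp restricted view,
#' 300-bp assembled-contig floor, k = 21 k-mer and sketch size 500000,
#' moderate-copy window 200-499, and the 50-kb scaffold floor for the sex
#' depth-ratio screen.
#'
#' @param sim a [sim_config()] describing the synthetic inputs.
#' @param mapper_w,max_mismatches seed length and mismatch allowance.
#' @param mapq_min primary MAPQ threshold for depth (default 0).
#' @param mapq_thresholds sweep thresholds.
#' @param depth_max,norm_max,breadth_max low-coverage screen cutoffs.
#' @param zero_min_len primary zero-interval length floor (bp).
#' @param zero_merge_gap candidate-level merge distance for zero intervals
#'   (bp); stray single-read placements inside an otherwise uncovered region
#'   are bridged before candidacy.
#' @param restrict_min_len sweep length restrictions (bp).
#' @param min_contig assembled-contig length floor (bp).
#' @param asm_min_kmer_count assembler k-mer coverage cutoff.  The default 5
#'   sits above the background left by chance-unmapped flanking mates (about
#'   3% of pooled depth) and far below planted-feature coverage, so contigs
#'   stop at insertion breakpoints instead of straggling into conserved
#'   flank.
#' @param kmer k-mer preset list (see [kmer_preset()]).
#' @param sketch_k,sketch_s,sketch_seed sketching parameters.
#' @param ratio_pseudocount,ratio_min_len sex depth-ratio parameters.
#' @param seed global seed overriding `sim$rng_seed` when non-NULL.
#' @return list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(),
                       mapper_w = 31, max_mismatches = 5,
                       mapq_min = 0, mapq_thresholds = c(10, 20, 30),
                       depth_max = 30, norm_max = 0.4, breadth_max = 0.9,
                       zero_min_len = 100, zero_merge_gap = 200,
                       restrict_min_len = c(1, 500),
                       min_contig = 300, asm_min_kmer_count = 5,
                       kmer = kmer_preset("exploratory"),
                       sketch_k = 21, sketch_s = 500000, sketch_seed = 42,
                       ratio_pseudocount = 0.5, ratio_min_len = 50000,
                       seed = NULL) {
  if (!is.null(seed)) sim$rng_seed <- as.integer(seed)
  cfg <- list(sim = sim, mapper_w = mapper_w,
              max_mismatches = max_mismatches, mapq_min = mapq_min,
              mapq_thresholds = mapq_thresholds, depth_max = depth_max,
              norm_max = norm_max, breadth_max = breadth_max,
              zero_min_len = zero_min_len, zero_merge_gap = zero_merge_gap,
              restrict_min_len = restrict_min_len, min_contig = min_contig,
              asm_min_kmer_count = asm_min_kmer_count,
              kmer = kmer, sketch_k = sketch_k, sketch_s = sketch_s,
              sketch_seed = sketch_seed,
              ratio_pseudocount = ratio_pseudocount,
              ratio_min_len = ratio_min_len)
  stopifnot(all(unlist(cfg[c("depth_max", "norm_max", "zero_min_len",
                             "min_contig", "sketch_k", "sketch_s")]) > 0))
  class(cfg) <- "run_config"
  cfg
}

pipeline_stage <- function(report, name, expr, verbose) {
  if (verbose) message("[covmark] stage: ", name)
  value <- tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
  report$stages[[name]] <- list(digest = content_digest(value))
  list(report = report, value = value)
}

#' Run the full discovery pipeline on synthetic data
#'
#' simulate -> map -> coverage -> candidate discovery -> sex k-mers ->
#' sketch/ordination, with a machine-readable report: per-sex and pooled
#' low-depth contig counts and percentages, zero-coverage statistics per MAPQ
#' threshold and length restriction, the ranked candidate list, the sex
#' k-mer summary, Mash distance/similarity matrices, PCoA coordinates and
#' (truth being available by construction) planted-feature recovery metrics.
#' Reported percentages are rounded to 1 decimal, depths to 2, distances to
#' 5; every rounded value is also present unrounded.
#'
#' @param config a [run_config()].
#' @param out_dir optional directory for TSV/JSON artifacts.
#' @param verbose log stage progression (default FALSE).
#' @param skip stages to omit, any of `"sweep"`, `"kmer"`, `"sketch"` (e.g.
#'   for replicated recovery studies that only need the discovery chain).
#' @return list of class `run_report`.
#' @export
run_pipeline <- function(config, out_dir = NULL, verbose = FALSE,
                         skip = character(0)) {
  stopifnot(inherits(config, "run_config"))
  report <- list(config = unclass(config)[setdiff(names(config), "sim")],
                 sim_config = unclass(config$sim), stages = list())

  st <- pipeline_stage(report, "simulate", {
    pair <- generate_genome_pair(config$sim)
    rs_m <- simulate_readset(pair$genome_A, config$sim, "male")
    rs_f <- simulate_readset(pair$genome_A, config$sim, "female")
    list(pair = pair, male = rs_m, female = rs_f)
  }, verbose)
  report <- st$report; sim <- st$value

  st <- pipeline_stage(report, "map", {
    idx <- build_index(sim$pair$genome_B, w = config$mapper_w)
    list(index = idx,
         male = map_reads(sim$male$reads, idx, config$max_mismatches,
                          config$sim$insert_mean),
         female = map_reads(sim$female$reads, idx, config$max_mismatches,
                            config$sim$insert_mean))
  }, verbose)
  report <- st$report; maps <- st$value

  st <- pipeline_stage(report, "coverage", {
    prof_m <- compute_depth(maps$male, mapq_min = config$mapq_min)
    prof_f <- compute_depth(maps$female, mapq_min = config$mapq_min)
    pooled <- pool_profiles(list(prof_m, prof_f))
    stats <- list(male = contig_stats(prof_m), female = contig_stats(prof_f),
                  pooled = contig_stats(pooled))
    sweep <- if ("sweep" %in% skip) NULL else
      mapq_sweep(list(male = maps$male, female = maps$female),
                 sim$pair$genome_B, config$mapq_thresholds,
                 config$restrict_min_len)
    zi <- zero_intervals(pooled, min_len = config$zero_min_len,
                         merge_gap = config$zero_merge_gap)
    ratio <- sex_depth_ratio(stats$male, stats$female,
                             config$ratio_pseudocount, config$ratio_min_len)
    list(stats = stats, sweep = sweep, zero = zi, ratio = ratio)
  }, verbose)
  report <- st$report; cov <- st$value

  st <- pipeline_stage(report, "discover", {
    low <- screen_low_coverage(cov$stats$pooled,
                               cov$stats[c("male", "female")],
                               config$depth_max, config$norm_max,
                               config$breadth_max)
    um_m <- extract_unmapped_pairs(maps$male, sim$male$reads)
    um_f <- extract_unmapped_pairs(maps$female, sim$female$reads)
    um_seqs <- filter_reads(c(um_m$seq1, um_m$seq2, um_f$seq1, um_f$seq2))
    asm <- assemble_unmapped(um_seqs, min_contig = config$min_contig,
                             min_kmer_count = config$asm_min_kmer_count)
    validated <- reciprocal_validate(asm, maps$index, um_seqs)
    cands <- candidate_regions(low, cov$zero, validated)
    ranked <- prioritize_candidates(cands, sim$pair$truth,
                                    genome_a = sim$pair$genome_A)
    list(low = low, n_unmapped_pairs = nrow(um_m) + nrow(um_f),
         assembled = asm, validated = validated, ranked = ranked,
         recovery = attr(ranked, "recovery"))
  }, verbose)
  report <- st$report; disc <- st$value

  km <- NULL
  if (!"kmer" %in% skip) {
  st <- pipeline_stage(report, "kmer", {
    kt_f <- count_kmers(sim$female$reads, config$kmer$k,
                        config$kmer$min_count)
    kt_m <- count_kmers(sim$male$reads, config$kmer$k, config$kmer$min_count)
    summ <- shared_stats(kt_f, kt_m)
    f_spec <- kmer_subtract(kt_f, kt_m)
    window <- copy_window_filter(f_spec)
    cross <- if (nrow(f_spec) > 0) top_n_crosscheck(f_spec, kt_m) else 0L
    list(summary = summ, n_female_specific_window = nrow(window),
         crosscheck_hits = as.integer(cross))
  }, verbose)
  report <- st$report; km <- st$value
  }

  sk <- NULL
  if (!"sketch" %in% skip) {
  st <- pipeline_stage(report, "sketch", {
    sk <- list(minhash_sketch(sim$pair$genome_A, config$sketch_k,
                              config$sketch_s, config$sketch_seed, "query"),
               minhash_sketch(sim$pair$genome_B, config$sketch_k,
                              config$sketch_s, config$sketch_seed,
                              "reference"))
    mm <- mash_distance_matrix(sk)
    list(matrix = mm, pcoa = pcoa_ordination(mm))
  }, verbose)
  report <- st$report; sk <- st$value
  }

  n_contigs <- nrow(cov$stats$pooled)
  low_counts <- vapply(cov$stats, function(s)
    sum(s$mean_depth < config$depth_max), integer(1))
  genome_len <- sum(cov$stats$pooled$length)
  report$coverage <- list(
    n_contigs = n_contigs,
    weighted_mean_depth = vapply(cov$stats, attr, numeric(1),
                                 "weighted_mean"),
    low_depth_counts = low_counts,
    low_depth_pct = vapply(low_counts, fmt_percent, numeric(1),
                           total = n_contigs),
    low_depth_fraction = low_counts / n_contigs,
    zero_bp = sum(cov$zero$length),
    zero_pct = fmt_percent(sum(cov$zero$length), genome_len),
    zero_fraction = sum(cov$zero$length) / genome_len,
    sweep = cov$sweep,
    sex_ratio_flagged = sum(cov$ratio$bias != "none"))
  report$candidates <- list(
    n = nrow(disc$ranked),
    by_source = table(disc$ranked$source),
    n_unmapped_pairs = disc$n_unmapped_pairs,
    n_assembled = length(disc$assembled),
    n_validated = length(disc$validated),
    recovery = disc$recovery,
    table = disc$ranked)
  report$kmer <- km
  report$mash <- if (is.null(sk)) NULL else list(
    distance = sk$matrix$distance,
    distance_rounded = round(sk$matrix$distance, 5),
    similarity = sk$matrix$similarity,
    shared = sk$matrix$shared,
    pcoa_points = sk$pcoa$points,
    pcoa_variance = sk$pcoa$variance_explained)
  class(report) <- "run_report"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.table(cov$sweep, file.path(out_dir, "mapq_sweep.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(disc$ranked[setdiff(names(disc$ranked), "sequence")],
                file.path(out_dir, "candidates.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(as.data.frame(cov$stats$pooled),
                file.path(out_dir, "pooled_contig_stats.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_zero_bed(cov$zero, file.path(out_dir, "zero_intervals.bed"))
    json <- report
    json$candidates$table <- NULL
    jsonlite::write_json(json, file.path(out_dir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         pretty = TRUE)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("covmark run_report\n")
  cat("  contigs:", x$coverage$n_contigs,
      "| pooled weighted mean depth:",
      round(x$coverage$weighted_mean_depth[["pooled"]], 2), "x\n")
  cat("  low-depth contigs (male/female/pooled):",
      paste0(x$coverage$low_depth_counts, " (",
             x$coverage$low_depth_pct, "%)", collapse = " / "), "\n")
  cat("  zero-coverage:", x$coverage$zero_bp, "bp (",
      x$coverage$zero_pct, "% )\n")
  cat("  candidates:", x$candidates$n, "| recovery sensitivity:",
      round(x$candidates$recovery$sensitivity, 3), "FDR:",
      round(x$candidates$recovery$fdr, 3), "\n")
  cat("  mash D(query, reference):",
      format(x$mash$distance_rounded[1, 2]), "\n")
  invisible(x)
}
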