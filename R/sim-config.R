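#' Simulation configuration for synthetic genome pairs and read sets
#'
#' Collects every parameter of the synthetic study system: two genomes sharing
#' an i.i.d. random backbone, shallow background divergence concentrated in a
#' few highly diverged islands, species-specific insertions present only in the
#' query genome, 2 x 150 bp paired-end reads with a 500 +/- 50 bp insert model
#' at ~40-fold depth per individual, and optional female-enriched tandem repeat
#' families for the sex k-mer screen.
#'
#' @param contig_count number of contigs in the shared backbone.
#' @param contig_length length in bp of each contig (scalar, recycled, or a
#'   vector of length `contig_count`).
#' @param background_rate substitution rate per site on the backbone outside
#'   islands (default 0.015, shallow interspecific divergence).
#' @param island_count,island_length_bp,island_divergence number, length and
#'   substitution rate of planted high-divergence islands.
#' @param insertion_count,insertion_length_bp species-specific sequence present
#'   only in the query genome.
#' @param read_length read length in bp (default 150).
#' @param insert_mean,insert_sd fragment-size model in bp (defaults 500, 50).
#' @param depth_per_individual fold coverage per simulated individual
#'   (default 40).
#' @param error_rate per-base substitution sequencing-error rate.
#' @param sex_repeat_families number of female-enriched repeat families to
#'   plant (default 0 = none).
#' @param sex_repeat_unit_bp repeat unit length in bp.
#' @param sex_repeat_copies tandem copy number per family; a scalar, or a
#'   length-2 window `c(lo, hi)` to draw from uniformly.
#' @param rng_seed integer seed; identical configurations give byte-identical
#'   outputs.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(contig_count = 5,
                       contig_length = 100000,
                       background_rate = 0.015,
                       island_count = 5,
                       island_length_bp = 2000,
                       island_divergence = 0.10,
                       insertion_count = 2,
                       insertion_length_bp = 1000,
                       read_length = 150,
                       insert_mean = 500,
                       insert_sd = 50,
                       depth_per_individual = 40,
                       error_rate = 0.001,
                       sex_repeat_families = 0,
                       sex_repeat_unit_bp = 100,
                       sex_repeat_copies = 300,
                       rng_seed = 1) {
  contig_length <- rep_len(as.integer(contig_length), contig_count)
  rates <- c(background_rate, island_divergence, error_rate)
  if (any(rates < 0) || any(rates > 1))
    stop("rates must lie in [0, 1]")
  lens <- c(contig_length, read_length, insert_mean,
            if (island_count > 0) island_length_bp,
            if (insertion_count > 0) insertion_length_bp,
            if (sex_repeat_families > 0) sex_repeat_unit_bp)
  if (any(lens <= 0)) stop("all lengths must be positive")
  if (insert_sd < 0) stop("insert_sd must be non-negative")
  if (depth_per_individual <= 0) stop("depth_per_individual must be positive")
  if (length(sex_repeat_copies) > 2 || any(sex_repeat_copies < 1))
    stop("sex_repeat_copies must be a positive scalar or c(lo, hi) window")
  if (island_count * island_length_bp >= sum(contig_length))
    stop("configuration error: islands (", island_count, " x ",
         island_length_bp, " bp) do not fit in ", sum(contig_length),
         " bp of contigs")
  cfg <- list(
    contig_count = as.integer(contig_count),
    contig_length = contig_length,
    background_rate = background_rate,
    island_count = as.integer(island_count),
    island_length_bp = as.integer(island_length_bp),
    island_divergence = island_divergence,
    insertion_count = as.integer(insertion_count),
    insertion_length_bp = as.integer(insertion_length_bp),
    read_length = as.integer(read_length),
    insert_mean = insert_mean,
    insert_sd = insert_sd,
    depth_per_individual = depth_per_individual,
    error_rate = error_rate,
    sex_repeat_families = as.integer(sex_repeat_families),
    sex_repeat_unit_bp = as.integer(sex_repeat_unit_bp),
    sex_repeat_copies = as.integer(sex_repeat_copies),
    rng_seed = as.integer(rng_seed))
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$contig_count, "contigs of",
      paste(unique(x$contig_length), collapse = "/"), "bp;",
      x$island_count, "islands,", x$insertion_count, "insertions;",
      "depth", x$depth_per_individual, "x; seed", x$rng_seed, "\n")
  invisible(x)
}
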