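# substitute positions `pos` (1-based) of chars vector, uniform over the 3
# alternative bases
substitute_bases <- function(chars, pos) {
  if (length(pos) == 0) return(chars)
  bases <- c("A", "C", "G", "T")
  cur <- match(chars[pos], bases)
  step <- sample.int(3, length(pos), replace = TRUE)
  chars[pos] <- bases[(cur - 1 + step) %% 4 + 1]
  chars
}

# sample `n` disjoint intervals of length `len` on contigs with lengths
# `contig_len`, avoiding intervals in `avoid` (data.frame contig/start/end,
# 0-based half-open).  Rejection sampling; errors out when placement fails.
place_intervals <- function(n, len, contig_len, avoid = NULL, what = "interval") {
  if (n == 0)
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  placed <- if (is.null(avoid)) {
    data.frame(contig = character(0), start = integer(0), end = integer(0),
               stringsAsFactors = FALSE)
  } else avoid[, c("contig", "start", "end")]
  eligible <- names(contig_len)[contig_len >= len]
  if (length(eligible) == 0)
    stop("configuration error: no contig can hold a ", what, " of ", len, " bp")
  out <- vector("list", n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(200L)) {
      ctg <- if (length(eligible) == 1) eligible else sample(eligible, 1)
      start <- sample.int(contig_len[[ctg]] - len + 1L, 1) - 1L
      end <- start + len
      clash <- placed$contig == ctg & placed$start < end & placed$end > start
      if (!any(clash)) { ok <- TRUE; break }
    }
    if (!ok)
      stop("configuration error: could not place ", what, " ", i,
           " of ", len, " bp without overlap (too many or too long)")
    row <- data.frame(contig = ctg, start = start, end = end,
                      stringsAsFactors = FALSE)
    placed <- rbind(placed, row)
    out[[i]] <- row
  }
  res <- do.call(rbind, out)
  res[order(res$contig, res$start), , drop = FALSE]
}

# deterministic repeat-unit sequences and copy numbers, shared between
# generate_genome_pair() (truth) and simulate_readset() (planting)
sex_repeat_table <- function(cfg) {
  if (cfg$sex_repeat_families == 0)
    return(data.frame(family = character(0), unit = character(0),
                      copies = integer(0), stringsAsFactors = FALSE))
  with_seed(cfg$rng_seed + 90001L, {
    units <- vapply(seq_len(cfg$sex_repeat_families),
                    function(i) random_dna(cfg$sex_repeat_unit_bp),
                    character(1))
    copies <- if (length(cfg$sex_repeat_copies) == 2) {
      sample(cfg$sex_repeat_copies[1]:cfg$sex_repeat_copies[2],
             cfg$sex_repeat_families, replace = TRUE)
    } else rep(cfg$sex_repeat_copies, cfg$sex_repeat_families)
    data.frame(family = paste0("sexrep_", seq_along(units)),
               unit = units, copies = as.integer(copies),
               stringsAsFactors = FALSE)
  })
}

#' Generate a synthetic genome pair with planted truth
#'
#' Builds a reference-species genome B as an i.i.d. random backbone and derives
#' the query-species genome A from it by background substitutions outside
#' planted islands, elevated substitution inside islands, and species-specific
#' insertion sequences absent from B.  All planted features are recorded as
#' ground truth: islands in B coordinates (0-based half-open), insertions in A
#' coordinates, plus the deterministic sex-repeat unit table.
#'
#' @param cfg a [sim_config()].
#' @return list with `genome_A`, `genome_B` ([Biostrings::DNAStringSet]) and
#'   `truth` (class `truth_set`: `divergent_islands`, `insertions`,
#'   `sex_repeat_units`).
#' @export
generate_genome_pair <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$rng_seed)
  contig_names <- sprintf("contig_%02d", seq_len(cfg$contig_count))
  contig_len <- setNames(cfg$contig_length, contig_names)

  backbone <- lapply(contig_len, function(n)
    sample(c("A", "C", "G", "T"), n, replace = TRUE))

  islands <- place_intervals(cfg$island_count, cfg$island_length_bp,
                             contig_len, what = "island")
  insert_loci <- place_intervals(cfg$insertion_count, 1L, contig_len,
                                 avoid = islands, what = "insertion locus")

  genome_a <- backbone
  for (ctg in contig_names) {
    n <- contig_len[[ctg]]
    in_island <- rep(FALSE, n)
    isl <- islands[islands$contig == ctg, , drop = FALSE]
    for (j in seq_len(nrow(isl)))
      in_island[(isl$start[j] + 1):isl$end[j]] <- TRUE
    hit <- runif(n) < ifelse(in_island, cfg$island_divergence,
                             cfg$background_rate)
    genome_a[[ctg]] <- substitute_bases(genome_a[[ctg]], which(hit))
  }

  insertions <- data.frame(contig = character(0), start = integer(0),
                           end = integer(0), sequence = character(0),
                           stringsAsFactors = FALSE)
  if (nrow(insert_loci) > 0) {
    insert_loci$sequence <- vapply(seq_len(nrow(insert_loci)), function(i)
      random_dna(cfg$insertion_length_bp), character(1))
    # apply insertions per contig in descending position so earlier coordinates
    # stay valid; A-coordinates then account for upstream insertions
    rows <- list()
    for (ctg in unique(insert_loci$contig)) {
      loci <- insert_loci[insert_loci$contig == ctg, , drop = FALSE]
      loci <- loci[order(loci$start), , drop = FALSE]
      shift <- 0L
      chars <- genome_a[[ctg]]
      pieces <- list()
      prev <- 0L
      for (j in seq_len(nrow(loci))) {
        at <- loci$start[j]
        pieces[[length(pieces) + 1L]] <- chars[seq_len(at - prev) + prev]
        pieces[[length(pieces) + 1L]] <- strsplit(loci$sequence[j], "")[[1]]
        a_start <- at + shift
        rows[[length(rows) + 1L]] <- data.frame(
          contig = ctg, start = a_start,
          end = a_start + cfg$insertion_length_bp,
          sequence = loci$sequence[j], stringsAsFactors = FALSE)
        shift <- shift + cfg$insertion_length_bp
        prev <- at
      }
      if (prev < length(chars))
        pieces[[length(pieces) + 1L]] <- chars[(prev + 1L):length(chars)]
      genome_a[[ctg]] <- unlist(pieces, use.names = FALSE)
    }
    insertions <- do.call(rbind, rows)
    insertions <- insertions[order(insertions$contig, insertions$start), ,
                             drop = FALSE]
    rownames(insertions) <- NULL
  }

  genome_a_str <- vapply(genome_a, paste, character(1), collapse = "")
  # island coordinates on A shift by the insertions upstream of them; record
  # the A-version sequence so sequence-level recovery checks have the truth
  if (nrow(islands) > 0) {
    shift <- vapply(seq_len(nrow(islands)), function(i) {
      up <- insert_loci$contig == islands$contig[i] &
        insert_loci$start <= islands$start[i]
      sum(up) * cfg$insertion_length_bp
    }, integer(1))
    islands$start_a <- islands$start + shift
    islands$end_a <- islands$end + shift
    islands$sequence_a <- substr(genome_a_str[islands$contig],
                                 islands$start_a + 1L, islands$end_a)
  } else {
    islands$start_a <- integer(0)
    islands$end_a <- integer(0)
    islands$sequence_a <- character(0)
  }

  truth <- list(divergent_islands = islands,
                insertions = insertions,
                sex_repeat_units = sex_repeat_table(cfg))
  class(truth) <- "truth_set"

  to_set <- function(lst) Biostrings::DNAStringSet(
    setNames(vapply(lst, paste, character(1), collapse = ""), names(lst)))
  list(genome_A = to_set(genome_a), genome_B = to_set(backbone), truth = truth)
}

#' @export
print.truth_set <- function(x, ...) {
  cat("truth_set:", nrow(x$divergent_islands), "islands,",
      nrow(x$insertions), "insertions,",
      nrow(x$sex_repeat_units), "sex repeat families\n")
  invisible(x)
}

#' Write truth intervals as BED (0-based half-open)
#'
#' @param truth a `truth_set`.
#' @param islands_path,insertions_path output paths (NULL to skip either).
#' @return invisibly, the truth set.
#' @export
write_truth_bed <- function(truth, islands_path = NULL, insertions_path = NULL) {
  wr <- function(df, path, name) {
    bed <- data.frame(df$contig, df$start, df$end,
                      paste0(name, seq_len(nrow(df))))
    write.table(bed, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(islands_path)) wr(truth$divergent_islands, islands_path, "island_")
  if (!is.null(insertions_path)) wr(truth$insertions, insertions_path, "insertion_")
  invisible(truth)
}
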