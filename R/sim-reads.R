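# inject i.i.d. substitution errors at `rate` into sequences
inject_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  n_err <- rbinom(length(seqs), nchar(seqs), rate)
  idx <- which(n_err > 0)
  for (i in idx) {
    chars <- strsplit(seqs[i], "")[[1]]
    pos <- sample.int(length(chars), n_err[i])
    seqs[i] <- paste(substitute_bases(chars, pos), collapse = "")
  }
  seqs
}

# plant each repeat family as one tandem array at a random locus
plant_repeats <- function(genome_chr, repeats) {
  loci <- vector("list", nrow(repeats))
  for (i in seq_len(nrow(repeats))) {
    array_seq <- strrep(repeats$unit[i], repeats$copies[i])
    ctg <- if (length(genome_chr) == 1) names(genome_chr) else
      sample(names(genome_chr), 1)
    at <- sample.int(nchar(genome_chr[[ctg]]) + 1L, 1) - 1L  # 0-based cut point
    genome_chr[[ctg]] <- paste0(substr(genome_chr[[ctg]], 1, at), array_seq,
                                substring(genome_chr[[ctg]], at + 1))
    loci[[i]] <- data.frame(family = repeats$family[i], contig = ctg,
                            start = at, end = at + nchar(array_seq),
                            stringsAsFactors = FALSE)
  }
  list(genome = genome_chr, loci = do.call(rbind, loci))
}

#' Simulate a paired-end read set with truth alignments
#'
#' Draws `round(contig_length * depth / (2 * read_length))` read pairs per
#' contig with fragment lengths from a truncated normal
#' (`insert_mean`, `insert_sd`, floored at `read_length`), uniform fragment
#' start, random fragment strand, and i.i.d. substitution errors.  Mate 2 is
#' the reverse complement of the fragment's other end.  The returned truth
#' alignments place every read at its sampled origin with MAPQ 60, so the
#' coverage stages can run without any external aligner.  For
#' `label = "female"` with configured repeat families, tandem repeat arrays
#' are planted into a copy of the genome before reads are drawn.
#'
#' @param genome reference to sequence from (DNAStringSet or named character).
#' @param cfg a [sim_config()]; the RNG stream is derived from
#'   `cfg$rng_seed` + 1 (male) or + 2 (female).
#' @param label `"male"` or `"female"`.
#' @param depth override for `cfg$depth_per_individual` (used by the k-mer
#'   screening stage, which samples shallower).
#' @return list with `reads` (data.frame `id`, `seq1`, `seq2`, constant Q40
#'   qualities), `truth_aln` (`covmark_aln`, MAPQ 60), `origins`
#'   (per-mate origin table) and `repeat_loci` (planted arrays, female only).
#' @export
simulate_readset <- function(genome, cfg, label = c("male", "female"),
                             depth = NULL) {
  label <- match.arg(label)
  stopifnot(inherits(cfg, "sim_config"))
  genome_chr <- as_genome_chr(genome)
  if (is.null(depth)) depth <- cfg$depth_per_individual
  set.seed(cfg$rng_seed + if (label == "male") 1L else 2L)

  repeat_loci <- NULL
  if (label == "female" && cfg$sex_repeat_families > 0) {
    planted <- plant_repeats(genome_chr, sex_repeat_table(cfg))
    genome_chr <- planted$genome
    repeat_loci <- planted$loci
  }

  rl <- cfg$read_length
  per_contig <- lapply(names(genome_chr), function(ctg) {
    len <- nchar(genome_chr[[ctg]])
    if (len < rl) {
      warning("contig '", ctg, "' (", len, " bp) is shorter than a read; skipped")
      return(NULL)
    }
    n <- round(len * depth / (2 * rl))
    if (n == 0) return(NULL)
    frag <- pmin(pmax(round(rnorm(n, cfg$insert_mean, cfg$insert_sd)), rl), len)
    start <- floor(runif(n) * (len - frag + 1)) + 1L  # 1-based fragment start
    end <- start + frag - 1L
    plus <- runif(n) < 0.5
    left <- substring(genome_chr[[ctg]], start, start + rl - 1L)
    right <- substring(genome_chr[[ctg]], end - rl + 1L, end)
    data.frame(contig = ctg, start = start, end = end, plus = plus,
               left = left, right = right, stringsAsFactors = FALSE)
  })
  per_contig <- per_contig[!vapply(per_contig, is.null, logical(1))]
  if (length(per_contig) == 0) stop("no contig long enough to sequence")
  frags <- do.call(rbind, per_contig)
  n <- nrow(frags)
  ids <- sprintf("%s_%07d", label, seq_len(n))

  right_rc <- revcomp(frags$right)
  left_rc <- revcomp(frags$left)
  # plus fragment: mate1 = left (fwd), mate2 = rc(right)
  # minus fragment: mate1 = rc(right), mate2 = left
  seq1 <- ifelse(frags$plus, frags$left, right_rc)
  seq2 <- ifelse(frags$plus, right_rc, frags$left)
  seq1 <- inject_errors(seq1, cfg$error_rate)
  seq2 <- inject_errors(seq2, cfg$error_rate)
  qual <- strrep("I", rl)
  reads <- data.frame(id = ids, seq1 = seq1, seq2 = seq2,
                      stringsAsFactors = FALSE)

  # truth alignments: reference positions of the two fragment ends
  pos1 <- ifelse(frags$plus, frags$start, frags$end - rl + 1L)
  pos2 <- ifelse(frags$plus, frags$end - rl + 1L, frags$start)
  rev1 <- !frags$plus
  rev2 <- frags$plus
  tlen1 <- ifelse(frags$plus, frags$end - frags$start + 1L,
                  -(frags$end - frags$start + 1L))
  base_flag <- FLAG_PAIRED + FLAG_PROPER
  flag1 <- base_flag + FLAG_FIRST + ifelse(rev1, FLAG_REVERSE, 0L) +
    ifelse(rev2, FLAG_MATE_REVERSE, 0L)
  flag2 <- base_flag + FLAG_SECOND + ifelse(rev2, FLAG_REVERSE, 0L) +
    ifelse(rev1, FLAG_MATE_REVERSE, 0L)
  cigar <- sprintf("%dM", rl)
  mk <- function(flag, pos, pnext, tlen, seqs) data.frame(
    qname = ids, flag = as.integer(flag), rname = frags$contig,
    pos = as.integer(pos), mapq = 60L, cigar = cigar, rnext = "=",
    pnext = as.integer(pnext), tlen = as.integer(tlen), seq = seqs,
    qual = qual, nm = NA_integer_, stringsAsFactors = FALSE)
  truth <- rbind(mk(flag1, pos1, pos2, tlen1, reads$seq1),
                 mk(flag2, pos2, pos1, -tlen1, reads$seq2))
  truth <- truth[order(truth$rname, truth$pos, truth$qname), ]
  rownames(truth) <- NULL
  contigs <- setNames(nchar(genome_chr), names(genome_chr))
  origins <- data.frame(id = rep(ids, 2), mate = rep(1:2, each = n),
                        contig = rep(frags$contig, 2),
                        pos = c(pos1, pos2),
                        rev = c(rev1, rev2), stringsAsFactors = FALSE)
  list(reads = reads, truth_aln = alignments(truth, contigs),
       origins = origins, repeat_loci = repeat_loci,
       sampled_genome = Biostrings::DNAStringSet(genome_chr))
}

#' Write a read set as a gzipped FASTQ pair
#'
#' @param reads data.frame with `id`, `seq1`, `seq2` as returned by
#'   [simulate_readset()].
#' @param prefix output prefix; files are `<prefix>_R1.fastq.gz` and
#'   `<prefix>_R2.fastq.gz`.
#' @return character vector of the two paths, invisibly.
#' @export
write_fastq_pair <- function(reads, prefix) {
  paths <- paste0(prefix, c("_R1.fastq.gz", "_R2.fastq.gz"))
  for (m in 1:2) {
    seqs <- reads[[paste0("seq", m)]]
    con <- gzfile(paths[m], "w")
    writeLines(paste0("@", reads$id, "/", m, "\n", seqs, "\n+\n",
                      strrep("I", nchar(seqs))), con)
    close(con)
  }
  invisible(paths)
}

#' Read a FASTQ pair back into a read table
#'
#' Minimal four-line-record FASTQ reader (gzip accepted); mate ids must agree
#' after stripping a trailing `/1` / `/2`.
#'
#' @param r1,r2 FASTQ paths.
#' @return data.frame with `id`, `seq1`, `seq2`.
#' @export
read_fastq_pair <- function(r1, r2) {
  rd <- function(path, mate) {
    lines <- readLines(path)
    if (length(lines) %% 4 != 0)
      stop("malformed FASTQ '", path, "': record ", length(lines) %/% 4 + 1,
           " is truncated")
    ids <- sub("/[12]$", "", sub("^@", "", lines[seq(1, length(lines), 4)]))
    ids <- sub(" .*$", "", ids)
    list(id = ids, seq = lines[seq(2, length(lines), 4)])
  }
  a <- rd(r1, 1); b <- rd(r2, 2)
  if (!identical(a$id, b$id)) stop("mate ids of the FASTQ pair do not agree")
  data.frame(id = a$id, seq1 = a$seq, seq2 = b$seq, stringsAsFactors = FALSE)
}
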