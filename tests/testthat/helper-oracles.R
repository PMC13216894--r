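# Shared fixtures and independent brute-force oracles.

rnd_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                             collapse = "")

# plant `n_mm` substitutions into a read at random positions
mutate_read <- function(read, n_mm) {
  if (n_mm == 0) return(read)
  chars <- strsplit(read, "")[[1]]
  pos <- sample(seq_along(chars), n_mm)
  bases <- c("A", "C", "G", "T")
  chars[pos] <- bases[(match(chars[pos], bases) %% 4) + 1]
  paste(chars, collapse = "")
}

# exhaustive-placement mapping oracle: scan every ungapped placement of the
# read and its reverse complement on every contig; best = fewest mismatches,
# ties by (contig index, position, strand fwd-first); NULL when no placement
# has <= max_mm mismatches
oracle_map <- function(refs, read, max_mm) {
  best <- NULL
  rl <- nchar(read)
  for (ci in seq_along(refs)) {
    ref <- refs[[ci]]
    for (ori in 0:1) {
      s <- if (ori == 0) read else revcomp(read)
      sc <- strsplit(s, "")[[1]]
      for (start in seq_len(nchar(ref) - rl + 1)) {
        rc <- strsplit(substr(ref, start, start + rl - 1), "")[[1]]
        mm <- sum(sc != rc)
        if (mm > max_mm) next
        cand <- list(contig = ci, pos = start, ori = ori, mm = mm)
        if (is.null(best) || mm < best$mm) best <- cand
      }
    }
  }
  best
}

# positionwise depth recount oracle over parsed M-runs
oracle_depth <- function(contig_len, recs, mapq_min) {
  depth <- integer(contig_len)
  for (i in seq_len(nrow(recs))) {
    if (recs$mapq[i] < mapq_min) next
    span <- recs$pos[i]:(recs$pos[i] + recs$mlen[i] - 1)
    depth[span] <- depth[span] + 1L
  }
  depth
}

# canonical k-mer recount oracle (substring enumeration, no compiled code)
oracle_kmer_count <- function(seqs, k, min_count) {
  km <- unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, seq_len(n - k + 1), seq_len(n - k + 1) + k - 1)
  }), use.names = FALSE)
  km <- km[!grepl("[^ACGT]", km)]
  if (length(km) == 0)
    return(data.frame(kmer = character(0), count = integer(0)))
  canon <- pmin(km, revcomp(km))
  tab <- table(canon)
  tab <- tab[tab >= min_count]
  out <- data.frame(kmer = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(out$kmer), , drop = FALSE]
  rownames(out) <- NULL
  out
}

oracle_distinct_kmers <- function(seqs, k) oracle_kmer_count(seqs, k, 1)$kmer

# exhaustive in-silico PCR oracle: enumerate every site of either primer on
# either strand (mismatch count by character comparison, 3' base exact), then
# every convergent plus/minus site pair with product in range
oracle_epcr <- function(forward, reverse, genome, max_mm, range) {
  out <- list()
  for (ctg in names(genome)) {
    subj <- genome[[ctg]]
    n <- nchar(subj)
    sites <- list()
    for (role in c("forward", "reverse")) {
      primer <- if (role == "forward") forward else reverse
      pl <- nchar(primer)
      pc <- strsplit(primer, "")[[1]]
      rc <- strsplit(revcomp(primer), "")[[1]]
      for (start in seq_len(n - pl + 1)) {
        win <- strsplit(substr(subj, start, start + pl - 1), "")[[1]]
        if (sum(win != pc) <= max_mm && win[pl] == pc[pl])
          sites[[length(sites) + 1]] <- data.frame(
            start = start, end = start + pl - 1, strand = "+", primer = role)
        if (sum(win != rc) <= max_mm && win[1] == rc[1])
          sites[[length(sites) + 1]] <- data.frame(
            start = start, end = start + pl - 1, strand = "-", primer = role)
      }
    }
    if (length(sites) == 0) next
    sites <- do.call(rbind, sites)
    plus <- sites[sites$strand == "+", , drop = FALSE]
    minus <- sites[sites$strand == "-", , drop = FALSE]
    for (i in seq_len(nrow(plus))) for (j in seq_len(nrow(minus))) {
      len <- minus$end[j] - plus$start[i] + 1
      if (minus$start[j] > plus$start[i] && len >= range[1] && len <= range[2])
        out[[length(out) + 1]] <- data.frame(
          contig = ctg, forward_primer = plus$primer[i],
          reverse_primer = minus$primer[j], forward_start = plus$start[i],
          reverse_end = minus$end[j], product_length = len)
    }
  }
  if (length(out) == 0)
    return(data.frame(contig = character(0), forward_start = integer(0),
                      reverse_end = integer(0), product_length = integer(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$contig, res$forward_start, res$reverse_end), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

# brute-force reciprocal interval overlap (both >= frac), double loop
oracle_reciprocal_hits <- function(cand, truth, frac = 0.5) {
  truth_hit <- logical(nrow(truth))
  cand_hit <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) for (j in seq_len(nrow(truth))) {
    if (cand$contig[i] != truth$contig[j]) next
    ov <- min(cand$end[i], truth$end[j]) - max(cand$start[i], truth$start[j])
    if (ov >= frac * (cand$end[i] - cand$start[i]) &&
        ov >= frac * (truth$end[j] - truth$start[j])) {
      truth_hit[j] <- TRUE
      cand_hit[i] <- TRUE
    }
  }
  list(truth_hit = truth_hit, cand_hit = cand_hit)
}

# minimal truth_set constructor for recovery tests
make_truth <- function(islands = NULL, insertions = NULL) {
  empty_iv <- data.frame(contig = character(0), start = integer(0),
                         end = integer(0), stringsAsFactors = FALSE)
  ins <- insertions
  if (is.null(ins))
    ins <- data.frame(contig = character(0), start = integer(0),
                      end = integer(0), sequence = character(0),
                      stringsAsFactors = FALSE)
  structure(list(divergent_islands = if (is.null(islands)) empty_iv else islands,
                 insertions = ins,
                 sex_repeat_units = data.frame()),
            class = "truth_set")
}
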