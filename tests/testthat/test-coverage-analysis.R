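toy_aln <- function(recs, contigs) {
  n <- nrow(recs)
  alignments(data.frame(
    qname = paste0("r", seq_len(n)), flag = 0L, rname = recs$rname,
    pos = recs$pos, mapq = recs$mapq, cigar = recs$cigar, rnext = "*",
    pnext = 0L, tlen = 0L, seq = "*", qual = "*",
    nm = NA_integer_, stringsAsFactors = FALSE), contigs)
}

test_that("depth accumulation follows CIGAR M runs and the MAPQ threshold", {
  aln <- toy_aln(data.frame(rname = "c1", pos = 1L, mapq = 60L,
                            cigar = "150M", stringsAsFactors = FALSE),
                 c(c1 = 1000L))
  prof <- compute_depth(aln)
  expect_equal(sum(prof$c1), 150)
  expect_true(all(prof$c1[1:150] == 1) && all(prof$c1[151:1000] == 0))
  st <- contig_stats(prof)
  expect_equal(st$mean_depth, 0.15)
  expect_equal(st$breadth, 0.15)

  # below-threshold records contribute nothing
  low <- toy_aln(data.frame(rname = "c1", pos = 1L, mapq = 0L,
                            cigar = "150M", stringsAsFactors = FALSE),
                 c(c1 = 1000L))
  expect_true(all(compute_depth(low, mapq_min = 30)$c1 == 0))

  # soft clips consume no reference
  clip <- toy_aln(data.frame(rname = "c1", pos = 10L, mapq = 60L,
                             cigar = "10S100M40S", stringsAsFactors = FALSE),
                  c(c1 = 1000L))
  expect_equal(sum(compute_depth(clip)$c1), 100)
  expect_equal(which(compute_depth(clip)$c1 == 1L), 10:109)

  bad <- toy_aln(data.frame(rname = "c1", pos = 1L, mapq = 60L,
                            cigar = "10M", stringsAsFactors = FALSE),
                 c(c1 = 100L))
  attr(bad, "contigs") <- c(c2 = 100L)  # header no longer matches records
  expect_error(compute_depth(bad), "unknown contig")
})

test_that("depth equals a positionwise recount on random records", {
  set.seed(61)
  for (rep in 1:5) {
    recs <- data.frame(rname = "c1",
                       pos = sample(1:800, 10, replace = TRUE),
                       mapq = sample(c(0L, 20L, 60L), 10, replace = TRUE),
                       mlen = sample(50:150, 10, replace = TRUE))
    recs$cigar <- sprintf("%dM", recs$mlen)
    aln <- toy_aln(recs, c(c1 = 1000L))
    for (thr in c(0, 30)) {
      expect_equal(as.integer(compute_depth(aln, mapq_min = thr)$c1),
                   oracle_depth(1000L, recs, thr))
    }
    # conservation: total depth equals total M length of passing records
    expect_equal(sum(compute_depth(aln)$c1), sum(recs$mlen))
  }
})

test_that("pooling is a positionwise sum with strict compatibility checks", {
  p1 <- depth_profiles(list(c1 = c(0L, 1L, 2L)))
  p2 <- depth_profiles(list(c1 = c(3L, 0L, 1L)))
  expect_equal(as.integer(pool_profiles(list(p1, p2))$c1), c(3, 1, 3))
  zero <- depth_profiles(list(c1 = c(0L, 0L, 0L)))
  expect_equal(as.integer(pool_profiles(list(p1, zero))$c1),
               as.integer(p1$c1))
  expect_error(pool_profiles(list(p1, depth_profiles(list(c2 = 1:3)))),
               "identical contigs")
  expect_error(pool_profiles(list(p1, depth_profiles(list(c1 = 1:3),
                                                     mapq_min = 10))),
               "MAPQ")

  set.seed(67)
  pa <- depth_profiles(list(x = sample(0:5, 400, TRUE),
                            y = sample(0:3, 300, TRUE)))
  pb <- depth_profiles(list(x = sample(0:5, 400, TRUE),
                            y = sample(0:3, 300, TRUE)))
  pooled <- contig_stats(pool_profiles(list(pa, pb)))
  expect_equal(pooled$mean_depth,
               contig_stats(pa)$mean_depth + contig_stats(pb)$mean_depth)
})

test_that("contig statistics, weighted mean and normalization behave", {
  prof <- depth_profiles(list(a = rep(10L, 100), b = rep(30L, 300)))
  st <- contig_stats(prof)
  expect_equal(attr(st, "weighted_mean"), 25)
  expect_equal(st$normalized_depth, c(10, 30) / 25)
  # length-weighted mean of normalized depth is 1 by construction
  expect_equal(sum(st$normalized_depth * st$length) / sum(st$length), 1)

  uni <- contig_stats(depth_profiles(list(a = rep(7L, 50), b = rep(7L, 500))))
  expect_true(all(uni$normalized_depth == 1))

  expect_equal(fmt_percent(5176, 44726), 11.6)
  expect_equal(fmt_percent(5961, 44726), 13.3)
})

test_that("zero-coverage intervals match hand enumeration", {
  prof <- c(0L, 0L, 1L, 2L, 0L, 0L, 0L, 3L)
  zi2 <- zero_intervals(prof, min_len = 2)
  expect_equal(zi2$start, c(0, 4))
  expect_equal(zi2$end, c(2, 7))
  zi3 <- zero_intervals(prof, min_len = 3)
  expect_equal(nrow(zi3), 1)
  expect_equal(c(zi3$start, zi3$end), c(4, 7))
  expect_equal(nrow(zero_intervals(rep(2L, 50), min_len = 1)), 0)

  # gap merging bridges isolated covered bases before the length filter
  gap <- c(rep(0L, 40), 1L, rep(0L, 40))
  expect_equal(nrow(zero_intervals(gap, min_len = 50)), 0)
  merged <- zero_intervals(gap, min_len = 50, merge_gap = 2)
  expect_equal(c(merged$start, merged$end, merged$length), c(0, 81, 81))

  # partition: zero bp at min_len 1 plus covered bp equals contig length
  set.seed(71)
  rprof <- sample(0:2, 500, TRUE, prob = c(0.4, 0.3, 0.3))
  zi <- zero_intervals(rprof, min_len = 1)
  expect_equal(sum(zi$length) + sum(rprof >= 1), 500)
})

test_that("the MAPQ sweep is monotone and collapses for uniform MAPQ", {
  cfg <- sim_config(contig_count = 1, contig_length = 30000,
                    island_count = 1, island_length_bp = 1500,
                    insertion_count = 0, depth_per_individual = 10,
                    rng_seed = 83)
  pair <- generate_genome_pair(cfg)
  idx <- build_index(pair$genome_B)
  alns <- list(
    male = map_reads(simulate_readset(pair$genome_A, cfg, "male")$reads, idx),
    female = map_reads(simulate_readset(pair$genome_A, cfg, "female")$reads,
                       idx))
  sw <- mapq_sweep(alns, pair$genome_B)
  for (set in names(alns)) for (ml in c(1, 500)) {
    rows <- sw[sw$set == set & sw$min_len == ml, ]
    expect_true(all(diff(rows$zero_pct) >= 0))
  }
  # the >= 500 bp restriction can only drop zero-coverage bp
  merged <- merge(sw[sw$min_len == 1, ], sw[sw$min_len == 500, ],
                  by = c("set", "mapq_min"))
  expect_true(all(merged$zero_bp.y <= merged$zero_bp.x))

  # a truth alignment set is uniformly MAPQ 60: identical rows across cuts
  truth_sw <- mapq_sweep(list(m = simulate_readset(pair$genome_A, cfg,
                                                   "male")$truth_aln),
                         pair$genome_A)
  for (ml in c(1, 500)) {
    rows <- truth_sw[truth_sw$min_len == ml, ]
    expect_true(all(rows$zero_bp == rows$zero_bp[1]))
    expect_true(all(rows$weighted_mean_depth == rows$weighted_mean_depth[1]))
  }
  expect_error(mapq_sweep(alns, pair$genome_B, thresholds = c(30, 10)),
               "ascending")
})

test_that("sex depth ratios use the pseudocount and the 50-kb floor", {
  stats_m <- data.frame(contig = c("s1", "s2", "s3"),
                        length = c(60000L, 60000L, 10000L),
                        mean_depth = c(40, 40, 55))
  stats_f <- data.frame(contig = c("s1", "s2", "s3"),
                        length = c(60000L, 60000L, 10000L),
                        mean_depth = c(40, 0, 1))
  tab <- sex_depth_ratio(stats_m, stats_f, pseudocount = 0.5)
  expect_equal(tab$ratio[1], 1)
  expect_equal(tab$bias[1], "none")
  expect_equal(tab$ratio[2], 40.5 / 0.5)  # 81, flagged male-biased
  expect_equal(tab$bias[2], "male")
  # extreme ratio on a 10-kb scaffold is excluded by the length filter
  expect_equal(tab$bias[3], "none")
  expect_error(sex_depth_ratio(stats_m, stats_f, pseudocount = 0), "positive")
})

test_that("pooled-subset containment holds on random coverage tables", {
  set.seed(89)
  for (rep in 1:20) {
    m <- runif(40, 0, 60)
    f <- runif(40, 0, 60)
    pooled <- m + f
    thr <- 30
    expect_true(all(which(pooled < thr) %in%
                    intersect(which(m < thr), which(f < thr))))
  }
})
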