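test_that("zero-divergence configuration reproduces the reference exactly", {
  cfg <- sim_config(contig_count = 2, contig_length = 5000,
                    background_rate = 0, island_count = 0,
                    insertion_count = 0, rng_seed = 3)
  pair <- generate_genome_pair(cfg)
  expect_identical(as.character(pair$genome_A), as.character(pair$genome_B))
  expect_equal(nrow(pair$truth$divergent_islands), 0)
  expect_equal(nrow(pair$truth$insertions), 0)
})

test_that("island mismatch counts match a positionwise comparison oracle", {
  cfg <- sim_config(contig_count = 3, contig_length = 20000,
                    background_rate = 0, island_count = 5,
                    island_length_bp = 2000, island_divergence = 0.10,
                    insertion_count = 0, rng_seed = 7)
  pair <- generate_genome_pair(cfg)
  a <- as.character(pair$genome_A)
  b <- as.character(pair$genome_B)
  isl <- pair$truth$divergent_islands
  expect_equal(nrow(isl), 5)
  sd3 <- 3 * sqrt(2000 * 0.10 * 0.90)
  total_mm <- 0
  for (j in seq_len(nrow(isl))) {
    sa <- strsplit(substr(a[[isl$contig[j]]], isl$start[j] + 1, isl$end[j]),
                   "")[[1]]
    sb <- strsplit(substr(b[[isl$contig[j]]], isl$start[j] + 1, isl$end[j]),
                   "")[[1]]
    mm <- sum(sa != sb)
    expect_lt(abs(mm - 200), sd3)
    total_mm <- total_mm + mm
  }
  # with background_rate 0 every difference lies inside an island
  all_mm <- sum(mapply(function(x, y)
    sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]]), a, b))
  expect_equal(all_mm, total_mm)
})

test_that("identical seeds give byte-identical genomes, truth and reads", {
  cfg <- sim_config(contig_count = 2, contig_length = 8000,
                    depth_per_individual = 4, sex_repeat_families = 1,
                    sex_repeat_unit_bp = 50, sex_repeat_copies = 20,
                    rng_seed = 19)
  p1 <- generate_genome_pair(cfg)
  p2 <- generate_genome_pair(cfg)
  expect_identical(as.character(p1$genome_A), as.character(p2$genome_A))
  expect_identical(p1$truth, p2$truth)
  r1 <- simulate_readset(p1$genome_A, cfg, "female")
  r2 <- simulate_readset(p2$genome_A, cfg, "female")
  expect_identical(r1$reads, r2$reads)
  expect_identical(as.data.frame(r1$truth_aln), as.data.frame(r2$truth_aln))
})

test_that("pair count, error-free substring property and realized depth hold", {
  cfg <- sim_config(contig_count = 1, contig_length = 100000,
                    background_rate = 0, island_count = 0,
                    insertion_count = 0, error_rate = 0,
                    depth_per_individual = 40, rng_seed = 23)
  pair <- generate_genome_pair(cfg)
  rs <- simulate_readset(pair$genome_B, cfg, "male")
  expect_equal(nrow(rs$reads), 13333)  # round(100000 * 40 / (2 * 150))

  g <- as.character(pair$genome_B)[[1]]
  some <- rs$reads[sample.int(nrow(rs$reads), 200), ]
  hits <- vapply(seq_len(nrow(some)), function(i) {
    grepl(some$seq1[i], g, fixed = TRUE) ||
      grepl(revcomp(some$seq1[i]), g, fixed = TRUE)
  }, logical(1))
  expect_true(all(hits))

  prof <- compute_depth(rs$truth_aln, pair$genome_B)
  st <- contig_stats(prof)
  expect_lt(abs(st$mean_depth[1] - 40) / 40, 0.05)
})

test_that("contigs shorter than a read are skipped with a warning", {
  cfg <- sim_config(contig_count = 1, contig_length = 5000,
                    island_count = 0, insertion_count = 0, rng_seed = 2)
  genome <- c(ok = rnd_dna(5000), tiny = rnd_dna(60))
  expect_warning(rs <- simulate_readset(genome, cfg, "male"), "shorter")
  expect_false(any(rs$origins$contig == "tiny"))
})

test_that("insertion sequences have no homolog in the reference genome", {
  cfg <- sim_config(contig_count = 2, contig_length = 10000,
                    island_count = 0, insertion_count = 2,
                    insertion_length_bp = 400, rng_seed = 31)
  pair <- generate_genome_pair(cfg)
  b <- as.character(pair$genome_B)
  for (j in seq_len(nrow(pair$truth$insertions))) {
    ins <- pair$truth$insertions$sequence[j]
    expect_false(any(vapply(b, grepl, logical(1), pattern = ins,
                            fixed = TRUE)))
    expect_false(any(vapply(b, grepl, logical(1), pattern = revcomp(ins),
                            fixed = TRUE)))
    # and the recorded interval really holds the sequence in genome A
    with(pair$truth$insertions[j, ], expect_identical(
      substr(as.character(pair$genome_A)[[contig]], start + 1, end), ins))
  }
})

test_that("planted female repeats dominate the female-only k-mer set", {
  cfg <- sim_config(contig_count = 1, contig_length = 30000,
                    background_rate = 0, island_count = 0,
                    insertion_count = 0, error_rate = 0,
                    depth_per_individual = 15, sex_repeat_families = 1,
                    sex_repeat_unit_bp = 100, sex_repeat_copies = 300,
                    rng_seed = 41)
  pair <- generate_genome_pair(cfg)
  rs_m <- simulate_readset(pair$genome_A, cfg, "male")
  rs_f <- simulate_readset(pair$genome_A, cfg, "female")
  k <- 21
  unit <- pair$truth$sex_repeat_units$unit[1]
  # planted set: canonical k-mers of the circularized unit (tandem junctions)
  planted <- oracle_distinct_kmers(paste0(unit, substr(unit, 1, k - 1)), k)
  f_km <- covmark:::cpp_distinct_kmers(c(rs_f$reads$seq1, rs_f$reads$seq2), k)
  m_km <- covmark:::cpp_distinct_kmers(c(rs_m$reads$seq1, rs_m$reads$seq2), k)
  f_only <- setdiff(f_km, m_km)
  expect_true(all(planted %in% f_only))
  # anything else unique to the female pool can only span the array ends
  expect_lte(length(setdiff(f_only, planted)), 4 * (k - 1))
})

test_that("FASTQ and SAM round-trips preserve the data", {
  cfg <- sim_config(contig_count = 1, contig_length = 4000,
                    island_count = 0, insertion_count = 0,
                    depth_per_individual = 3, rng_seed = 13)
  pair <- generate_genome_pair(cfg)
  rs <- simulate_readset(pair$genome_B, cfg, "male")
  tmp <- withr::local_tempdir()
  paths <- write_fastq_pair(rs$reads, file.path(tmp, "sim"))
  back <- read_fastq_pair(paths[1], paths[2])
  expect_identical(back, rs$reads)

  sam <- file.path(tmp, "truth.sam")
  write_sam(rs$truth_aln, sam)
  back_aln <- read_sam(sam)
  expect_identical(as.data.frame(back_aln), as.data.frame(rs$truth_aln))
  expect_identical(attr(back_aln, "contigs"), attr(rs$truth_aln, "contigs"))

  fa <- file.path(tmp, "genome.fa")
  write_genome_fasta(pair$genome_B, fa)
  expect_identical(as.character(read_genome_fasta(fa)),
                   as.character(pair$genome_B))
})

test_that("impossible placements raise a configuration error", {
  expect_error(sim_config(contig_count = 1, contig_length = 5000,
                          island_count = 10, island_length_bp = 1000),
               "configuration error")
  cfg <- sim_config(contig_count = 1, contig_length = 10000,
                    island_count = 4, island_length_bp = 2400, rng_seed = 1)
  expect_error(generate_genome_pair(cfg), "configuration error")
})
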