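test_that("low-coverage screening flags by depth, breadth and both sexes", {
  pooled <- data.frame(
    contig = c("s1", "s2", "s3"), length = c(10000L, 10000L, 10000L),
    mean_depth = c(23.89, 80, 25), breadth = c(0.4832, 0.99, 0.99),
    normalized_depth = c(23.89, 80, 25) / 59.6)
  sexes <- lapply(c(m = 10, f = 10), function(base) data.frame(
    contig = pooled$contig, length = pooled$length,
    mean_depth = c(base, 40, 11), breadth = 0.9,
    normalized_depth = c(base, 40, 11) / 29.8))
  out <- screen_low_coverage(pooled, sexes)
  expect_identical(out$contig, "s1")  # s3 fails the breadth ceiling

  # flag set equals a brute-force filter over random tables
  set.seed(97)
  for (rep in 1:10) {
    n <- 30
    tab <- data.frame(contig = paste0("c", 1:n), length = 1000L,
                      mean_depth = runif(n, 0, 80),
                      breadth = runif(n, 0.3, 1))
    tab$normalized_depth <- tab$mean_depth / 40
    got <- screen_low_coverage(tab, NULL, require_both_sexes = FALSE)
    want <- tab$contig[tab$mean_depth < 30 & tab$breadth < 0.9]
    expect_identical(got$contig, want)
  }
})

test_that("unmapped-pair extraction keeps only doubly unmapped pairs", {
  reads <- data.frame(id = c("a", "b", "c"),
                      seq1 = strrep("ACGT", 10), seq2 = strrep("TGCA", 10),
                      stringsAsFactors = FALSE)
  mk <- function(id, flag) data.frame(
    qname = id, flag = flag, rname = "*", pos = 0L, mapq = 0L, cigar = "*",
    rnext = "*", pnext = 0L, tlen = 0L, seq = "*", qual = "*",
    stringsAsFactors = FALSE)
  U <- covmark:::FLAG_UNMAPPED
  aln <- alignments(rbind(
    mk("a", 0x1L + 0x40L + U), mk("a", 0x1L + 0x80L + U),   # both unmapped
    mk("b", 0x1L + 0x40L), mk("b", 0x1L + 0x80L + U),       # one mapped
    mk("c", 0x1L + 0x40L), mk("c", 0x1L + 0x80L)),          # both mapped
    c(c1 = 100L))
  out <- extract_unmapped_pairs(aln, reads)
  expect_identical(out$id, "a")
  expect_equal(attr(out, "single_end_dropouts"), 1)

  all_mapped <- alignments(rbind(mk("c", 0x1L + 0x40L), mk("c", 0x1L + 0x80L)),
                           c(c1 = 100L))
  expect_equal(nrow(extract_unmapped_pairs(all_mapped, reads)), 0)

  orphan <- alignments(mk("a", 0x1L + 0x40L + U), c(c1 = 100L))
  expect_warning(out2 <- extract_unmapped_pairs(orphan, reads), "two mates")
  expect_equal(nrow(out2), 0)
})

test_that("read filtering applies entropy and quality rules like brute force", {
  expect_equal(trinucleotide_entropy(strrep("A", 50)), 0)
  set.seed(101)
  good <- rnd_dna(150)
  expect_identical(filter_reads(c(strrep("A", 150), good)), good)

  seqs <- c(replicate(20, rnd_dna(100)), strrep("AT", 50), strrep("G", 100))
  quals <- c(replicate(20, strrep("I", 100)), strrep("I", 100),
             strrep("#", 100))
  got <- filter_reads(seqs, quals, min_mean_q = 20, entropy_min = 2)
  keep <- trinucleotide_entropy(seqs) >= 2 &
    vapply(quals, function(q) mean(utf8ToInt(q)) - 33, numeric(1)) >= 20
  expect_identical(got, seqs[keep])
})

test_that("the unitig assembler reconstructs a tiled novel sequence", {
  set.seed(103)
  novel <- rnd_dna(600)
  starts <- sample(1:(600 - 99), 180, replace = TRUE)  # ~30x
  reads <- substring(novel, starts, starts + 99)
  flip <- runif(180) < 0.5
  reads[flip] <- revcomp(reads[flip])
  ctg <- assemble_unmapped(reads, k_asm = 31, min_contig = 300,
                           min_kmer_count = 2)
  expect_equal(length(ctg), 1)
  expect_gte(nchar(ctg[[1]]), 0.95 * 600)
  expect_true(grepl(ctg[[1]], novel, fixed = TRUE) ||
              grepl(revcomp(ctg[[1]]), novel, fixed = TRUE))

  # a 250-bp reconstructable fragment falls below the length floor
  short <- rnd_dna(250)
  sreads <- substring(short, seq(1, 151, by = 2), seq(1, 151, by = 2) + 99)
  expect_equal(length(assemble_unmapped(sreads, min_contig = 300,
                                        min_kmer_count = 2)), 0)
  expect_gte(length(assemble_unmapped(sreads, min_contig = 100,
                                      min_kmer_count = 2)), 1)

  expect_equal(length(assemble_unmapped(character(0))), 0)
  expect_error(assemble_unmapped(reads, k_asm = 30), "odd")
})

test_that("every unitig is a walk of solid k-mers of its input", {
  set.seed(107)
  src <- strrep(rnd_dna(900), 2)  # an internal repeat creates real branches
  starts <- sample(1:(nchar(src) - 99), 300, replace = TRUE)
  reads <- substring(src, starts, starts + 99)
  ctg <- assemble_unmapped(reads, min_contig = 100, min_kmer_count = 2)
  solid <- oracle_kmer_count(reads, 31, 2)$kmer
  for (s in ctg)
    expect_true(all(oracle_distinct_kmers(s, 31) %in% solid))
})

test_that("reciprocal validation rejects reference copies and chimeras", {
  set.seed(109)
  ref <- c(ref = rnd_dna(5000))
  idx <- build_index(ref, w = 31)
  verbatim <- substr(ref[[1]], 1001, 1600)
  absent <- rnd_dna(600)
  chimera <- paste0(substr(absent, 1, 300), substr(ref[[1]], 2001, 2300))
  contigs <- c(verbatim = verbatim, absent = absent, chimera = chimera)
  src <- unlist(lapply(contigs, function(s)
    substring(s, seq(1, 451, by = 25), seq(1, 451, by = 25) + 149)))
  out <- reciprocal_validate(contigs, idx, unname(src))
  rep <- attr(out, "report")
  expect_identical(names(out), "absent")
  expect_equal(rep$retained, c(FALSE, TRUE, FALSE))
  expect_equal(rep$window_map_fraction[rep$contig == "verbatim"], 1)
  expect_equal(rep$window_map_fraction[rep$contig == "absent"], 0)
  expect_gt(rep$window_map_fraction[rep$contig == "chimera"], 0.1)
  # an absent contig without read support is also rejected
  no_support <- reciprocal_validate(c(absent = absent), idx,
                                    substring(verbatim, 1:10, 150:159))
  expect_equal(length(no_support), 0)
})

test_that("in-silico PCR reproduces coordinate arithmetic and the oracle", {
  set.seed(113)
  tmpl <- rnd_dna(500)
  fwd <- substr(tmpl, 101, 120)
  rev <- revcomp(substr(tmpl, 299, 318))
  amp <- insilico_pcr(primer_pair(fwd, rev), c(t = tmpl))
  expect_equal(nrow(amp), 1)
  expect_equal(amp$forward_start, 101)
  expect_equal(amp$reverse_end, 318)
  expect_equal(amp$product_length, 218)

  # 3 mismatches at the best site exceed the allowance: no amplicon
  fwd3 <- mutate_read(mutate_read(mutate_read(fwd, 1), 1), 1)
  while (sum(strsplit(fwd3, "")[[1]] != strsplit(fwd, "")[[1]]) < 3)
    fwd3 <- mutate_read(fwd3, 1)
  expect_equal(nrow(insilico_pcr(primer_pair(fwd3, rev, max_mismatches = 2),
                                 c(t = tmpl))), 0)

  expect_error(primer_pair("ACGT", rev), "15-35")
  expect_error(primer_pair(sub("A", "N", paste0(fwd, "A")), rev), "A,C,G,T")

  # exhaustive site-pair enumeration on a multi-site toy genome
  for (rep in 1:3) {
    g <- c(g1 = paste0(rnd_dna(300), fwd, rnd_dna(150),
                       substr(revcomp(fwd), 1, 20), rnd_dna(100),
                       revcomp(rev), rnd_dna(200)),
           g2 = rnd_dna(800))
    pp <- primer_pair(fwd, rev, max_mismatches = 2,
                      product_range = c(50, 2000))
    got <- insilico_pcr(pp, g)
    want <- oracle_epcr(fwd, rev, g, 2, c(50, 2000))
    expect_equal(nrow(got), nrow(want))
    if (nrow(got) > 0) {
      expect_equal(got$forward_start, want$forward_start)
      expect_equal(got$reverse_end, want$reverse_end)
      expect_equal(got$product_length, want$product_length)
    }
  }
})

test_that("recovery metrics equal brute-force interval overlap", {
  truth <- make_truth(islands = data.frame(
    contig = "c1", start = c(1000L, 5000L), end = c(3000L, 6000L),
    stringsAsFactors = FALSE))
  exact <- candidate_regions(zero_iv = data.frame(
    contig = "c1", start = 1000L, end = 3000L, length = 2000L,
    stringsAsFactors = FALSE))
  ranked <- prioritize_candidates(exact, truth)
  rec <- attr(ranked, "recovery")
  expect_equal(rec$sensitivity, 0.5)  # one of two islands, exactly
  expect_equal(rec$fdr, 0)

  none <- prioritize_candidates(candidate_regions(), truth)
  expect_equal(attr(none, "recovery")$sensitivity, 0)

  set.seed(127)
  for (rep in 1:10) {
    cand <- data.frame(contig = "c1",
                       start = sample(seq(0, 9000, 100), 6))
    cand$end <- cand$start + sample(c(200L, 800L, 1500L), 6, TRUE)
    cand$length <- cand$end - cand$start
    truth_iv <- data.frame(contig = "c1",
                           start = sample(seq(0, 9000, 500), 3))
    truth_iv$end <- truth_iv$start + 1000L
    got <- attr(prioritize_candidates(
      candidate_regions(zero_iv = cand), make_truth(islands = truth_iv)),
      "recovery")
    want <- oracle_reciprocal_hits(cand, truth_iv)
    expect_equal(got$n_truth_recovered, sum(want$truth_hit))
  }
})
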