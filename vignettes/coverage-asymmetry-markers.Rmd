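---
title: "Methods: coverage-asymmetry marker discovery on synthetic genome pairs"
author: "covmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coverage-asymmetry marker discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its methods: the model behind each
stage, the parameters that matter, what the synthetic data do and do not
emulate, and the numerical choices that were genuinely open.

## The study system the generator emulates

`sim_config()` encodes a pair of recently diverged fish-like genomes observed
through short-read resequencing of one male and one female individual of the
query species:

* **Backbone**: i.i.d. uniform A/C/G/T contigs (default 5 x 100 kb). A
  uniform random backbone is the simplest null for mapping — no repeats, no
  GC structure — so every mapping failure in the simulation is attributable
  to planted divergence, planted absence, or sequencing error.
* **Background divergence** `background_rate = 0.015`: substitutions per
  site between the two genomes outside islands, the "shallow but consistent"
  regime (~98.5% identity) in which cross-species mapping still succeeds for
  most reads.
* **Islands** (default 5 x 2 kb at `island_divergence = 0.10`): localized
  regions of elevated divergence. Substitutions pick uniformly among the
  three alternative bases (Jukes–Cantor-like symmetry; the data give no
  reason for a richer substitution model).
* **Insertions** (default 2 x 1 kb): random sequence present only in the
  query genome; truth intervals are recorded in query coordinates, islands
  in reference coordinates (0-based half-open throughout; SAM positions are
  1-based and conversions are centralized).
* **Reads**: 2 x 150 bp pairs, fragment length truncated-normal(500, 50)
  floored at the read length, uniform fragment start, random fragment
  strand, i.i.d. substitution errors at `error_rate = 0.001`, constant Q40
  qualities (base-quality modelling plays no role in any downstream
  statistic). Pairs per contig are `round(len * depth / (2 * 150))`, with
  `depth_per_individual = 40`.
* **Sex repeats**: optional female-enriched families planted as one tandem
  array per family (unit 100 bp, 300 copies by default). A single tandem
  locus is the minimal structure that produces the moderate-copy k-mer
  signature.

What the generator deliberately does **not** model: indels in the divergence
process (the downstream statistics use only position, MAPQ and
mapped/unmapped status, so the mapper is ungapped and brute-force
verifiable), real repeat landscapes, GC/coverage bias, quality-score decay,
and PCR duplicates. Passing the recovery tests therefore demonstrates that
the framework's logic is correct under its own assumptions, not that real
genomes — where repeats and assembly artifacts also produce coverage
asymmetry — would behave as cleanly.

## The mapper and its sensitivity contract

`build_index()` stores every canonical w-mer (default w = 31) of the
reference with all positions; `map_reads()` seeds at every read offset in
both orientations and extends each seeded placement ungapped across the full
read. A placement is acceptable at ≤ `max_mismatches` (default 5, i.e. ~3.3%
per-read divergence tolerance for 150-bp reads — reads from the 1.5%
background map, island and insertion reads drop). The best placement wins
(fewest mismatches; ties broken by lowest contig, position, strand), and
MAPQ is a documented three-level surrogate: 60 when the margin over the
runner-up is ≥2 mismatches (or no runner-up exists), 20 at margin 1, 0 when
tied. Multi-mapping reads are placed at the tie-broken best locus with
MAPQ 0 rather than discarded, so MAPQ-threshold sweeps have well-defined
effects.

Seed-and-extend guarantees discovery of any placement that leaves at least
one exact w-window in the read. For a 150-bp read at w = 31 this is certain
up to 3 mismatches and near-certain for random placements at 5; the
mapper/oracle equivalence suite exercises the guaranteed regime. This is the
same qualitative contract real seed mappers have, made explicit.

## Coverage statistics and the pooling argument

Depth adds 1 per reference position covered by CIGAR M (external SAM with
the full op alphabet is accepted; D/N consume reference without depth).
Breadth is the fraction of positions with depth ≥ 1 — the standard
convention; no depth floor above 1 is applied by default, though the
threshold is a parameter. Normalized depth divides each contig's mean by the
length-weighted genome mean, so the 30x pooled cutoff and the 0.4x
normalized cutoff coincide at ~80x pooled coverage.

Pooling male and female alignments is positionwise summation, and the screen
requires sub-threshold normalized depth in *each* individual as well:
because the pooled mean is the sum of the individual means, the pooled
low-depth set is always contained in the intersection of the per-individual
sets — the mechanism by which pooling collapses stochastic dropouts while
preserving genuine absence.

The exploratory sex screen computes `(male + eps) / (female + eps)` per
scaffold with `eps = 0.5` depth units (the pseudocount only needs to
stabilize near-zero denominators; any small value behaves identically) and
flags ratios ≥2 or ≤0.5, restricted to scaffolds ≥50 kb.

## Zero-coverage intervals: strict runs vs candidate merging

`zero_intervals()` returns maximal zero-depth runs at least `min_len` long
(primary default 100 bp; 500 bp for the restricted sweep view; the mean
lengths involved imply a primary floor well below 500). The operation is
strict by default. The *pipeline*, however, merges runs separated by ≤200 bp
of covered sequence before candidacy (`zero_merge_gap`, bedtools
`merge -d` style): at 10% island divergence a 150-bp read still chance-maps
with ≤5 mismatches at P ≈ 1.5e-3, so an island observed at ~80x pooled depth
is typically crossed by one or two stray placements that would otherwise
split its zero run. Merged interval length is the span end − start,
including bridged bases.

## Unmapped-read assembly and reciprocal validation

Pairs with **both** mates unmapped (the conservative reading of "pairs that
failed to align"; single-end dropouts are counted but not assembled) pass a
quality/complexity filter (mean Phred ≥20; trinucleotide Shannon entropy ≥2
bits, which removes homopolymers and dinucleotide repeats while keeping
random sequence at ~5.8 bits) and enter a canonical-k-mer de Bruijn unitig
assembler (k = 31, maximal non-branching paths, deterministic seed order,
contigs ≥300 bp kept).

Two coverage cutoffs exist deliberately. The operation's default k-mer
cutoff is 2 (drop singletons), appropriate for clean tiling input. The
pipeline uses 5: both-unmapped pairs include mates that chance-fail in
conserved flank (~3% of reads at the background divergence, i.e. ~2.5x of
stray flank coverage at 80x pooled), and a cutoff above that background
stops contigs at insertion breakpoints instead of letting them straggle
hundreds of bases into conserved sequence; it also removes coincident-error
branch k-mers that would fragment island contigs.

Reciprocal validation tiles each contig into 150-bp windows, maps them to
the cross-species reference at a permissive 10 mismatches, and retains the
contig only if ≤10% of windows map *and* back-mapped source-read mean depth
is ≥5x. The window fraction is computed over interior windows (first and
last tile excluded when a contig has ≥3): a contig assembled from
both-unmapped pairs necessarily carries up to a read length of flanking
homology at each end, because junction-spanning reads are unmapped; terminal
homology is therefore expected for genuine insertion contigs, whereas a
half-insertion/half-backbone chimera still fails because its backbone half
occupies interior windows.

## Recovery scoring

With truth available, sensitivity is the fraction of planted features
recovered by at least one candidate at ≥50% reciprocal overlap — intervals
against island intervals via interval arithmetic; assembled contigs against
feature sequences via reciprocal 31-mer containment, where the candidate
side is matched against the feature plus ±300 bp of breakpoint flank (the
sequence context a junction contig legitimately extends into) and the
feature side must be ≥50% covered by the candidate. The false-discovery
proportion is candidate-centric: a candidate counts as true when ≥50% of it
lies within a planted feature. A 600-bp interval wholly inside a 2-kb island
is not a false discovery even though it fails the reciprocal test that
sensitivity uses; the two metrics answer different questions.

## Sex-specific k-mers and the copy-number window

Counting is canonical (lexicographic minimum of k-mer and reverse
complement), N-free, with entries below `min_count` dropped; two presets are
carried: exploratory (k = 21, min 3) and stringent (k = 31, min ≥20).
Sex-specific sets are plain key subtraction; the summary reports the
partition counts, the shared fraction of the union, and the specific-count
ratio.

The moderate-copy window (200–499) applies to *occurrence counts in the read
database*, so window membership is governed by the product of genomic copy
number and sequencing depth: a family with `c` genomic copies appears at
about `c * d * (L - k + 1) / L` occurrences at per-base depth `d`. The
k-mer screening simulations therefore sample reads at ~1.25x per individual,
which places a 300-copy family at ~300 expected occurrences — inside the
window — while backbone and error k-mers stay far below the stringent
min-count of 20. At 40x the same family would sit near 10,000 occurrences
and the window would instead select ~6–14-copy families; the screening depth
is a calibration choice of the synthetic study, fixed once from this
arithmetic. A side effect worth knowing: at 1.25x the male stringent table
is nearly empty, so the top-5000 crosscheck (which returns 0 present) is a
structural rather than statistical confirmation in the simulation.

## Sketching, Mash distance and ordination

Sketches keep the s smallest distinct values (default s = 500,000, k = 21)
of a seeded splitmix64-style hash of each canonical k-mer, truncated to 53
bits so values are exactly representable as R doubles (collision probability
at s = 5e5 is ~1e-5 and affects the Jaccard estimate negligibly). The hash
seed (default 42) is recorded in sketch files; sketches are only comparable
at equal k, s and seed.

The Jaccard index j is estimated from the bottom-s of the merged union
(the merged-sketch estimator used by the published MinHash genome-distance
method), and `D = -(1/k) ln(2j/(1+j))`, with D = 0 at j = 1 and capped at 1
at j = 0; similarity is 1 − D. Under i.i.d. substitutions at rate r the
expected shared k-mer fraction is (1−r)^k, giving D ≈ r; at r = 0.015 the
estimator lands on 0.0151–0.0152 with s = 1e5 on megabase genomes, matching
the divergence regime of interest. When s exceeds the total distinct k-mer
count the estimate is exact.

PCoA double-centers the squared distances (B = −½ J D² J, J = I − 1/n) and
eigendecomposes B. Axes with eigenvalues above a relative tolerance of 1e-9
are retained; coordinates scale eigenvectors by the square roots of their
eigenvalues; variance explained divides by the positive-eigenvalue total;
negative eigenvalues (non-Euclidean distances) are reported but excluded
from coordinates. Significance values for Mash distances are not reported:
the null model requires a genome-size estimate the analysis does not carry.

## Problem sizes and determinism

The packaged simulations use 500-kb genome pairs at 40x per individual for
recovery (10 replicates), megabase pairs for Mash calibration (5 pairs,
s = 1e5), and a 150-kb genome for the sex k-mer screen — sizes at which
every stage's behaviour is statistically unambiguous while a full validation
run stays in the minutes range on a single core. All randomness flows from
`rng_seed` (readsets derive their streams from seed+1/seed+2 so the sexes
differ but reproduce); identical configurations give byte-identical genomes,
reads, truth tables and pipeline reports. Null runs with zero planted
divergence produce no candidates at all; null runs with background
divergence but nothing planted produce no flagged contigs and no validated
unmapped contigs.

## Known limitations

* Ungapped mapping cannot place reads across indels; real structural
  variation between genuine genomes would require a gapped aligner, for
  which the SAM interfaces accept external alignments interchangeably.
* The k-mer machinery packs k-mers into 64-bit words, so k ≤ 31; both
  presets fit, but longer k would need a wider encoding.
* The seed index lives in an external pointer and must be rebuilt rather
  than serialized.
* Overall read mapping rates are a property of the mapper's stringency
  surrogate, not a reproduction of any particular aligner's defaults; the
  package reports them but anchors its claims on planted-truth recovery.
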