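---
title: "Methods: depth-capped resampling and ensemble calling for capture data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: depth-capped resampling and ensemble calling for capture data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Target-enrichment long-read sequencing (hybridization capture of exon-sized
regions followed by PCR and nanopore sequencing) delivers deep but *uneven*
coverage: per-region capture and amplification efficiency varies by an
order of magnitude, so a caller sees some positions at 500× and others at
20× in the same run. Long reads carry a high per-base error rate (around
Q11, i.e. ~8% expected error), so genotypes must be inferred from many
noisy observations; but models tuned on whole-genome data degrade at depths
far above their training range, and global downsampling throws away
evidence exactly where it is scarcest. `capcall` implements per-position
depth capping with ensemble averaging, plus the QC and benchmarking around
it, and a simulator that generates the whole data ecosystem so every stage
is testable hermetically.

# By-position resampling

At a candidate position, after keeping only primary alignments with
mapping quality ≥ `min_mapq` (default 60), let $d$ be the number of
observations (matched bases, insertions attached to their anchor base,
deletion gaps) and $m$ = `max_depth` (default 100), $k$ =
`max_partitions` (default 5), $q_0$ = `base_q_cutoff` (default Phred 5).

* $d \le m$: the column passes through as a single partition, *including*
  observations below $q_0$. Low-depth positions lose nothing.
* $d > m$: observations with quality $< q_0$ are dropped, leaving $d'$.
  If $d' \le m$, the filtered pool is the single partition. Otherwise
  $n = \min(k, \lceil d'/m \rceil)$ partitions are built; when
  $d' > n\,m$ only the $n\,m$ highest-quality observations are retained
  (ties broken by ascending read identifier, for determinism), which
  preferentially keeps high-quality evidence. The retained pool is
  shuffled (seeded) and chunked into partitions of exactly $m$; a short
  final chunk is refilled by sampling, without replacement, observations
  already assigned elsewhere — a read can appear in two partitions but
  never twice in one.

Partitioning is independent per column: a read may land in partition 1 at
one position and partition 3 at the next. Partitions are meant to be
exchangeable replicates of the local evidence, which is why retention is a
quality *cutoff* plus top-$n\,m$ cap followed by random chunking — sorting
observations into partitions by quality would stratify the replicates and
bias the ensemble. The per-column shuffle seed is derived from the
configured seed and the column's coordinates, so identical inputs give
identical partitions while neighbouring columns shuffle independently.

# Probability model and ensemble

Every (partition × model) pair produces four distributions
(`task_probabilities()`):

* `gt21`: 21 unordered genotypes over {A, C, G, T, I, D}, where I and D
  are insertion/deletion pseudo-alleles;
* `zygosity`: hom-ref, hom-alt, het-alt, het-multi;
* `len1`, `len2`: indel length per haplotype, binned −16…+16 with the
  extremes open (33 bins); `len1` carries the smaller of the genotype's
  two allele lengths, `len2` the larger.

The class layouts live in one constants table so an external model (e.g. a
trained network exposed through R) can be plugged in via
`probability_model()`; the package treats any conforming model
interchangeably.

The bundled `naive_model()` is a transparent diploid-likelihood model, not
a trained network, and the package makes no claim of matching a trained
caller's accuracy on real data. For genotype $g = \{a_1, a_2\}$ each
observation contributes
$\tfrac12 p(o|a_1) + \tfrac12 p(o|a_2)$ with $p(o|a) = 1-\varepsilon$ if
$o$ supports $a$ and $\varepsilon/3$ otherwise; $\varepsilon$ is the
observation's Phred error probability floored at `error_rate_prior` and
capped at 0.75 (a quality string cannot promise more noise than random).
The prior spreads `het_prior` uniformly over the active heterozygous
classes and the remainder over the active homozygous classes. The four
bases are always active; I/D become active only when supporting
observations exist, since an indel allele could not otherwise be realized
as a concrete sequence. The posterior is reported as `gt21` and
marginalized into the other tasks; non-indel genotypes put their length
mass on 0.

The ensemble step is an element-wise arithmetic mean of each task vector
over all partitions and models. Averaging before any thresholding means a
single aggregated decision is made per position (partitions never cast
votes independently).

**Decision rule** (`decide()`): zygosity argmax `hom_ref` → reference call.
Otherwise the `gt21` argmax fixes the allele pair; insertion sequences and
deletion lengths are realized as the most frequent event of the length
given by the length-task argmax among the column's observations. When
tasks disagree, zygosity wins on hom-ref-versus-variant, the genotype task
wins on allele identity, the genotype string comes from zygosity
(hom-alt → `1/1`, het-alt → `0/1`, het-multi → `1/2`), and the record is
flagged `TASK_CONFLICT` — conflicts are resolved deterministically but
kept visible. `QUAL` is $-10\log_{10}(1-p)$ with $p$ the smallest argmax
probability over the consulted tasks (length tasks only consulted for
indel alleles), capped at 99.

**Candidate selection** is not specified by the resampling/ensemble design
itself, so the caller uses a configurable rule: a target position becomes a
candidate when non-reference observations (mismatches + deletion gaps +
insertion anchors) reach both `min_alt_fraction` (default 0.125) and
`min_alt_reads` (default 4). Columns over reference N are never candidates.

**Indel conventions.** Insertions attach to the anchor base before the
inserted sequence and outrank the anchor's base observation (one
observation per read per column). A deletion yields observations at every
deleted position, carrying the *remaining* deleted length; the emitted VCF
record is anchored one base to the left, `REF` spanning the deleted bases.
Candidate positions interior to an already-emitted deletion are suppressed,
so one deletion event produces exactly one record rather than a ladder of
shifted representations. A het-multi pair mixing a deletion with another
allele cannot share a single VCF anchor; the better-supported allele is
kept and the record flagged.

# Capture QC

* **Depth** counts only matched (reference-consuming, query-consuming)
  bases — deletion gaps and clips add nothing — matching the pileup
  semantics used for calling.
* **Uniformity** has no single standard formula; the package uses the
  common capture definition *percent of target bases with DoC ≥ 0.2 × mean
  on-target DoC*, with the factor configurable
  (`coverage_summary(uniformity_factor=)`).
* **Flanked-site coverage** (`site_coverage()`) evaluates the union of
  `[site − flank, site + flank]` windows intersected with profiled bases;
  a site whose entire window lies outside the profile is reported
  separately and counted below threshold.
* **Uncovered regions** are those whose maximum count of distinct
  overlapping reads (on aligned spans, so deletion gaps still count as
  overlap) falls below `min_reads`; `min_reads = 1` is the literal "no
  read covered". GC content is annotated from the reference (N bases
  excluded from the denominator) because capture dropout is
  characteristically GC-driven.
* **Read quality** averages error *probabilities*, not Phred values,
  before converting back to Phred — correct on the probability scale.
  N50 is the largest L such that reads ≥ L hold at least half of all bases.

# Benchmarking

Truth and calls are decomposed to single-alt records, normalized (shared
suffix then prefix trimmed keeping one base; indels shifted left while the
reference context permits), restricted to confident ∩ target regions by
record position, and matched exactly on (chrom, pos, ref, alt, unordered
genotype). A genotype error at a true site is one FP plus one FN. This is
deliberately simpler than haplotype-resolution comparison engines: it is
deterministic, dependency-free, and exact matching after normalization is
adequate for synthetic data with non-overlapping planted variants.
Zero-denominator metrics are reported as 0 with an explicit flag, never
NaN.

# The simulator

`simulate_capture()` emulates an ONT-style capture library:

| parameter | default | rationale |
|---|---|---|
| `read_length_mean` | 1000 bp | capture libraries size-selected around 1 kb |
| `read_length_sd` | 250 bp | wide long-read length spread (N50 well above the mean) |
| `region_length_mean` | 164 bp | average exon size |
| `mean_read_phred` | Q11 | typical long-read per-base accuracy |
| `mean_depth` | 120× | one-flowcell medical-exome scale |
| `capture_bias_sigma` | 0.6 | log-normal per-region depth multiplier |
| `sub_error_rate` / `indel_error_rate` | 5% / 2% | raw long-read error profile |
| `snv_rate` / `indel_rate` | 0.0061 / 0.00102 per base | ≈300 SNVs + 50 indels on the default panel |
| `het_fraction` | 0.5 | half the planted variants heterozygous |
| `low_mapq_fraction` / `secondary_fraction` | 4% / 2% | a small non-uniquely-mapped read class so MAPQ/primary filters are exercised |

Design choices worth knowing:

* Reads are emitted **pre-aligned at their true positions** with CIGARs
  reflecting planted indels and injected errors; FASTQ is also written for
  users who want to run a real aligner. This keeps tests hermetic — no
  aligner in the loop.
* Fragment midpoints are uniform over the region extended by half the
  read's own length on each side: expected coverage is flat across the
  region and tapers over the flanks, reproducing the broad
  margin/splice-site coverage of capture long reads. Region read counts
  are Poisson with mean $D_r (L + \bar R)/\bar R$, $D_r$ the region's
  biased depth, so realized mean depth converges to
  `mean_depth`·$e^{\sigma^2/2}$ (log-normal mean) for isolated regions;
  closely spaced regions additionally receive each other's flank coverage,
  as real adjacent exons do.
* Error injection order is substitutions then 1-bp indels; erroneous bases
  draw their qualities from the same distribution as correct ones (errors
  are not quality-flagged). The error process is deliberately neutral:
  no homopolymer-specific error model, no chimeric reads, no
  signal-level simulation.
* Per-read quality: a read-level mean Phred is drawn Normal(`mean_read_phred`, 3)
  truncated at ≥ 3 (mirroring a basecaller minimum q-score filter), then
  per-base qualities jitter around it with sd 3. Jitter on the Phred scale
  lowers the probability-scale mean, so the per-base mean is shifted up by
  $10(\sigma \ln 10/10)^2/(2\ln 10) \approx 1.04$ dB to make the per-read
  mean *error probability* land at the drawn Phred mean.
* Variants are planted with ≥ 15 bp spacing (so planted events never
  overlap and exact matching is well-defined), uniformly inside target
  regions; variant counts are Poisson draws at the configured rates over
  covered bases. All reads are forward-strand; strand does not enter the
  pileup or the model.

What passing tests on this simulator do **not** show: performance on real
basecaller error structure (homopolymer indels, strand bias, systematic
miscalls), on reference contexts with repeats or segmental duplication, or
with a trained network as the probability model. The simulator validates
the *machinery* — resampling, averaging, decision, QC, benchmarking — not
real-data accuracy claims.

# Numerical and scale choices

* Standard validation fixture: 200 kb reference, 300 regions, ~350 planted
  variants, 120× depth, two-model ensemble (`default_models()`: the
  diploid-likelihood model under two prior settings, ε-floor 0.05 /
  het-prior 0.5 and ε-floor 0.10 / het-prior 1/3). It runs in a few
  minutes on one CPU; the oracle-based suites (partition invariants on
  1000 random columns, 10,000-set averaging and decision-table checks)
  each run in well under a minute.
* Probability work is done in log space and normalized by the max before
  exponentiation; task vectors must sum to 1 within 1e−6.
* Degenerate inputs: empty columns and empty read sets are errors at the
  operations that need evidence (`partition_column`, `naive_model`,
  `read_stats`); zero-candidate target sets return empty call sets; empty
  truth or call sets benchmark to flagged zero metrics.
* Ties: equal-quality retention breaks by ascending read id; equal-support
  alt alleles by allele rank (A < C < G < T < I < D); equal-frequency
  insertion sequences lexicographically; equal-frequency indel lengths by
  the smaller length.
* Seeds: every stage derives its seed from one configured integer via a
  modular hash kept below 2³¹, so a single `--seed` reproduces all
  artifacts byte-for-byte.

# Limitations

* The bundled model is a likelihood stand-in; plugging in a trained model
  is supported but not provided.
* Multi-allelic support is limited to two alt alleles (het-multi), and a
  deletion cannot share a record with another allele type.
* No haplotype phasing, no structural variants, no CRAM/tabix, single
  sample per VCF.
* Benchmarking is exact-match after normalization, not haplotype-aware;
  complex representations that differ by more than one left-shiftable
  indel will not be reconciled.
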