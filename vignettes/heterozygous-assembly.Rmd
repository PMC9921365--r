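---
title: "Heterozygosity-aware assembly: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heterozygosity-aware assembly: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it
implements: the models behind each stage, the tunable parameters with
their defaults and units, what the synthetic-data generator does and
does not emulate, the numerical choices that were genuinely open, and
the known limitations.

## The problem

A diploid genome with ~1% per-base heterozygosity diverges enough
between its two haplotypes that a de Bruijn assembler reconstructs many
regions twice, once per haplotype.  The assembly then exceeds the
haploid genome size by the heterozygous fraction, read depth on those
duplicated contigs halves (each attracts only one haplotype's reads),
and scaffolding links become ambiguous.  The pipeline here removes the
duplication at the contig stage using that depth signature plus
read-pair geometry, then scaffolds and gap-fills the haploid set.

## k-mer spectrum model (`count_kmer_spectrum`, `estimate_genome`)

K-mers are counted canonically (lexicographic minimum of k-mer and
reverse complement; k must be odd so the two can never tie).  The
default k = 19 balances specificity against the (L−k+1)/L depth
dilution at L = 100 bp reads.

On the multiplicity histogram, smoothed with a centred 3-bin moving
average:

* **error cutoff** — the first local minimum above multiplicity 1.
  Sequencing errors create mostly-novel k-mers at multiplicity ~1-2; a
  spectrum that rises from the start has no error component and the
  cutoff is 1.  Plateau ties resolve toward lower multiplicity.
* **peaks** — smoothed local maxima above the cutoff whose height is at
  least `major_peak_frac` (default 0.2) of the tallest; each is refined
  to the raw-histogram mode within ±1 bin.  The homozygous peak is the
  highest-multiplicity major peak; a heterozygous peak is accepted
  within [0.35, 0.65] of it.
* **genome size** — `sum(m * hist[m], m >= cutoff)` divided by the
  homozygous peak depth.  The integer mode quantises this estimate by
  roughly 1/depth (±2% at 50×), so the divisor actually used is the
  histogram centroid within ±20% of the mode — a fractional peak depth
  reported as `hom_peak_refined` alongside the modal
  `hom_peak_depth`.
* **heterozygosity** — distinct k-mers between the cutoff and the
  midpoint of the two peaks are haplotype-unique (count *h*; each
  heterozygous locus contributes from both haplotypes, hence *h*/2 loci
  per haploid genome); those from the midpoint up to 1.5× the
  homozygous peak are shared (count *d*).  With
  `a = (h/2)/(h/2 + d)`, per-base heterozygosity is
  `r = 1 − (1 − a)^(1/k)`, inverting the fact that a position's k-mer
  is haplotype-unique exactly when it spans ≥ 1 SNP.  The upper bound
  at 1.5× the peak keeps two-copy repeat k-mers out of *d*; the simple
  two-window attribution is used in place of a full mixture-model fit —
  closed-form, testable, and it recovers simulated rates (the test
  suite checks 1% heterozygosity to within 0.25 percentage points).
  This attribution assumes SNP-dominated divergence, which is why the
  simulator realises heterozygosity as SNPs by default.

Known limitation: on spectra whose repeat peak rivals the homozygous
peak in height (repeat fraction ≫ 40%), the highest-multiplicity major
peak may be a repeat peak; `major_peak_frac` is exposed for such data.

## Unitigs and depth (`build_unitigs`, `compute_contig_depth`)

Unitigs are maximal non-branching paths over canonical k-mers with
count ≥ `min_kmer_count` (default 3, consistent with the spectrum error
cutoff at ~60× coverage; use 1 for error-free data, where even terminal
k-mers observed once are real).  Tips and bubbles are **not** popped:
each SNP yields a pair of parallel bubble-arm unitigs, and haplotype
duplication is resolved later at the contig stage, so the graph stage
must preserve both paths.  Unitigs are emitted in canonical orientation
and the set is invariant to read order (iteration over nodes is sorted,
not hash-ordered).

Read placement uses exact canonical 31-mer seeding plus ungapped
extension, scored by matching bases over the read/reference overlap
(clipped at reference ends; defaults `min_identity` 0.9,
`min_overlap` 31 bp).  This is sufficient for substitution error rates
up to ~1% at desk scale; SAM from an external aligner can be converted
with `sam_to_placements()` instead.  Depth is aligned bases of
*uniquely-best* placed reads (strictly better than the second-best
candidate) divided by contig length; ties are excluded and reported as
`multi_mass`, because ambiguous reads would inflate repeat depth.

Coordinates follow R's 1-based inclusive convention throughout the R
interface; the compiled kernels work 0-based and convert at the
boundary, as does the SAM importer.

## Bubble collapse (`classify_heterozygous` … `collapse_bubbles`)

* **Classification** is strict `depth < threshold`.  The portable
  default is `auto_ratio` 0.75 × homozygous peak (the midpoint between
  the 1× and 0.5× depth populations, equivalent to an absolute 60 at an
  80× peak); an absolute `depth_threshold` reproduces fixed published
  rules.
* **Links** require both mates uniquely placed on different contigs and
  are stratified by implied relative orientation — pairs implying
  different orientations never merge.  An edge needs ≥ `min_support`
  (default 3) pairs.  Gap estimates derive from insert geometry
  (`insert_mean − d_a − d_b`); their SD is floored at
  `insert_sd/sqrt(support)`.  A pair is discordant when a mate sits
  further than `insert_mean + 3·insert_sd` from the implied contig end,
  or when the implied overlap exceeds
  `read_length + 3·insert_sd` — the extra insert-noise allowance
  matters: cutting at exactly `−read_length` truncates the upper insert
  tail and biases gap means upward by ~`0.5·insert_sd`.
* **Clustering**: two heterozygous contigs co-cluster iff they link to
  a shared flank with identical orientation (same flank end, same
  het-contig end) and their gap intervals (mean ± 3 SD) overlap, for
  every shared flank; when a contig has several links to one flank the
  best-supported one is its evidence.  Clusters are connected
  components, so transitive chains are allowed; components larger than
  two (repeat-confounded bubbles) are flagged `multi_member` rather
  than split, since only one member will be kept anyway.  Sequence
  identity between members (`bubble_identity()`) is reported for review
  but never required — the criterion is purely positional.
* **Collapse** keeps the longest member per cluster; ties fall back to
  higher depth, then lexicographically smaller id, so results are
  deterministic.  Collapse can only shrink the assembly, the removal
  report maps every removed contig to exactly one retained partner, and
  re-running on the collapsed output removes nothing (surviving
  members have no remaining partner to cluster with).

## Scaffolding and gap closing

* **Masking**: a contig is masked only when *both* high-depth
  (> `high_depth_ratio` × homozygous peak; default 1.75, between 1×
  unique and 2× two-copy — the conjunction is deliberate, depth alone
  flags clean two-copy repeats that scaffold fine) *and* conflicting —
  ≥ 2 neighbours at one end whose occupancy intervals cannot coexist.
* **Hierarchical joins**: libraries ascending by insert size; each
  round maps that library to the *current* scaffold renderings and
  joins ends greedily by support (ties on support at an end leave it
  unjoined and logged as ambiguous).  Later libraries can only join,
  never break, earlier joins; processing long inserts first instead
  lets them bridge across skipped neighbours, which is the regression
  the test suite guards against.  Joins are locally greedy rather than
  globally optimal — deterministic and faithful to the staged design.
* **Rendering** emits unfilled gaps as N runs of
  `max(1, round(gap))`; negative estimates render as a single N and
  are written as AGP `U` gaps (`N` for positive estimates).
* **Gap closing** pools reads of pairs anchored within one insert
  length of a gap, walks inward from both flanks while exactly one
  k-mer extension (k = 31) has ≥ `min_count` (default 2) read support,
  and accepts a fill only when a walk reaches the opposite flank's
  first k−1 bases or the two walks overlap exactly over ≥ k−1 bases.
  Bases outside N runs are never modified; iteration stops when a full
  pass closes nothing.

## The synthetic-data generator

`simulate_diploid_genome()` emulates the study subject: a diploid
genome with tunable per-base heterozygosity (default 0.012, the regime
of highly heterozygous marine invertebrates), optional dispersed
repeats (near-identical copies of one sampled unit at 1% internal
divergence — enough to break unitigs, not enough to merge copies), and
optionally heterozygosity concentrated into blocks
(`het_block_length`, `het_block_fraction`) separated by runs of
homozygosity, the mosaic real outbred genomes show; the genome-wide
rate is preserved either way.  Variants are SNPs by default because the
spectrum model assumes SNP-dominated divergence; `indel_fraction`
enables 1-10 bp indels (used by the collapse tests to create
unequal-length haplotype pairs).  Repeat settings dense enough to leave
no 64 bp unique anchor between copies are rejected outright rather than
silently clamped.

`simulate_reads()` draws fragments uniformly from the two haplotypes,
Normal insert sizes truncated at 2×read length, innie (paired-end) or
outie (mate-pair) orientation, uniform substitution errors, and
constant Phred-35 base qualities — quality modelling is irrelevant to
the methods under test.  Read names carry provenance as
`id:hap:pos:strand` (haplotype, 1-based fragment start, fragment
strand), which the truth evaluators parse.
`fragment_into_contigs()` converts a truth genome into the contig
fixture with labelled haplotype pairs that lets collapse be tested in
isolation from assembly quality.

What passing tests therefore show: the depth/orientation/distance rules
recover haplotype structure when coverage is uniform, errors are
substitutions, inserts are Normal and repeats are near-identical.  What
they do not show: robustness to GC-biased coverage, indel-rich
platforms, chimeric pairs, or contamination — none of which the
generator emulates.

## Problem sizes

The test suite and the acceptance script run, per stage: 500 kb diploid
genomes at 60× for spectrum recovery; 200 kb genomes for collapse
(~160 contigs) and scaffolding (~40 contigs, 2/5/10 kb mate-pair
libraries at 20×); 120 kb with 22 gaps of 200-400 bp for gap closing.
These sizes give every estimator hundreds of independent events while
keeping a full run in the minutes range on one core; all rates of
interest are scale-free, and the pipeline's kernels are linear in read
count.

## Other design decisions

* Tie-breaks are documented and deterministic everywhere (collapse
  retention order; longest-transcript selection by exonic bp, then
  lexicographic transcript id; spectrum plateau ties toward lower
  multiplicity).
* `intron_exon_accounting()` uses the longest transcript per gene and
  rejects transcripts with overlapping exons instead of guessing a
  resolution.
* The size~repeat regression reports R² at full precision and computes
  its p from the exact t transform of the correlation; with four
  species (df = 2) this has the closed form
  `P = 1 − t/sqrt(2 + t²)`, which the tests use as an independent
  oracle.
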