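# hetasm — heterozygosity-aware draft genome assembly at desk scale

Short-read assemblies of highly heterozygous diploid genomes (marine
invertebrates routinely exceed 1% per-base heterozygosity) suffer a
characteristic failure: the two haplotypes of divergent regions assemble
into *separate* contigs, inflating the assembly far beyond the haploid
genome size and breaking downstream scaffolding.  The classic remedy,
used for many invertebrate draft genomes, is a depth-aware pipeline:

1. **k-mer spectrum estimation.**  From the multiplicity histogram of
   canonical k-mers (k = 19), the error cutoff is the first local
   minimum above multiplicity 1, the homozygous peak sits at the k-mer
   depth *c*, and a heterozygous peak at ≈ *c*/2.  Genome size is
   `sum(m · hist[m], m ≥ cutoff) / c`.  With *h* haplotype-unique and
   *d* shared distinct k-mers, the fraction of k-mers spanning a SNP is
   `a = (h/2) / (h/2 + d)` and per-base heterozygosity is
   `r = 1 − (1 − a)^(1/k)`.
2. **Unitigs and depth.**  De Bruijn unitigs (bubbles deliberately not
   popped), then per-contig depth from uniquely-best-placed reads.
3. **Bubble collapse.**  Contigs with depth *below a threshold* (the
   half-depth signature; threshold 0.75 × homozygous peak, or an
   absolute value) are heterozygous candidates; read-pair links with ≥ 3
   supporting pairs, stratified by orientation, cluster them into
   bubbles when they attach to the same flanks with consistent
   orientation and distance; each bubble keeps only its longest member.
4. **Scaffolding.**  Duplicated contigs (high depth *and* conflicting
   connections) are masked; mate-pair libraries are applied in
   *ascending* insert-size order, each round greedily joining scaffold
   ends with ≥ 3 concordant pairs.
5. **Gap closing.**  Reads whose mates anchor next to a gap feed a
   flank-anchored greedy k-mer walk from both sides; a gap is replaced
   only when the walks meet exactly (≥ k−1 base overlap).
6. **QC and comparative statistics.**  N50/N90, unambiguous-read and
   transcript remapping rates, and the ordinary least-squares regression
   of assembled genome size (Mb) on repeat content (%) across species,
   with the p-value from `t = r · sqrt((n−2)/(1−r²))` at n−2 degrees of
   freedom.

Every stage is validated against ground truth from the built-in diploid
genome and read simulator, so the package doubles as a test bed for
heterozygosity-aware assembly heuristics.

## Worked example

Simulate a 200 kb diploid genome at 1.2% heterozygosity concentrated in
2 kb blocks, sequence it to 60×, estimate its parameters from the k-mer
spectrum, and collapse the haplotype bubbles:

```r
library(hetasm)

truth <- simulate_diploid_genome(200000, het_rate = 0.012,
                                 het_block_length = 2000,
                                 het_block_fraction = 0.4, seed = 42)
#> <diploid_truth> 200000 bp haploid, 2392 variants (1.196% het), 0 repeat copies
reads <- simulate_reads(truth, library_spec(500, 50, 100), coverage = 60,
                        seed = 43)
est <- estimate_genome(count_kmer_spectrum(reads, k = 19),
                       read_length = 100)
est
#> <genome_estimate> size 203119 bp, heterozygosity 1.110%
#>   hom peak 48x, het peak 25x, error cutoff 1
```

The estimate recovers the haploid size within 2% and the realised
heterozygosity (1.196%) within 0.1 percentage points; the homozygous
k-mer peak at 48× is 60× base coverage diluted by the (L−k+1)/L edge
factor, with the heterozygous peak at half that.

```r
contigs <- compute_contig_depth(
  fragment_into_contigs(truth, min_len = 800, max_len = 2000, seed = 44),
  reads)
#> <contig_set> 164 contigs, 280000 bp total, N50 2000 bp, median depth 53.8
#>   truth labels: het_pair=80, homozygous=84
flagged <- classify_heterozygous(contigs, auto_ratio = 0.75,
                                 estimate = est)
graph <- build_link_graph(flagged, reads, min_support = 3)
clusters <- cluster_bubbles(graph)
#> <bubble_clusters> 40 clusters (0 multi-member)
collapsed <- collapse_bubbles(flagged, clusters)
collapsed$contigs
#> <contig_set> 124 contigs, 200000 bp total, N50 2000 bp, median depth 57.3
```

The 80 haplotype-pair contigs (at ~half depth, 280 kb total with
duplication) collapse to one contig per locus: exactly the 200 kb
haploid genome, with all 84 homozygous contigs untouched.  Scaffolding
and gap closing continue from there (`hierarchical_scaffold()`,
`close_gaps()`, `render_scaffolds()`, `write_agp()`).

The comparative regression across the four packaged tubeworm genome
summaries:

```r
fit_size_repeat_regression(tubeworm_genome_table())
#> <size_repeat_fit> n=4: size = -73.08 + 20.90 * repeat%  (R2 = 0.9896, P = 0.0052)
```

A thin CLI over the same functions ships in `inst/scripts/hetasm`
(subcommands `simulate`, `kmer`, `stats`, `regress`, `introns`).

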