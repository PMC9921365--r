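#' Build unitigs from short-insert reads via a de Bruijn graph
#'
#' Nodes are canonical k-mers observed at least `min_kmer_count` times;
#' unitigs are maximal non-branching paths.  Tips and bubbles are *not*
#' popped: in a heterozygous genome each SNP produces a pair of parallel
#' bubble-arm unitigs, and haplotype duplication is removed later at the
#' contig stage ([collapse_bubbles()]), so the graph stage must preserve
#' both haplotype paths.
#'
#' @param reads Character vector of reads, a `read_pairs` object, a list
#'   of either, or FASTQ path(s).
#' @param k Odd k-mer size, 11-31 (default 31).
#' @param min_kmer_count Minimum k-mer multiplicity to enter the graph
#'   (default 3, suppressing sequencing-error k-mers).
#' @return A [contig_set] of unitigs (each reported in its
#'   lexicographically canonical orientation, longest first).
#' @export
build_unitigs <- function(reads, k = 31L, min_kmer_count = 3L) {
  check_k(k)
  stopifnot(min_kmer_count >= 1)
  reads <- as_read_vector(reads)
  seqs <- if (length(reads) == 0) character(0) else
    cpp_build_unitigs(toupper(unname(reads)), as.integer(k),
                      as.integer(min_kmer_count))
  if (length(seqs) == 0) {
    warning("no k-mer passed min_kmer_count; returning an empty contig set")
    return(contig_set(character(0)))
  }
  seqs <- canonical_seq(seqs)
  seqs <- seqs[order(-nchar(seqs), seqs)]
  out <- contig_set(stats::setNames(seqs, sprintf("utg%06d", seq_along(seqs))))
  attr(out, "k") <- as.integer(k)
  attr(out, "min_kmer_count") <- as.integer(min_kmer_count)
  out
}

#' Compute per-contig read depth from unique placements
#'
#' Depth is the total number of aligned bases of uniquely-best-placed
#' reads divided by contig length.  Reads with tied best placements are
#' excluded -- they would inflate repeat depth ambiguously -- and their
#' aligned bases are recorded separately as `multi_mass`.  The halving of
#' this depth on haplotype-specific contigs is the signal
#' [classify_heterozygous()] exploits.
#'
#' @param contigs A [contig_set].
#' @param reads Reads in any form [build_unitigs()] accepts, or a
#'   placement data frame from [map_reads()]/[sam_to_placements()].
#' @param seed_k,seed_step,min_identity,min_overlap Passed to
#'   [map_reads()].
#' @return `contigs` with `depth` and `multi_mass` filled in.
#' @export
compute_contig_depth <- function(contigs, reads, seed_k = 31L,
                                 seed_step = 20L, min_identity = 0.9,
                                 min_overlap = 31L) {
  stopifnot(inherits(contigs, "contig_set"), nrow(contigs) > 0)
  pl <- if (is.data.frame(reads)) reads else
    map_reads(contigs, as_read_vector(reads), seed_k = seed_k,
              seed_step = seed_step, min_identity = min_identity,
              min_overlap = min_overlap)
  hit <- pl[!is.na(pl$ref), , drop = FALSE]
  bases <- hit$ref_end - hit$ref_start + 1L
  uniq <- rowsum(bases[hit$unique], hit$ref[hit$unique])
  multi <- rowsum(bases[!hit$unique], hit$ref[!hit$unique])
  contigs$depth <- 0
  contigs$multi_mass <- 0
  i <- match(rownames(uniq), contigs$id)
  contigs$depth[i] <- uniq[, 1] / contigs$length[i]
  j <- match(rownames(multi), contigs$id)
  contigs$multi_mass[j] <- multi[, 1] / contigs$length[j]
  contigs
}

check_k <- function(k) {
  if (k %% 2 == 0) stop("k must be odd (canonicalization is ambiguous ",
                        "for even k)")
  if (k < 11 || k > 31) stop("k must lie in [11, 31]")
  invisible(TRUE)
}
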