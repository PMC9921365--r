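n50 <- function(lens, frac = 0.5) {
  lens <- sort(as.numeric(lens), decreasing = TRUE)
  lens[which(cumsum(lens) >= frac * sum(lens))[1]]
}

#' Assembly summary statistics
#'
#' N50 is the length of the sequence at which the cumulative length
#' (sequences sorted descending) first reaches half of the total; N90
#' likewise at 90%.  N runs are excluded from the GC denominator.
#'
#' @param sequences A [contig_set], named character vector, rendered
#'   scaffolds, or a FASTA path.
#' @return An `assembly_stats` list: `total_length`, `n_sequences`,
#'   `N50`, `N90`, `max_length`, `min_length`, `GC`, `N_bases`.
#' @examples
#' assembly_stats(c(a = "ACGT", b = "GGGGCCCC"))$N50
#' @export
assembly_stats <- function(sequences) {
  if (inherits(sequences, "contig_set"))
    sequences <- stats::setNames(sequences$seq, sequences$id)
  if (length(sequences) == 1 && !grepl("^[ACGTNacgtn]*$", sequences) &&
      file.exists(sequences))
    sequences <- read_fasta(sequences)
  if (length(sequences) == 0) stop("no sequences: empty assembly")
  lens <- nchar(sequences)
  counts <- Reduce(`+`, lapply(sequences, function(s) {
    b <- table(factor(strsplit(s, "")[[1]], levels = c("A", "C", "G", "T", "N")))
    as.numeric(b)
  }))
  names(counts) <- c("A", "C", "G", "T", "N")
  acgt <- sum(counts[c("A", "C", "G", "T")])
  structure(list(total_length = sum(lens), n_sequences = length(lens),
                 N50 = n50(lens), N90 = n50(lens, 0.9),
                 max_length = max(lens), min_length = min(lens),
                 GC = if (acgt > 0) (counts[["C"]] + counts[["G"]]) / acgt
                      else NA_real_,
                 N_bases = counts[["N"]]),
            class = "assembly_stats")
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat(sprintf(paste0("<assembly_stats> %d sequences, %.0f bp total\n",
                     "  N50 %.0f, N90 %.0f, max %.0f, min %.0f, GC %.1f%%,",
                     " %d N bases\n"),
              x$n_sequences, x$total_length, x$N50, x$N90, x$max_length,
              x$min_length, 100 * x$GC, x$N_bases))
  invisible(x)
}

#' Remapping-based completeness of an assembly
#'
#' Reads mode: the fraction of reads aligned unambiguously (unique best
#' placement, second-best strictly worse) and the fraction of assembly
#' positions covered at least once by those reads.  Transcripts mode:
#' the fraction of queries of length >= `min_length` (default 500 bp)
#' that align at >= `min_identity` (default 90%) identity over the query.
#'
#' @param queries Reads (character vector, `read_pairs`, list, FASTQ
#'   paths) or transcript sequences / FASTA path.
#' @param assembly A [contig_set], named character vector or FASTA path.
#' @param mode `"reads"` or `"transcripts"`.
#' @param min_identity Identity threshold (transcripts mode).
#' @param min_length Minimum query length entering the denominator
#'   (transcripts mode).
#' @param seed_k,seed_step Passed to [map_reads()].
#' @return A list: `query_aligned_fraction`, `assembly_covered_fraction`
#'   (reads mode; NA otherwise), `n_queries`, `mode`.
#' @export
alignment_coverage <- function(queries, assembly,
                               mode = c("reads", "transcripts"),
                               min_identity = 0.9, min_length = 500L,
                               seed_k = 31L, seed_step = 20L) {
  mode <- match.arg(mode)
  if (inherits(assembly, "contig_set"))
    assembly <- stats::setNames(assembly$seq, assembly$id)
  if (length(assembly) == 1 && !grepl("^[ACGTNacgtn]*$", assembly) &&
      file.exists(assembly))
    assembly <- read_fasta(assembly)
  queries <- if (mode == "reads") as_read_vector(queries) else {
    if (length(queries) == 1 && !grepl("^[ACGTNacgtn]*$", queries) &&
        file.exists(queries)) read_fasta(queries) else queries
  }
  stopifnot(length(queries) > 0, length(assembly) > 0)

  if (mode == "reads") {
    rl <- min(nchar(queries))
    pl <- map_reads(assembly, queries, seed_k = seed_k,
                    seed_step = seed_step, min_identity = min_identity,
                    min_overlap = max(31L, floor(0.9 * rl)))
    hit <- pl[!is.na(pl$ref) & pl$unique, , drop = FALSE]
    covered <- 0
    if (nrow(hit) > 0) {
      by_ref <- split(hit, hit$ref)
      covered <- sum(vapply(names(by_ref), function(r) {
        ir <- IRanges::reduce(IRanges::IRanges(by_ref[[r]]$ref_start,
                                               by_ref[[r]]$ref_end))
        sum(IRanges::width(ir))
      }, numeric(1)))
    }
    list(query_aligned_fraction = nrow(hit) / length(queries),
         assembly_covered_fraction = covered / sum(nchar(assembly)),
         n_queries = length(queries), mode = mode)
  } else {
    queries <- queries[nchar(queries) >= min_length]
    if (length(queries) == 0)
      return(list(query_aligned_fraction = NA_real_,
                  assembly_covered_fraction = NA_real_, n_queries = 0L,
                  mode = mode))
    pl <- map_reads(assembly, queries, seed_k = seed_k,
                    seed_step = max(seed_step, 50L), min_identity = 0,
                    min_overlap = as.integer(min_identity * min_length))
    aligned <- !is.na(pl$ref) &
      pl$matches >= min_identity * nchar(queries)
    list(query_aligned_fraction = mean(aligned),
         assembly_covered_fraction = NA_real_,
         n_queries = length(queries), mode = mode)
  }
}

#' Order-and-orientation accuracy of scaffolds against simulation truth
#'
#' For contigs produced by [fragment_into_contigs()] (which records
#' `truth_start` coordinates), checks every adjacent pair of contigs in
#' truth order: the pair is recovered when the two contigs are adjacent
#' in a scaffold with the correct relative orientation.
#'
#' @param sset A [hierarchical_scaffold()] result whose contigs carry
#'   `truth_start`.
#' @return A list: `accuracy` (fraction of truth-adjacent pairs
#'   recovered), `n_pairs`, `n_correct`.
#' @export
scaffold_order_accuracy <- function(sset) {
  stopifnot(inherits(sset, "scaffold_set"),
            "truth_start" %in% names(sset$contigs))
  ctg <- sset$contigs
  ord <- ctg$id[order(ctg$truth_start)]
  n_pairs <- length(ord) - 1L
  n_ok <- 0L
  for (i in seq_len(n_pairs)) {
    c1 <- ord[i]
    c2 <- ord[i + 1L]
    for (df in sset$scaffolds) {
      j <- match(c1, df$contig_id)
      k <- match(c2, df$contig_id)
      if (is.na(j) || is.na(k) || abs(j - k) != 1L) next
      if ((k == j + 1L && df$orient[j] == "+" && df$orient[k] == "+") ||
          (k == j - 1L && df$orient[j] == "-" && df$orient[k] == "-")) {
        n_ok <- n_ok + 1L
        break
      }
    }
  }
  list(accuracy = n_ok / n_pairs, n_pairs = n_pairs, n_correct = n_ok)
}
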