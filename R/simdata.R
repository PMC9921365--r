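#' Specification of a sequencing library
#'
#' Captures the geometry and error model of one Illumina-like paired
#' library.  Short-insert libraries (e.g. 180/300/500 bp) read inward from
#' the two fragment ends (`paired_end_innie`); long-insert mate-pair
#' libraries (e.g. 2/5/10/15 kb) read outward (`mate_pair_outie`).
#'
#' @param insert_mean Mean insert (fragment) size in bp.
#' @param insert_sd Standard deviation of the insert size in bp.
#' @param read_length Read length in bp.
#' @param layout `"paired_end_innie"` or `"mate_pair_outie"`.
#' @param error_rate Per-base substitution probability, in \[0, 0.1\].
#' @return A `library_spec` object.
#' @examples
#' library_spec(500, 50, 100)
#' library_spec(5000, 500, 100, layout = "mate_pair_outie")
#' @export
library_spec <- function(insert_mean, insert_sd, read_length,
                         layout = c("paired_end_innie", "mate_pair_outie"),
                         error_rate = 0) {
  layout <- match.arg(layout)
  stopifnot(insert_mean > 0, insert_sd >= 0, read_length > 0)
  if (error_rate < 0 || error_rate > 0.1)
    stop("error_rate must lie in [0, 0.1]")
  if (layout == "paired_end_innie" && insert_mean < 2 * read_length)
    stop("paired-end insert_mean must be >= 2 * read_length")
  structure(list(insert_mean = insert_mean, insert_sd = insert_sd,
                 read_length = as.integer(read_length), layout = layout,
                 error_rate = error_rate),
            class = "library_spec")
}

#' @export
print.library_spec <- function(x, ...) {
  cat(sprintf("<library_spec> %s, insert %g +/- %g bp, reads %d bp, error %g\n",
              x$layout, x$insert_mean, x$insert_sd, x$read_length,
              x$error_rate))
  invisible(x)
}

#' Simulate a diploid genome with known heterozygosity and repeats
#'
#' Generates two haplotypes of a diploid individual.  Haplotype B is
#' derived from haplotype A by a recorded list of variants (SNPs by
#' default, small indels optionally), so every downstream recovery test
#' has exact ground truth.  Heterozygous sites are placed uniformly
#' (binomially) by default; setting `het_block_length` and
#' `het_block_fraction` concentrates them into blocks separated by runs of
#' homozygosity, the mosaic structure real outbred genomes show.
#' Repeats are near-identical (1% internal divergence) dispersed copies of
#' a single sampled unit, dense enough to break unitigs while keeping
#' copies distinguishable.
#'
#' @param length Haploid genome length in bp (>= 1000).
#' @param het_rate Genome-wide per-base heterozygosity, in \[0, 0.05\].
#' @param repeat_fraction Fraction of haplotype A inside repeat copies,
#'   in \[0, 0.6\].
#' @param repeat_unit_length Length of the repeated unit in bp.
#' @param het_block_length,het_block_fraction Optional het-block mosaic:
#'   mean block length and the genome fraction covered by blocks.  Within
#'   blocks the SNP rate is `het_rate / het_block_fraction` so the
#'   genome-wide rate is preserved.
#' @param indel_fraction Fraction of variants realised as 1-10 bp
#'   insertions/deletions instead of SNPs (default 0: SNPs only, the
#'   regime the k-mer heterozygosity model assumes).
#' @param seed Integer seed; the result is fully reproducible from it.
#' @return A `diploid_truth` object: haplotype sequences, the variant
#'   table (`pos`, `ref`, `alt`, `kind` on haplotype A coordinates),
#'   repeat and het-block annotations.
#' @examples
#' g <- simulate_diploid_genome(10000, het_rate = 0.01, seed = 1)
#' nrow(g$variants)
#' @export
simulate_diploid_genome <- function(length, het_rate = 0.012,
                                    repeat_fraction = 0,
                                    repeat_unit_length = 500,
                                    het_block_length = NULL,
                                    het_block_fraction = NULL,
                                    indel_fraction = 0,
                                    seed = 1) {
  stopifnot(length >= 1000, het_rate >= 0, het_rate <= 0.05,
            repeat_fraction >= 0, repeat_fraction <= 0.6,
            indel_fraction >= 0, indel_fraction <= 1)
  length <- as.integer(length)
  set.seed(seed)

  bases <- c("A", "C", "G", "T")
  geno <- sample(bases, length, replace = TRUE)

  # --- repeats: dispersed copies of one unit, each in its own slot so a
  # unique anchor of >= 64 bp separates consecutive copies ---
  repeats <- data.frame(start = integer(0), end = integer(0),
                        family = character(0))
  if (repeat_fraction > 0) {
    n_copies <- max(1L, as.integer(round(repeat_fraction * length /
                                           repeat_unit_length)))
    slot <- length %/% n_copies
    if (slot - repeat_unit_length < 65L)
      stop("repeat_fraction/repeat_unit_length leave no unique anchors ",
           ">= 64 bp between repeat copies; lower the repeat density")
    unit <- sample(bases, repeat_unit_length, replace = TRUE)
    starts <- integer(n_copies)
    for (i in seq_len(n_copies)) {
      off <- sample.int(slot - repeat_unit_length - 63L, 1L)
      starts[i] <- (i - 1L) * slot + off
      copy <- unit
      nmut <- stats::rbinom(1L, repeat_unit_length, 0.01)
      if (nmut > 0) {
        at <- sample.int(repeat_unit_length, nmut)
        copy[at] <- vapply(copy[at], function(b)
          sample(setdiff(bases, b), 1L), character(1))
      }
      geno[starts[i]:(starts[i] + repeat_unit_length - 1L)] <- copy
    }
    repeats <- data.frame(start = starts,
                          end = starts + repeat_unit_length - 1L,
                          family = "rep1")
  }
  hap_a <- paste(geno, collapse = "")

  # --- heterozygous sites ---
  het_blocks <- NULL
  if (!is.null(het_block_length) && !is.null(het_block_fraction) &&
      het_block_fraction > 0 && het_rate > 0) {
    block_rate <- het_rate / het_block_fraction
    if (block_rate > 0.2)
      stop("het_rate / het_block_fraction implies an in-block SNP rate > 0.2")
    n_blocks <- max(1L, as.integer(round(length * het_block_fraction /
                                           het_block_length)))
    slot <- length %/% n_blocks
    if (slot <= het_block_length + 2L)
      stop("het_block_fraction too high for het_block_length")
    bstart <- (seq_len(n_blocks) - 1L) * slot +
      vapply(seq_len(n_blocks), function(i)
        sample.int(slot - het_block_length - 1L, 1L), integer(1))
    het_blocks <- data.frame(start = bstart,
                             end = bstart + het_block_length - 1L)
    pos <- unlist(lapply(seq_len(n_blocks), function(i) {
      hit <- which(runif(het_block_length) < block_rate)
      bstart[i] + hit - 1L
    }))
  } else {
    pos <- if (het_rate > 0) which(runif(length) < het_rate) else integer(0)
  }
  pos <- sort(unique(pos))

  variants <- data.frame(pos = integer(0), ref = character(0),
                         alt = character(0), kind = character(0))
  if (length(pos) > 0) {
    kind <- rep("snp", length(pos))
    if (indel_fraction > 0) {
      is_indel <- runif(length(pos)) < indel_fraction
      kind[is_indel] <- sample(c("ins", "del"), sum(is_indel), replace = TRUE)
    }
    ref <- substring(hap_a, pos, pos)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1),
                  USE.NAMES = FALSE)
    len <- rep(1L, length(pos))
    for (i in which(kind != "snp")) {
      l <- sample.int(10L, 1L)
      if (kind[i] == "ins") {           # VCF-style: ref base + inserted seq
        alt[i] <- paste0(ref[i], paste(sample(bases, l, replace = TRUE),
                                       collapse = ""))
      } else {                          # deletion: ref span, alt = first base
        end <- min(pos[i] + l, length)
        ref[i] <- substring(hap_a, pos[i], end)
        alt[i] <- substring(hap_a, pos[i], pos[i])
        len[i] <- end - pos[i] + 1L
      }
    }
    # enforce strictly increasing, non-overlapping variant spans
    keep <- rep(TRUE, length(pos))
    prev_end <- -1L
    for (i in seq_along(pos)) {
      if (pos[i] <= prev_end) keep[i] <- FALSE
      else prev_end <- pos[i] + len[i] - 1L
    }
    variants <- data.frame(pos = pos, ref = ref, alt = alt, kind = kind,
                           stringsAsFactors = FALSE)[keep, , drop = FALSE]
    rownames(variants) <- NULL
  }

  structure(list(haplotype_a = hap_a,
                 haplotype_b = apply_variants(hap_a, variants),
                 variants = variants, repeats = repeats,
                 het_blocks = het_blocks, length = length, seed = seed),
            class = "diploid_truth")
}

#' @export
print.diploid_truth <- function(x, ...) {
  cat(sprintf(
    "<diploid_truth> %d bp haploid, %d variants (%.3f%% het), %d repeat copies\n",
    x$length, nrow(x$variants), 100 * nrow(x$variants) / x$length,
    nrow(x$repeats)))
  invisible(x)
}

#' Apply a variant table to a haplotype sequence
#'
#' Reconstructs haplotype B from haplotype A and the recorded variants
#' (the round-trip identity every `diploid_truth` object satisfies).
#'
#' @param seq Haplotype A sequence (single string).
#' @param variants Variant table with `pos`, `ref`, `alt` (VCF-style:
#'   `ref` is the affected span on `seq` starting at `pos`).
#' @return The edited sequence.
#' @export
apply_variants <- function(seq, variants) {
  if (is.null(variants) || nrow(variants) == 0) return(seq)
  stopifnot(all(diff(variants$pos) > 0))
  n <- nrow(variants)
  pieces <- character(2L * n + 1L)
  prev <- 1L
  for (i in seq_len(n)) {
    p <- variants$pos[i]
    if (substring(seq, p, p + nchar(variants$ref[i]) - 1L) != variants$ref[i])
      stop("variant ", i, " ref allele does not match the sequence")
    pieces[2L * i - 1L] <- substring(seq, prev, p - 1L)
    pieces[2L * i] <- variants$alt[i]
    prev <- p + nchar(variants$ref[i])
  }
  pieces[2L * n + 1L] <- substring(seq, prev, nchar(seq))
  paste(pieces, collapse = "")
}

# map haplotype-A positions to haplotype-B positions given the variant
# table (identity when all variants are SNPs)
a_to_b_position <- function(pos, variants) {
  if (nrow(variants) == 0) return(pos)
  vend <- variants$pos + nchar(variants$ref) - 1L
  delta <- cumsum(nchar(variants$alt) - nchar(variants$ref))
  idx <- findInterval(pos - 0.5, vend)
  pos + c(0L, delta)[idx + 1L]
}

#' Simulate a paired read library from a diploid genome
#'
#' Fragments are drawn uniformly from the two haplotypes in equal
#' expectation; insert sizes are Normal(`insert_mean`, `insert_sd`)
#' truncated at `2 * read_length`; mate orientation follows the library
#' layout.  Read names carry truth provenance as `id:hap:pos:strand`
#' (haplotype A/B, 1-based fragment start on that haplotype, fragment
#' strand), which the QC evaluators parse.
#'
#' @param truth A [simulate_diploid_genome()] result, or a single sequence
#'   (treated as a homozygous genome).
#' @param lib A [library_spec()].
#' @param coverage Total fold coverage of the haploid genome.
#' @param seed Integer seed.
#' @return A `read_pairs` object: named character vectors `r1`, `r2` plus
#'   the library `spec`.
#' @examples
#' g <- simulate_diploid_genome(10000, het_rate = 0, seed = 1)
#' rp <- simulate_reads(g, library_spec(500, 50, 100), coverage = 10, seed = 2)
#' length(rp$r1)
#' @export
simulate_reads <- function(truth, lib, coverage, seed = 1) {
  stopifnot(inherits(lib, "library_spec"), coverage > 0)
  if (is.character(truth)) {
    stopifnot(length(truth) == 1, nchar(truth) > 0)
    truth <- structure(list(haplotype_a = truth, haplotype_b = truth,
                            variants = data.frame(), length = nchar(truth)),
                       class = "diploid_truth")
  }
  stopifnot(inherits(truth, "diploid_truth"))
  haps <- c(A = truth$haplotype_a, B = truth$haplotype_b)
  hap_len <- nchar(haps)
  rl <- lib$read_length
  if (lib$insert_mean > min(hap_len))
    stop("insert_mean exceeds the genome length")
  set.seed(seed)

  n_pairs <- as.integer(round(coverage * truth$length / (2 * rl)))
  stopifnot(n_pairs >= 1)
  hap <- sample(c("A", "B"), n_pairs, replace = TRUE)
  ins <- pmax(2L * rl, as.integer(round(rnorm(n_pairs, lib$insert_mean,
                                              lib$insert_sd))))
  ins <- pmin(ins, hap_len[hap])
  start <- 1L + as.integer(floor(runif(n_pairs) * (hap_len[hap] - ins + 1)))
  end <- start + ins - 1L

  left <- substring(haps[hap], start, start + rl - 1L)
  right <- substring(haps[hap], end - rl + 1L, end)
  if (lib$layout == "paired_end_innie") {
    m1 <- left
    m2 <- revcomp(right)
  } else {                               # mate_pair_outie: reads face outward
    m1 <- revcomp(left)
    m2 <- right
  }
  # a fragment from the reverse strand swaps the mate roles
  swap <- runif(n_pairs) < 0.5
  r1 <- ifelse(swap, m2, m1)
  r2 <- ifelse(swap, m1, m2)

  if (lib$error_rate > 0) {
    r1 <- inject_errors(r1, lib$error_rate)
    r2 <- inject_errors(r2, lib$error_rate)
  }
  ids <- sprintf("r%07d:%s:%d:%s", seq_len(n_pairs), hap, start,
                 ifelse(swap, "-", "+"))
  names(r1) <- ids
  names(r2) <- ids
  structure(list(r1 = r1, r2 = r2, spec = lib), class = "read_pairs")
}

#' @export
print.read_pairs <- function(x, ...) {
  cat(sprintf("<read_pairs> %d pairs of %d bp reads (%s, insert %g bp)\n",
              length(x$r1), x$spec$read_length, x$spec$layout,
              x$spec$insert_mean))
  invisible(x)
}

inject_errors <- function(reads, rate) {
  rl <- nchar(reads[1])
  total <- length(reads) * rl
  n_err <- stats::rbinom(1L, total, rate)
  if (n_err == 0) return(reads)
  at <- sample.int(total, n_err)
  ri <- (at - 1L) %/% rl + 1L
  off <- (at - 1L) %% rl + 1L
  bases <- c("A", "C", "G", "T")
  for (j in seq_len(n_err)) {
    old <- substring(reads[ri[j]], off[j], off[j])
    substr(reads[ri[j]], off[j], off[j]) <-
      sample(setdiff(bases, old), 1L)
  }
  reads
}

#' Fragment a diploid truth genome into truth-labelled contigs
#'
#' Produces the contig fixture the bubble-collapse stage is tested on:
#' homozygous regions are emitted once, heterozygous regions are emitted
#' as labelled haplotype pairs (partner ids recorded), and the
#' concatenation of haplotype-A-derived fragments reconstructs
#' haplotype A exactly.
#'
#' @param truth A [simulate_diploid_genome()] result.
#' @param min_len,max_len Homozygous fragments are drawn uniformly from
#'   this length range.
#' @param split_at_het_blocks Emit each heterozygous block (or variant
#'   cluster) as one haplotype pair with boundaries at the block edges
#'   (default).  When `FALSE` the genome is chopped uniformly and each
#'   fragment is labelled by whether it contains a variant.
#' @param seed Integer seed.
#' @return A [contig_set] with `truth_label` (`homozygous`/`het_pair`),
#'   `partner_id`, `truth_start`/`truth_end` (haplotype A coordinates) and
#'   `truth_hap` columns.
#' @export
fragment_into_contigs <- function(truth, min_len = 500, max_len = 2000,
                                  split_at_het_blocks = TRUE, seed = 1) {
  stopifnot(inherits(truth, "diploid_truth"), min_len <= max_len,
            min_len >= 1)
  set.seed(seed)
  L <- truth$length
  v <- truth$variants

  # heterozygous intervals on haplotype A
  het <- NULL
  if (split_at_het_blocks && nrow(v) > 0) {
    vend <- v$pos + nchar(v$ref) - 1L
    if (!is.null(truth$het_blocks)) {
      hb <- truth$het_blocks
      has_var <- vapply(seq_len(nrow(hb)), function(i)
        any(v$pos >= hb$start[i] & vend <= hb$end[i]), logical(1))
      het <- hb[has_var, , drop = FALSE]
    } else {
      pad <- 100L
      grp <- cumsum(c(1L, diff(v$pos) >= min_len))
      het <- do.call(rbind, lapply(split(seq_len(nrow(v)), grp), function(ix)
        data.frame(start = max(1L, v$pos[ix[1]] - pad),
                   end = min(L, vend[ix[length(ix)]] + pad))))
      # merge padded intervals that now touch
      if (nrow(het) > 1) {
        keep <- list(het[1, ])
        for (i in 2:nrow(het)) {
          last <- keep[[length(keep)]]
          if (het$start[i] <= last$end + 1L)
            keep[[length(keep)]]$end <- max(last$end, het$end[i])
          else keep[[length(keep) + 1L]] <- het[i, ]
        }
        het <- do.call(rbind, keep)
      }
    }
    rownames(het) <- NULL
  }

  chop <- function(from, to) {
    out <- list()
    p <- from
    while (p <= to) {
      len <- sample(min_len:max_len, 1L)
      if (to - p + 1L - len < min_len) len <- to - p + 1L
      out[[length(out) + 1L]] <- c(p, min(to, p + len - 1L))
      p <- p + len
    }
    out
  }

  segs <- list()   # each: list(start, end, het)
  if (is.null(het) || nrow(het) == 0) {
    for (s in chop(1L, L))
      segs[[length(segs) + 1L]] <- list(start = s[1], end = s[2],
                                        het = FALSE)
    if (!split_at_het_blocks && nrow(v) > 0) {
      for (i in seq_along(segs)) {
        sg <- segs[[i]]
        segs[[i]]$het <- any(v$pos >= sg$start & v$pos <= sg$end)
      }
    }
  } else {
    p <- 1L
    for (i in seq_len(nrow(het))) {
      if (het$start[i] > p)
        for (s in chop(p, het$start[i] - 1L))
          segs[[length(segs) + 1L]] <- list(start = s[1], end = s[2],
                                            het = FALSE)
      segs[[length(segs) + 1L]] <- list(start = het$start[i],
                                        end = het$end[i], het = TRUE)
      p <- het$end[i] + 1L
    }
    if (p <= L)
      for (s in chop(p, L))
        segs[[length(segs) + 1L]] <- list(start = s[1], end = s[2],
                                          het = FALSE)
  }

  rows <- list()
  for (i in seq_along(segs)) {
    sg <- segs[[i]]
    seq_a <- substring(truth$haplotype_a, sg$start, sg$end)
    if (sg$het) {
      sb <- a_to_b_position(sg$start, v)
      eb <- a_to_b_position(sg$end + 1L, v) - 1L
      seq_b <- substring(truth$haplotype_b, sb, eb)
      ida <- sprintf("ctg%05da", i)
      idb <- sprintf("ctg%05db", i)
      rows[[length(rows) + 1L]] <- data.frame(
        id = c(ida, idb), seq = c(seq_a, seq_b),
        truth_label = "het_pair", partner_id = c(idb, ida),
        truth_start = sg$start, truth_end = sg$end,
        truth_hap = c("A", "B"), stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        id = sprintf("ctg%05d", i), seq = seq_a,
        truth_label = "homozygous", partner_id = NA_character_,
        truth_start = sg$start, truth_end = sg$end,
        truth_hap = "A", stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  contig_set(stats::setNames(df$seq, df$id),
             truth_label = df$truth_label, partner_id = df$partner_id,
             truth_start = df$truth_start, truth_end = df$truth_end,
             truth_hap = df$truth_hap)
}
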