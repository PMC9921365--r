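#' Construct a contig set
#'
#' The central sequence container of the pipeline: a data frame with one
#' row per contig (`id`, `seq`, `length`, `depth`, `multi_mass`) plus any
#' extra per-contig columns (truth labels, het flags, ...).
#'
#' @param seqs Named character vector of contig sequences (names become
#'   ids; unnamed input is given `ctg%05d` ids).
#' @param depth Optional numeric vector of per-contig mean depths.
#' @param ... Further per-contig columns (recycled by `data.frame`).
#' @return A `contig_set` (also a `data.frame`).
#' @export
contig_set <- function(seqs, depth = NA_real_, ...) {
  if (length(seqs) == 0) {
    df <- data.frame(id = character(0), seq = character(0),
                     length = integer(0), depth = numeric(0),
                     multi_mass = numeric(0), stringsAsFactors = FALSE)
    class(df) <- c("contig_set", "data.frame")
    return(df)
  }
  seqs <- toupper(seqs)
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("ctg%05d", seq_along(seqs))
  if (anyDuplicated(ids)) stop("contig ids must be unique")
  if (length(seqs) > 0 && any(!grepl("^[ACGTN]*$", seqs)))
    stop("contig sequences must be uppercase ACGTN")
  df <- data.frame(id = ids, seq = unname(seqs),
                   length = nchar(seqs), depth = depth,
                   multi_mass = NA_real_, ...,
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  class(df) <- c("contig_set", "data.frame")
  df
}

#' @export
print.contig_set <- function(x, ...) {
  cat(sprintf("<contig_set> %d contigs, %d bp total", nrow(x),
              sum(x$length)))
  if (nrow(x) > 0) {
    cat(sprintf(", N50 %d bp", n50(x$length)))
    if (any(!is.na(x$depth)))
      cat(sprintf(", median depth %.1f", stats::median(x$depth, na.rm = TRUE)))
  }
  cat("\n")
  if ("truth_label" %in% names(x) && nrow(x) > 0) {
    tab <- table(x$truth_label)
    cat("  truth labels:", paste(names(tab), tab, sep = "=", collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Map reads to reference sequences
#'
#' Exact canonical k-mer seeding followed by ungapped extension, the
#' internal aligner used for depth computation, link building and
#' coverage QC.  Placements are scored by matching bases over the
#' read/reference overlap (reads overhanging a reference end are
#' clipped); a read is *uniquely* placed when its best score is strictly
#' better than the second best.  Sufficient for substitution error rates
#' up to ~1% at desk scale; SAM from an external aligner can be converted
#' with [sam_to_placements()] instead.
#'
#' @param refs A [contig_set], or named character vector of references.
#' @param reads Character vector of read sequences.
#' @param seed_k Seed k-mer length (default 31).
#' @param seed_step Distance between successive seed positions in the read.
#' @param min_identity Minimum matches/overlap for a valid placement.
#' @param min_overlap Minimum read/reference overlap in bp.
#' @return A data frame with one row per read: `ref` (id or `NA`), `pos`
#'   (1-based leftmost reference position, may be < 1 for clipped reads),
#'   `strand`, `matches`, `overlap`, `second_matches`, `unique`,
#'   `ref_start`/`ref_end` (1-based clipped interval).
#' @export
map_reads <- function(refs, reads, seed_k = 31L, seed_step = 20L,
                      min_identity = 0.9, min_overlap = 31L) {
  ids <- if (inherits(refs, "contig_set")) refs$id else
    (names(refs) %||% as.character(seq_along(refs)))
  seqs <- if (inherits(refs, "contig_set")) refs$seq else unname(refs)
  stopifnot(length(seqs) > 0)
  m <- cpp_map_reads(seqs, unname(reads), as.integer(seed_k),
                     as.integer(seed_step), min_identity,
                     as.integer(min_overlap))
  data.frame(read = names(reads) %||% as.character(seq_along(reads)),
             ref = ids[m$ref], pos = m$pos + 1L, strand = m$strand,
             matches = m$matches, overlap = m$overlap,
             second_matches = m$second_matches, unique = m$unique,
             ref_start = m$ref_start + 1L, ref_end = m$ref_end,
             stringsAsFactors = FALSE)
}

#' Convert SAM alignments to the internal placement table
#'
#' Lets the pipeline compose with an external aligner: primary alignments
#' from a SAM file are converted into the same placement table
#' [map_reads()] produces.  Uniqueness is taken from mapping quality
#' (MAPQ > 0), the conventional unambiguous-placement signal.
#'
#' @param path Path to a SAM file.
#' @return A placement data frame (see [map_reads()]).
#' @export
sam_to_placements <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "@")]
  if (length(ln) == 0)
    return(data.frame(read = character(0), ref = character(0),
                      pos = integer(0), strand = character(0),
                      matches = integer(0), overlap = integer(0),
                      second_matches = integer(0), unique = logical(0),
                      ref_start = integer(0), ref_end = integer(0)))
  f <- strsplit(ln, "\t")
  flag <- vapply(f, function(x) as.integer(x[2]), integer(1))
  keep <- bitwAnd(flag, 0x900) == 0          # primary alignments only
  f <- f[keep]; flag <- flag[keep]
  mapped <- bitwAnd(flag, 0x4) == 0
  seqlen <- vapply(f, function(x) nchar(x[10]), integer(1))
  pos <- vapply(f, function(x) as.integer(x[4]), integer(1))
  mapq <- vapply(f, function(x) as.integer(x[5]), integer(1))
  data.frame(
    read = vapply(f, `[`, character(1), 1),
    ref = ifelse(mapped, vapply(f, `[`, character(1), 3), NA_character_),
    pos = ifelse(mapped, pos, NA_integer_),
    strand = ifelse(mapped, ifelse(bitwAnd(flag, 0x10) > 0, "-", "+"),
                    NA_character_),
    matches = ifelse(mapped, seqlen, 0L),
    overlap = ifelse(mapped, seqlen, 0L),
    second_matches = 0L,
    unique = mapped & mapq > 0,
    ref_start = ifelse(mapped, pos, NA_integer_),
    ref_end = ifelse(mapped, pos + seqlen - 1L, NA_integer_),
    stringsAsFactors = FALSE)
}
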