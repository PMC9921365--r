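#' Read a FASTA file
#'
#' @param path Path to a (optionally gzipped) FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Read a FASTQ file
#'
#' @param path Path to a (optionally gzipped) FASTQ file.
#' @return Named character vector of uppercase sequences.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector, or a [contig_set].
#' @param path Output path.
#' @param width Line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 80L) {
  if (inherits(seqs, "contig_set")) {
    seqs <- stats::setNames(seqs$seq, seqs$id)
  }
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Write paired reads to a pair of FASTQ files
#'
#' Base qualities are written as a constant Phred 35 ('D'); quality
#' modelling is outside the scope of the simulator.
#'
#' @param pairs A [simulate_reads()] result.
#' @param prefix Output prefix; `<prefix>_1.fastq` and `<prefix>_2.fastq`
#'   are written (gzipped when `gz = TRUE`).
#' @param gz Compress output with gzip.
#' @return Character vector of the two paths, invisibly.
#' @export
write_read_pairs <- function(pairs, prefix, gz = FALSE) {
  stopifnot(inherits(pairs, "read_pairs"))
  ext <- if (gz) ".fastq.gz" else ".fastq"
  paths <- paste0(prefix, c("_1", "_2"), ext)
  for (i in 1:2) {
    r <- pairs[[c("r1", "r2")[i]]]
    x <- Biostrings::DNAStringSet(r)
    names(x) <- paste0(names(r), "/", i)
    qual <- Biostrings::BStringSet(strrep("D", nchar(r)))
    Biostrings::writeXStringSet(x, paths[i], format = "fastq",
                                qualities = qual,
                                compress = if (gz) "gzip" else FALSE)
  }
  invisible(paths)
}

#' Read a paired FASTQ library back into a read-pairs object
#'
#' @param path1,path2 FASTQ files for the first and second mates.
#' @param spec The [library_spec()] the library was sequenced with.
#' @return A `read_pairs` object as produced by [simulate_reads()].
#' @export
read_read_pairs <- function(path1, path2, spec) {
  r1 <- read_fastq(path1)
  r2 <- read_fastq(path2)
  names(r1) <- sub("/1$", "", names(r1))
  names(r2) <- sub("/2$", "", names(r2))
  if (length(r1) != length(r2)) stop("mate files differ in read count")
  structure(list(r1 = r1, r2 = r2, spec = spec), class = "read_pairs")
}
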