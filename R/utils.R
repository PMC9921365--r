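#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences (ACGTN).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# lexicographically canonical form of a sequence (min of seq, revcomp)
canonical_seq <- function(x) {
  rc <- revcomp(x)
  ifelse(x <= rc, x, rc)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# extract read sequences from the various accepted forms
as_read_vector <- function(reads) {
  if (is.character(reads)) {
    if (length(reads) == 0) return(character(0))
    if (length(reads) <= 4 && all(file.exists(reads))) {
      return(unlist(lapply(reads, read_fastq), use.names = TRUE))
    }
    return(reads)
  }
  if (inherits(reads, "read_pairs")) return(c(reads$r1, reads$r2))
  if (is.list(reads)) return(unlist(lapply(reads, as_read_vector), use.names = TRUE))
  stop("cannot interpret `reads`: expected character vector, file path(s) or read_pairs")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
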