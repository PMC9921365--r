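#' Count the canonical k-mer spectrum of a read set
#'
#' Counts every k-mer in canonical form (the lexicographic minimum of the
#' k-mer and its reverse complement, unambiguous for odd k) and returns
#' the multiplicity histogram: how many distinct canonical k-mers were
#' observed m times, for every m.  k-mers containing non-ACGT symbols are
#' skipped.
#'
#' @param reads Character vector of reads, a `read_pairs` object, a list
#'   of either, or FASTQ path(s).
#' @param k Odd k-mer size, 11-31 (default 19).
#' @return A `kmer_spectrum`: data frame with `multiplicity` and `count`
#'   columns, with attributes `k` and `total_instances`
#'   (= sum(multiplicity * count), the number of k-mer instances streamed).
#' @examples
#' sp <- count_kmer_spectrum(c("ACGTACGTACGTACGTACGTACG"), k = 19)
#' sp
#' @export
count_kmer_spectrum <- function(reads, k = 19L) {
  check_k(k)
  reads <- as_read_vector(reads)
  hist <- if (length(reads) == 0)
    data.frame(multiplicity = integer(0), count = numeric(0))
  else cpp_kmer_spectrum(toupper(unname(reads)), as.integer(k))
  structure(hist, k = as.integer(k),
            total_instances = sum(hist$multiplicity * hist$count),
            class = c("kmer_spectrum", "data.frame"))
}

#' @export
print.kmer_spectrum <- function(x, ...) {
  cat(sprintf("<kmer_spectrum> k=%d, %d distinct k-mers, %.0f instances\n",
              attr(x, "k"), round(sum(x$count)), attr(x, "total_instances")))
  invisible(x)
}

#' Estimate genome size and heterozygosity from a k-mer spectrum
#'
#' The k-mer frequency-distribution method.  After smoothing the
#' histogram with a centred 3-bin moving average, the error cutoff is the
#' first local minimum above multiplicity 1 (sequencing-error k-mers form
#' a spike at low multiplicity).  The homozygous peak is the
#' highest-multiplicity major peak above the cutoff; in a diploid
#' spectrum a second, heterozygous peak sits near half that depth.
#'
#' Genome size is `sum(m * hist[m], m >= cutoff) / hom_peak_depth`
#' (haploid bp).  Heterozygosity uses two-peak attribution: distinct
#' k-mers with multiplicity in `[cutoff, midpoint)` are haplotype-unique
#' (count h, two haplotypes' worth), those in `[midpoint, 1.5 * hom]` are
#' shared (count d); with `a = (h/2) / (h/2 + d)` the per-base rate is
#' r = 1 - (1 - a)^(1/k), since a site is heterozygous-unique exactly
#' when its k-mer spans at least one SNP.
#'
#' @param spectrum A [count_kmer_spectrum()] result.
#' @param ploidy 1 or 2.  Requesting ploidy 1 on a bimodal spectrum
#'   records a warning in the result rather than failing.
#' @param read_length Optional read length; when given, the implied base
#'   coverage `hom_peak / ((L - k + 1) / L)` is reported (the k-mer depth
#'   of a base is diluted by the `(L - k + 1) / L` edge factor).
#' @param major_peak_frac A smoothed local maximum counts as a major peak
#'   when its height is at least this fraction of the tallest peak.
#' @return A `genome_estimate`: `genome_size` (haploid bp),
#'   `heterozygosity` (fraction), `hom_peak_depth` (modal multiplicity),
#'   `hom_peak_refined` (centroid of the histogram within 20% of the
#'   mode; the fractional depth the size estimate divides by),
#'   `het_peak_depth`
#'   (NA when no heterozygous peak is detected), `error_cutoff`,
#'   `coverage` (NA without `read_length`), `warnings`.
#' @examples
#' sp <- structure(data.frame(multiplicity = 60L, count = 10000),
#'                 k = 19L, total_instances = 6e5,
#'                 class = c("kmer_spectrum", "data.frame"))
#' estimate_genome(sp)$genome_size   # 10000
#' @export
estimate_genome <- function(spectrum, ploidy = 2L, read_length = NULL,
                            major_peak_frac = 0.2) {
  stopifnot(inherits(spectrum, "kmer_spectrum"), ploidy %in% c(1L, 2L))
  if (nrow(spectrum) == 0) stop("spectrum uninformative: no k-mers counted")
  k <- attr(spectrum, "k")
  M <- max(spectrum$multiplicity)
  h <- numeric(M)
  h[spectrum$multiplicity] <- spectrum$count

  # centred 3-bin moving average (zero-padded)
  hp <- c(0, h, 0)
  s <- (hp[1:M] + hp[2:(M + 1)] + hp[3:(M + 2)]) / 3

  # error cutoff: first local minimum above m = 1; a spectrum that rises
  # from the start has no error component
  cutoff <- 1L
  if (M >= 3) {
    for (m in 2:(M - 1)) {
      if (s[m] <= s[m - 1] && s[m] < s[m + 1]) { cutoff <- m; break }
      if (s[m] > s[m - 1]) break
    }
  }

  # smoothed local maxima at multiplicity >= cutoff (plateau ties resolved
  # toward lower multiplicity), refined to the raw-histogram mode
  peaks <- integer(0)
  if (M >= 2) {
    for (m in max(cutoff, 2L):M) {
      left <- s[m - 1]
      right <- if (m == M) 0 else s[m + 1]
      if (s[m] > left && s[m] >= right) peaks <- c(peaks, m)
    }
  } else if (h[1] > 0) peaks <- 1L
  if (length(peaks) == 0) stop("spectrum uninformative: no peak above cutoff")
  peaks <- peaks[s[peaks] >= major_peak_frac * max(s[peaks])]
  refine <- function(p) {
    win <- max(1L, p - 1L):min(M, p + 1L)
    win[which.max(h[win])]
  }
  peaks <- sort(unique(vapply(peaks, refine, integer(1))))

  hom_peak <- max(peaks)
  het_cand <- peaks[peaks >= 0.35 * hom_peak & peaks <= 0.65 * hom_peak]
  het_peak <- if (length(het_cand) > 0)
    het_cand[which.max(s[het_cand])] else NA_integer_

  warnings <- character(0)
  if (ploidy == 1L && !is.na(het_peak))
    warnings <- "ploidy 1 requested but the spectrum is bimodal"

  mm <- seq_len(M)
  # fractional peak depth: centroid of the histogram within +/-20% of the
  # mode; the integer mode alone quantizes the size estimate by ~1/depth
  win <- mm >= ceiling(0.8 * hom_peak) & mm <= floor(1.2 * hom_peak)
  hom_refined <- sum(mm[win] * h[win]) / sum(h[win])
  genome_size <- sum(mm[mm >= cutoff] * h[mm >= cutoff]) / hom_refined

  heterozygosity <- 0
  if (ploidy == 2L && !is.na(het_peak)) {
    midpoint <- (het_peak + hom_peak) / 2
    upper <- round(1.5 * hom_peak)
    h_uni <- sum(h[mm >= cutoff & mm < midpoint])
    d_shared <- sum(h[mm >= midpoint & mm <= upper])
    alpha <- (h_uni / 2) / (h_uni / 2 + d_shared)
    heterozygosity <- 1 - (1 - alpha)^(1 / k)
  }

  coverage <- NA_real_
  if (!is.null(read_length))
    coverage <- hom_refined / ((read_length - k + 1) / read_length)

  structure(list(genome_size = genome_size,
                 heterozygosity = heterozygosity,
                 hom_peak_depth = hom_peak,
                 hom_peak_refined = hom_refined,
                 het_peak_depth = het_peak,
                 error_cutoff = cutoff, coverage = coverage,
                 k = k, ploidy = ploidy, warnings = warnings),
            class = "genome_estimate")
}

#' @export
print.genome_estimate <- function(x, ...) {
  cat(sprintf("<genome_estimate> size %.0f bp, heterozygosity %.3f%%\n",
              x$genome_size, 100 * x$heterozygosity))
  cat(sprintf("  hom peak %dx, het peak %s, error cutoff %d\n",
              x$hom_peak_depth,
              if (is.na(x$het_peak_depth)) "none" else
                paste0(x$het_peak_depth, "x"),
              x$error_cutoff))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Write a k-mer spectrum as a two-column TSV
#'
#' @param spectrum A `kmer_spectrum`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  write.table(as.data.frame(spectrum), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
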