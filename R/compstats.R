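#' Assembled-genome summaries of four vestimentiferan tubeworms
#'
#' The per-species assembled genome size (Mb) and repeat content (%) of
#' the four deep-sea tubeworm draft genomes shipped with the package,
#' the input of the size~repeat regression.
#'
#' @return A data frame: `species`, `assembled_size_mb`,
#'   `repeat_content_pct`.
#' @export
tubeworm_genome_table <- function() {
  path <- system.file("extdata", "tubeworm_genomes.tsv", package = "hetasm",
                      mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Regress assembled genome size on repeat content
#'
#' Ordinary least squares of genome size (Mb) on repeat content (%)
#' across species.  `r_squared` is the squared Pearson correlation; the
#' p-value is the two-sided t test on the correlation,
#' `t = r * sqrt((n - 2) / (1 - r^2))` against t with n - 2 degrees of
#' freedom.
#'
#' @param summaries Data frame with `repeat_content_pct` and
#'   `assembled_size_mb` columns (e.g. [tubeworm_genome_table()]).
#' @param min_n Minimum number of species (default 3; with 2 points the
#'   fit is exact and the p-value undefined).
#' @return A `size_repeat_fit`: `slope`, `intercept`, `r_squared`,
#'   `p_value`, `n`, plus the underlying `lm` fit and data.
#' @examples
#' fit <- fit_size_repeat_regression(tubeworm_genome_table())
#' round(fit$r_squared, 4)
#' @export
fit_size_repeat_regression <- function(summaries, min_n = 3L) {
  stopifnot(is.data.frame(summaries),
            all(c("repeat_content_pct", "assembled_size_mb") %in%
                  names(summaries)))
  x <- summaries$repeat_content_pct
  y <- summaries$assembled_size_mb
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < min_n) stop("need at least ", min_n, " species")
  if (length(unique(x)) < 2 || sd(x) == 0)
    stop("repeat content has zero variance; regression undefined")
  if (any(x < 0 | x > 100) || any(y <= 0))
    stop("repeat content must be a percent in [0,100], sizes positive")
  fit <- lm(y ~ x)
  r <- stats::cor(x, y)
  r2 <- r^2
  p <- if (n > 2 && r2 < 1) {
    t <- r * sqrt((n - 2) / (1 - r2))
    2 * pt(-abs(t), df = n - 2)
  } else NA_real_
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = r2, p_value = p, n = n, model = fit,
                 data = data.frame(repeat_content_pct = x,
                                   assembled_size_mb = y)),
            class = "size_repeat_fit")
}

#' @export
print.size_repeat_fit <- function(x, ...) {
  cat(sprintf(
    "<size_repeat_fit> n=%d: size = %.2f + %.2f * repeat%%  (R2 = %.4f, P = %.4f)\n",
    x$n, x$intercept, x$slope, x$r_squared, x$p_value))
  invisible(x)
}

#' @export
plot.size_repeat_fit <- function(x, ...) {
  graphics::plot(x$data$repeat_content_pct, x$data$assembled_size_mb,
                 xlab = "Repeat content (%)",
                 ylab = "Assembled genome size (Mb)",
                 pch = 19, ...)
  graphics::abline(x$intercept, x$slope, lty = 2)
  graphics::legend("topleft", bty = "n", legend = sprintf(
    "R2 = %.2f, P = %.4f", x$r_squared, x$p_value))
  invisible(x)
}

#' Exon and intron length accounting from a GFF3 annotation
#'
#' Per mRNA, introns are the gaps between consecutive exons after
#' sorting; per gene only the longest transcript (most exonic bp, ties
#' broken by lexicographic transcript id) is counted, and totals are
#' summed over genes.  Transcripts with overlapping exons are rejected
#' and logged.
#'
#' @param annotation Path to a GFF3 file (1-based inclusive coordinates)
#'   with gene/mRNA/exon features, or a `GRanges` from
#'   `rtracklayer::import`.
#' @return A list: `exon_total`, `intron_total` (bp), `n_genes`,
#'   `n_introns`, `mean_intron_length`, `intron_exon_ratio`,
#'   `skipped_transcripts`.
#' @examples
#' gff <- tempfile(fileext = ".gff3")
#' writeLines(c("##gff-version 3",
#'   "chr1\t.\tgene\t1\t300\t.\t+\t.\tID=g1",
#'   "chr1\t.\tmRNA\t1\t300\t.\t+\t.\tID=t1;Parent=g1",
#'   "chr1\t.\texon\t1\t100\t.\t+\t.\tParent=t1",
#'   "chr1\t.\texon\t201\t300\t.\t+\t.\tParent=t1"), gff)
#' intron_exon_accounting(gff)$intron_total  # 100
#' @export
intron_exon_accounting <- function(annotation) {
  if (is.character(annotation)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("reading GFF3 files requires the rtracklayer package")
    annotation <- rtracklayer::import(annotation, format = "gff3")
  }
  if (!requireNamespace("GenomicRanges", quietly = TRUE))
    stop("intron/exon accounting requires the GenomicRanges package")
  typ <- as.character(annotation$type)
  first_chr <- function(x) vapply(x, function(v)
    if (length(v) > 0) as.character(v[1]) else NA_character_, character(1))

  mrna <- annotation[typ %in% c("mRNA", "transcript")]
  tx_gene <- stats::setNames(first_chr(mrna$Parent), as.character(mrna$ID))
  tx_gene[is.na(tx_gene)] <- names(tx_gene)[is.na(tx_gene)]

  ex <- annotation[typ == "exon"]
  if (length(ex) == 0) stop("annotation contains no exon features")
  parent <- first_chr(ex$Parent)
  if (anyNA(parent)) stop("exon features without Parent attribute")
  exdf <- data.frame(tx = parent,
                     start = GenomicRanges::start(ex),
                     end = GenomicRanges::end(ex),
                     stringsAsFactors = FALSE)

  skipped <- character(0)
  per_tx <- lapply(split(exdf, exdf$tx), function(d) {
    d <- d[order(d$start), , drop = FALSE]
    if (nrow(d) > 1 && any(d$start[-1] <= d$end[-nrow(d)])) return(NULL)
    span <- d$end[nrow(d)] - d$start[1] + 1L
    exon <- sum(d$end - d$start + 1L)
    list(exon = exon, intron = span - exon, n_introns = nrow(d) - 1L)
  })
  bad <- vapply(per_tx, is.null, logical(1))
  if (any(bad)) {
    skipped <- names(per_tx)[bad]
    warning("rejected ", sum(bad),
            " transcript(s) with overlapping exons: ",
            paste(utils::head(skipped, 5), collapse = ", "))
    per_tx <- per_tx[!bad]
  }
  if (length(per_tx) == 0) stop("no usable transcripts")

  gene <- tx_gene[names(per_tx)]
  gene[is.na(gene)] <- names(per_tx)[is.na(gene)]   # orphan transcripts
  exon_len <- vapply(per_tx, `[[`, numeric(1), "exon")
  # longest transcript per gene: most exonic bp, ties to smaller tx id
  ord <- order(gene, -exon_len, names(per_tx))
  chosen <- !duplicated(gene[ord])
  sel <- names(per_tx)[ord][chosen]

  exon_total <- sum(vapply(per_tx[sel], `[[`, numeric(1), "exon"))
  intron_total <- sum(vapply(per_tx[sel], `[[`, numeric(1), "intron"))
  n_introns <- sum(vapply(per_tx[sel], `[[`, numeric(1), "n_introns"))
  list(exon_total = exon_total, intron_total = intron_total,
       n_genes = length(sel), n_introns = n_introns,
       mean_intron_length = if (n_introns > 0) intron_total / n_introns
                            else NA_real_,
       intron_exon_ratio = intron_total / exon_total,
       skipped_transcripts = skipped)
}
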