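# shared fixture builders -- everything is generated in code at test time

random_seq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# error-free reads tiling a sequence at a fixed stride (deterministic,
# full coverage of every k-mer)
tiled_reads <- function(seq, read_length = 100L, stride = 10L) {
  starts <- unique(c(seq(1L, nchar(seq) - read_length + 1L, by = stride),
                     nchar(seq) - read_length + 1L))
  substring(seq, starts, starts + read_length - 1L)
}

# independent N50 oracle: largest L such that sequences of length >= L
# hold at least `frac` of the total bases (scans candidates directly)
n50_oracle <- function(lens, frac = 0.5) {
  total <- sum(lens)
  cand <- sort(unique(lens), decreasing = TRUE)
  for (L in cand) if (sum(lens[lens >= L]) >= frac * total) return(L)
  min(lens)
}

# random toy gene models + GFF3 writer + per-base classification oracle
make_toy_genes <- function(n_genes, seed) {
  set.seed(seed)
  genes <- list()
  pos <- 1000L
  for (g in seq_len(n_genes)) {
    n_tx <- sample(1:3, 1)
    txs <- list()
    for (t in seq_len(n_tx)) {
      n_ex <- sample(1:6, 1)
      starts <- ends <- integer(n_ex)
      p <- pos + sample(0:200, 1)
      for (e in seq_len(n_ex)) {
        len <- sample(50:400, 1)
        starts[e] <- p
        ends[e] <- p + len - 1L
        p <- ends[e] + sample(30:500, 1)   # next exon after an intron
      }
      txs[[t]] <- data.frame(start = starts, end = ends)
    }
    genes[[g]] <- txs
    pos <- max(vapply(txs, function(d) max(d$end), integer(1))) + 2000L
  }
  genes
}

write_toy_gff3 <- function(genes, path) {
  ln <- "##gff-version 3"
  for (g in seq_along(genes)) {
    gid <- sprintf("g%03d", g)
    gspan <- range(unlist(genes[[g]]))
    ln <- c(ln, sprintf("chr1\ttoy\tgene\t%d\t%d\t.\t+\t.\tID=%s",
                        gspan[1], gspan[2], gid))
    for (t in seq_along(genes[[g]])) {
      tid <- sprintf("%s.t%d", gid, t)
      d <- genes[[g]][[t]]
      ln <- c(ln, sprintf("chr1\ttoy\tmRNA\t%d\t%d\t.\t+\t.\tID=%s;Parent=%s",
                          min(d$start), max(d$end), tid, gid))
      ln <- c(ln, sprintf("chr1\ttoy\texon\t%d\t%d\t.\t+\t.\tParent=%s",
                          d$start, d$end, tid))
    }
  }
  writeLines(ln, path)
  path
}

# per-base oracle: label every genomic base exon/intron for the longest
# (most exonic bp, ties by transcript order) transcript of each gene
toy_gene_totals_oracle <- function(genes) {
  exon_total <- 0L
  intron_total <- 0L
  for (txs in genes) {
    exbp <- vapply(txs, function(d) sum(d$end - d$start + 1L), integer(1))
    best <- txs[[which.max(exbp)]]        # ties: first = smallest tx id
    span <- min(best$start):max(best$end)
    is_exon <- rep(FALSE, length(span))
    for (e in seq_len(nrow(best)))
      is_exon[span >= best$start[e] & span <= best$end[e]] <- TRUE
    exon_total <- exon_total + sum(is_exon)
    intron_total <- intron_total + sum(!is_exon)
  }
  list(exon_total = exon_total, intron_total = intron_total)
}

# definitional regression oracle: explicit covariance sums and the
# closed-form two-sided t CDF for df = 2: P(|T| > t) = 1 - t/sqrt(2 + t^2)
regression_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  syy <- sum((y - mean(y))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  r2 <- sxy^2 / (sxx * syy)
  slope <- sxy / sxx
  t <- sqrt(r2) * sqrt((n - 2) / (1 - r2))
  p <- if (n == 4) 1 - t / sqrt(2 + t^2) else 2 * stats::pt(-abs(t), n - 2)
  list(slope = slope, intercept = mean(y) - slope * mean(x),
       r_squared = r2, p_value = p)
}
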