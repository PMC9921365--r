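test_that("zero-rate genome has identical haplotypes and no annotations", {
  g <- simulate_diploid_genome(10000, het_rate = 0, repeat_fraction = 0,
                               seed = 1)
  expect_identical(g$haplotype_a, g$haplotype_b)
  expect_equal(nrow(g$variants), 0)
  expect_equal(nrow(g$repeats), 0)
  expect_equal(nchar(g$haplotype_a), 10000)
})

test_that("variant fraction matches the binomial expectation", {
  n <- 100000
  p <- 0.01
  g <- simulate_diploid_genome(n, het_rate = p, seed = 7)
  obs <- nrow(g$variants) / n
  expect_lt(abs(obs - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("repeat annotations cover the requested genome fraction", {
  g <- simulate_diploid_genome(50000, het_rate = 0, repeat_fraction = 0.2,
                               repeat_unit_length = 1000, seed = 3)
  covered <- sum(g$repeats$end - g$repeats$start + 1)
  expect_gte(covered / 50000, 0.18)
  expect_lte(covered / 50000, 0.22)
  expect_true(all(g$repeats$start >= 1 & g$repeats$end <= 50000))
})

test_that("repeat density leaving no unique anchors is rejected", {
  expect_error(simulate_diploid_genome(10000, repeat_fraction = 0.5,
                                       repeat_unit_length = 60, seed = 1),
               "anchor")
})

test_that("applying the variant table reproduces haplotype B", {
  for (ind in c(0, 0.3)) {
    g <- simulate_diploid_genome(20000, het_rate = 0.02,
                                 indel_fraction = ind, seed = 5)
    expect_gt(nrow(g$variants), 0)
    expect_true(all(diff(g$variants$pos) > 0))
    expect_identical(apply_variants(g$haplotype_a, g$variants),
                     g$haplotype_b)
  }
})

test_that("generation is deterministic in the seed, including FASTQ bytes", {
  g1 <- simulate_diploid_genome(5000, het_rate = 0.01, seed = 9)
  g2 <- simulate_diploid_genome(5000, het_rate = 0.01, seed = 9)
  expect_identical(g1$haplotype_a, g2$haplotype_a)
  expect_identical(g1$variants, g2$variants)
  lib <- library_spec(300, 30, 75, error_rate = 0.005)
  r1 <- simulate_reads(g1, lib, coverage = 5, seed = 4)
  r2 <- simulate_reads(g2, lib, coverage = 5, seed = 4)
  expect_identical(r1, r2)
  f1 <- write_read_pairs(r1, tempfile())
  f2 <- write_read_pairs(r2, tempfile())
  expect_identical(readLines(f1[1]), readLines(f2[1]))
  expect_identical(readLines(f1[2]), readLines(f2[2]))
})

test_that("pair count matches the coverage formula", {
  g <- simulate_diploid_genome(10000, het_rate = 0, seed = 2)
  rp <- simulate_reads(g, library_spec(500, 50, 100), coverage = 60,
                       seed = 3)
  expect_lt(abs(length(rp$r1) - 3000) / 3000, 0.05)  # 60*10000/(2*100)
})

test_that("error-free reads are exact substrings of a haplotype", {
  g <- simulate_diploid_genome(20000, het_rate = 0.01, seed = 11)
  for (layout in c("paired_end_innie", "mate_pair_outie")) {
    rp <- simulate_reads(g, library_spec(1000, 100, 80, layout = layout),
                         coverage = 2, seed = 12)
    hay <- c(g$haplotype_a, g$haplotype_b,
             revcomp(c(g$haplotype_a, g$haplotype_b)))
    for (r in c(rp$r1[1:50], rp$r2[1:50]))
      expect_true(any(vapply(hay, function(h)
        grepl(r, h, fixed = TRUE), logical(1))))
  }
})

test_that("empirical insert sizes match the library specification", {
  g <- simulate_diploid_genome(50000, het_rate = 0, seed = 13)
  rp <- simulate_reads(g, library_spec(500, 50, 100), coverage = 10,
                       seed = 14)
  p1 <- map_reads(c(gen = g$haplotype_a), rp$r1)
  p2 <- map_reads(c(gen = g$haplotype_a), rp$r2)
  ok <- p1$unique & p2$unique
  ins <- pmax(p1$ref_end, p2$ref_end)[ok] -
    pmin(p1$ref_start, p2$ref_start)[ok] + 1
  expect_gt(sum(ok), 1000)
  expect_lt(abs(mean(ins) - 500), 3 * 50 / sqrt(sum(ok)) + 1)
})

test_that("an insert larger than the genome is rejected", {
  g <- simulate_diploid_genome(1000, het_rate = 0, seed = 1)
  expect_error(simulate_reads(g, library_spec(5000, 100, 100), 10),
               "insert")
})

test_that("library specifications are validated", {
  expect_error(library_spec(150, 10, 100), ">= 2")
  expect_error(library_spec(500, 10, 100, error_rate = 0.5), "error_rate")
})

test_that("fragmenting a homozygous genome yields only unpaired contigs", {
  g <- simulate_diploid_genome(20000, het_rate = 0, seed = 15)
  ctg <- fragment_into_contigs(g, min_len = 500, max_len = 1500, seed = 16)
  expect_true(all(ctg$truth_label == "homozygous"))
  expect_true(all(is.na(ctg$partner_id)))
  expect_identical(paste(ctg$seq, collapse = ""), g$haplotype_a)
})

test_that("one heterozygous block becomes exactly one labelled pair", {
  g <- simulate_diploid_genome(20000, het_rate = 0.0025,
                               het_block_length = 5000,
                               het_block_fraction = 0.25, seed = 17)
  expect_equal(nrow(g$het_blocks), 1)
  ctg <- fragment_into_contigs(g, min_len = 500, max_len = 1500, seed = 18)
  pairs <- ctg[ctg$truth_label == "het_pair", ]
  expect_equal(nrow(pairs), 2)
  expect_identical(sort(pairs$partner_id), sort(pairs$id))
  expect_equal(unique(pairs$truth_start), g$het_blocks$start)
  expect_equal(unique(pairs$truth_end), g$het_blocks$end)
  # the pair carries both haplotype versions of that interval
  a <- pairs$seq[pairs$truth_hap == "A"]
  b <- pairs$seq[pairs$truth_hap == "B"]
  expect_identical(a, substring(g$haplotype_a, g$het_blocks$start,
                                g$het_blocks$end))
  expect_false(identical(a, b))
  # conservation: haplotype-A-derived fragments reconstruct haplotype A
  af <- ctg[ctg$truth_hap == "A", ]
  expect_identical(paste(af$seq[order(af$truth_start)], collapse = ""),
                   g$haplotype_a)
})
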