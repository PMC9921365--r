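mask_fixture <- function(depths, edges) {
  ctg <- contig_set(c(X = random_seq(2000, 301), P = random_seq(3000, 302),
                      Q = random_seq(3000, 303)),
                    depth = depths)
  graph <- structure(list(edges = edges, nodes = data.frame(
    id = ctg$id, het = FALSE, depth = ctg$depth, length = ctg$length),
    spec = library_spec(2000, 150, 100), min_support = 3L),
    class = "link_graph")
  list(ctg = ctg, graph = graph)
}

mk_edge <- function(a, end_a, b, end_b, gap, sd = 50) {
  data.frame(a = a, end_a = end_a, b = b, end_b = end_b,
             orientation = NA_character_, gap_mean = gap, gap_sd = sd,
             support = 5L, stringsAsFactors = FALSE)
}

test_that("masking requires both high depth and conflicting connections", {
  # two neighbours claim the same stretch at X's right end -> conflict
  conflict <- rbind(mk_edge("P", "L", "X", "R", 100),
                    mk_edge("Q", "L", "X", "R", 150))
  fx <- mask_fixture(c(2.2 * 60, 60, 60), conflict)
  rep1 <- mask_duplicated_contigs(fx$ctg, fx$graph, 60)
  expect_true(rep1$masked[rep1$contig_id == "X"])
  expect_false(any(rep1$masked[rep1$contig_id != "X"]))

  # same depth, colinear-compatible links (P then Q fit on one line)
  colinear <- rbind(mk_edge("P", "L", "X", "R", 100, 10),
                    mk_edge("Q", "L", "X", "R", 3500, 10))
  fx2 <- mask_fixture(c(2.2 * 60, 60, 60), colinear)
  rep2 <- mask_duplicated_contigs(fx2$ctg, fx2$graph, 60)
  expect_false(any(rep2$masked))

  # normal depth is never masked regardless of links
  fx3 <- mask_fixture(c(60, 60, 60), conflict)
  rep3 <- mask_duplicated_contigs(fx3$ctg, fx3$graph, 60)
  expect_false(any(rep3$masked))
  expect_true(rep3$conflicting[rep3$contig_id == "X"])
})

test_that("a single contig without links becomes one gap-free scaffold", {
  ctg <- contig_set(c(solo = random_seq(3000, 304)))
  lib <- simulate_reads(random_seq(3000, 304),
                        library_spec(500, 50, 100), 5, seed = 305)
  sset <- hierarchical_scaffold(ctg, lib)
  expect_length(sset$scaffolds, 1)
  expect_equal(nrow(sset$scaffolds[[1]]), 1)
  expect_identical(render_scaffolds(sset)[[1]], ctg$seq[1])
})

test_that("a mate-pair bridge joins two contigs with the right gap", {
  set.seed(306)
  a <- random_seq(6000, 307)
  gapseq <- random_seq(1300, 308)
  b <- random_seq(6000, 309)
  genome <- paste0(a, gapseq, b)
  ctg <- contig_set(c(A = a, B = b))
  mp <- simulate_reads(genome, library_spec(2000, 150, 100,
                                            layout = "mate_pair_outie"),
                       coverage = 20, seed = 310)
  sset <- hierarchical_scaffold(ctg, mp, min_support = 3)
  expect_length(sset$scaffolds, 1)
  df <- sset$scaffolds[[1]]
  expect_equal(nrow(df), 2)
  # estimated gap within 3 SD of the true 1300 bp
  lg <- build_link_graph(ctg, mp, min_support = 3)
  expect_lt(abs(df$gap_after[1] - 1300),
            3 * lg$edges$gap_sd[1] / sqrt(lg$edges$support[1]) + 50)
})

test_that("scaffolding conserves contigs and never lowers N50", {
  g <- simulate_diploid_genome(60000, het_rate = 0, seed = 311)
  ctg <- fragment_into_contigs(g, min_len = 3000, max_len = 5000,
                               seed = 312)
  mp <- simulate_reads(g, library_spec(2000, 200, 100,
                                       layout = "mate_pair_outie"),
                       coverage = 20, seed = 313)
  sset <- hierarchical_scaffold(ctg, mp)
  placed <- unname(unlist(lapply(sset$scaffolds, `[[`, "contig_id")))
  expect_identical(sort(placed), sort(ctg$id))
  scf_n50 <- assembly_stats(render_scaffolds(sset))$N50
  ctg_n50 <- assembly_stats(ctg)$N50
  expect_gte(scf_n50, ctg_n50)
})

test_that("masked contigs stay unplaced", {
  g <- simulate_diploid_genome(30000, het_rate = 0, seed = 314)
  ctg <- fragment_into_contigs(g, min_len = 3000, max_len = 5000,
                               seed = 315)
  mask <- data.frame(contig_id = ctg$id,
                     high_depth = FALSE, conflicting = FALSE,
                     masked = seq_len(nrow(ctg)) == 2)
  mp <- simulate_reads(g, library_spec(2000, 200, 100,
                                       layout = "mate_pair_outie"),
                       coverage = 15, seed = 316)
  sset <- hierarchical_scaffold(ctg, mp, mask = mask)
  placed <- unlist(lapply(sset$scaffolds, `[[`, "contig_id"))
  expect_false(ctg$id[2] %in% placed)
  expect_identical(sset$unplaced, ctg$id[2])
})

test_that("gap closing fills a unique 500 bp gap at high identity", {
  set.seed(317)
  a <- random_seq(5000, 318)
  gapseq <- random_seq(500, 319)
  b <- random_seq(5000, 320)
  genome <- paste0(a, gapseq, b)
  ctg <- contig_set(c(A = a, B = b))
  mp <- simulate_reads(genome, library_spec(2000, 150, 100,
                                            layout = "mate_pair_outie"),
                       coverage = 20, seed = 321)
  sset <- hierarchical_scaffold(ctg, mp)
  expect_length(sset$scaffolds, 1)
  pe <- simulate_reads(genome, library_spec(500, 50, 100),
                       coverage = 60, seed = 322)
  res <- close_gaps(sset, pe, k = 31)
  expect_identical(res$report$status, "closed")
  fill <- res$scaffolds$scaffolds[[1]]$fill[1]
  rend <- render_scaffolds(res$scaffolds)[[1]]
  if (rend != genome) {
    rend <- revcomp(rend)
    fill <- revcomp(fill)
  }
  # filled bases at >= 99% identity to the simulated truth
  expect_equal(nchar(fill), 500)
  expect_gte(mean(strsplit(fill, "")[[1]] == strsplit(gapseq, "")[[1]]),
             0.99)
  # non-gap bases byte-identical before vs after
  expect_identical(substring(rend, 1, 5000), a)
  expect_identical(substring(rend, nchar(rend) - 4999, nchar(rend)), b)
})

test_that("a gap with no anchoring reads is left unchanged", {
  ctg <- contig_set(c(A = random_seq(2000, 323), B = random_seq(2000, 324)))
  sset <- structure(list(
    scaffolds = list(scf00001 = data.frame(
      contig_id = c("A", "B"), orient = "+",
      gap_after = c(300, NA), fill = NA_character_,
      stringsAsFactors = FALSE)),
    unplaced = character(0), contigs = ctg, log = character(0)),
    class = "scaffold_set")
  before <- render_scaffolds(sset)
  unrelated <- simulate_reads(random_seq(10000, 325),
                              library_spec(500, 50, 100), 10, seed = 326)
  res <- close_gaps(sset, unrelated, k = 31)
  expect_identical(res$report$status, "open")
  expect_identical(render_scaffolds(res$scaffolds), before)
})

test_that("rendering and AGP agree on scaffold structure", {
  ctg <- contig_set(c(A = random_seq(1000, 327), B = random_seq(800, 328)))
  sset <- structure(list(
    scaffolds = list(scf00001 = data.frame(
      contig_id = c("A", "B"), orient = c("+", "-"),
      gap_after = c(42, NA), fill = NA_character_,
      stringsAsFactors = FALSE)),
    unplaced = character(0), contigs = ctg, log = character(0)),
    class = "scaffold_set")
  rend <- render_scaffolds(sset)
  expect_equal(nchar(rend[[1]]), 1000 + 42 + 800)
  expect_identical(substring(rend[[1]], 1043, 1842), revcomp(ctg$seq[2]))
  agp <- tempfile(fileext = ".agp")
  write_agp(sset, agp)
  ln <- strsplit(readLines(agp)[-1], "\t")
  expect_equal(length(ln), 3)            # W, N, W
  expect_identical(vapply(ln, `[`, "", 5), c("W", "N", "W"))
  expect_equal(as.integer(ln[[3]][3]), nchar(rend[[1]]))
  expect_identical(ln[[3]][9], "-")
})

test_that("reversing a scaffold round-trips", {
  df <- data.frame(contig_id = c("a", "b", "c"), orient = c("+", "-", "+"),
                   gap_after = c(10, 20, NA),
                   fill = c("ACGT", NA, NA), stringsAsFactors = FALSE)
  expect_identical(hetasm:::rev_scaffold_df(hetasm:::rev_scaffold_df(df)), df)
  r <- hetasm:::rev_scaffold_df(df)
  expect_identical(r$contig_id, c("c", "b", "a"))
  expect_identical(r$orient, c("-", "+", "-"))
  expect_identical(r$gap_after, c(20, 10, NA))
  expect_identical(r$fill, c(NA, "ACGT", NA))
})
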