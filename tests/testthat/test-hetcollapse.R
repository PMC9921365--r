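fake_estimate <- function(hom_peak) {
  structure(list(genome_size = NA, heterozygosity = NA,
                 hom_peak_depth = hom_peak, het_peak_depth = NA,
                 error_cutoff = 1), class = "genome_estimate")
}

two_contigs <- function() {
  contig_set(c(A = random_seq(1000, 201), B = random_seq(1000, 202)),
             depth = c(60, 60))
}

# hand-built placement rows (bypassing the mapper) for link-rule tests
placement <- function(ref, pos, strand) {
  data.frame(read = "r", ref = ref, pos = pos, strand = strand,
             matches = 100L, overlap = 100L, second_matches = 0L,
             unique = TRUE, ref_start = pmax(1L, pos),
             ref_end = pos + 99L, stringsAsFactors = FALSE)
}

test_that("depth classification uses a strict less-than threshold", {
  ctg <- contig_set(c(c1 = random_seq(1000, 203), c2 = random_seq(1000, 204)),
                    depth = c(58, 62))
  cl <- classify_heterozygous(ctg, depth_threshold = 60)
  expect_identical(cl$het, c(TRUE, FALSE))
  cl60 <- classify_heterozygous(contig_set(c(x = random_seq(500, 1)),
                                           depth = 60),
                                depth_threshold = 60)
  expect_false(cl60$het)          # depth exactly 60 is not heterozygous
})

test_that("classification handles the all-homozygous and auto-ratio cases", {
  ctg <- contig_set(c(a = random_seq(500, 205), b = random_seq(500, 206)),
                    depth = c(80, 95))
  expect_false(any(classify_heterozygous(ctg, depth_threshold = 60)$het))
  cl <- classify_heterozygous(ctg, auto_ratio = 0.75,
                              estimate = fake_estimate(80))
  expect_equal(attr(cl, "depth_threshold"), 60)
  expect_error(classify_heterozygous(ctg, depth_threshold = 0), "positive")
  expect_error(classify_heterozygous(ctg), "exactly one")
  expect_error(classify_heterozygous(ctg, depth_threshold = 60,
                                     auto_ratio = 0.75), "exactly one")
})

test_that("edges need at least three concordant, same-orientation pairs", {
  ctg <- two_contigs()
  spec <- library_spec(500, 50, 100)
  conc <- function(n) list(
    p1 = do.call(rbind, replicate(n, placement("A", 700, "+"),
                                  simplify = FALSE)),
    p2 = do.call(rbind, replicate(n, placement("B", 100, "-"),
                                  simplify = FALSE)))
  rp <- structure(list(r1 = character(0), r2 = character(0), spec = spec),
                  class = "read_pairs")
  g3 <- build_link_graph(ctg, rp, placements = conc(3))
  expect_equal(nrow(g3$edges), 1)
  expect_equal(g3$edges$support, 3)
  expect_equal(g3$edges$orientation, "forward-forward")
  g2 <- build_link_graph(ctg, rp, placements = conc(2))
  expect_equal(nrow(g2$edges), 0)
  # 2 + 1 pairs split across two orientation strata: both below threshold
  mix <- conc(2)
  mix$p1 <- rbind(mix$p1, placement("A", 700, "+"))
  mix$p2 <- rbind(mix$p2, placement("B", 100, "+"))
  gm <- build_link_graph(ctg, rp, placements = mix)
  expect_equal(nrow(gm$edges), 0)
})

test_that("gap estimates follow the insert-geometry arithmetic", {
  ctg <- two_contigs()
  spec <- library_spec(2000, 150, 100)
  rp <- structure(list(r1 = character(0), r2 = character(0), spec = spec),
                  class = "read_pairs")
  # mates 300 bp and 400 bp from the inward ends: gap = 2000 - 300 - 400
  pl <- list(
    p1 = do.call(rbind, replicate(3, placement("A", 1000 - 300 + 1, "+"),
                                  simplify = FALSE)),
    p2 = do.call(rbind, replicate(3, placement("B", 400 - 100 + 1, "-"),
                                  simplify = FALSE)))
  g <- build_link_graph(ctg, rp, placements = pl)
  expect_equal(g$edges$gap_mean, 1300)
})

test_that("a read-pairs object without insert statistics is rejected", {
  ctg <- two_contigs()
  bad <- structure(list(r1 = "ACGT", r2 = "ACGT", spec = NULL),
                   class = "read_pairs")
  expect_error(build_link_graph(ctg, bad), "insert")
})

fixture_graph <- function(edges) {
  nodes <- data.frame(
    id = c("H1", "H2", "H3", "U1", "U2"),
    het = c(TRUE, TRUE, TRUE, FALSE, FALSE),
    depth = c(30, 30, 30, 60, 60), length = c(1200, 1100, 1000, 5000, 5000),
    stringsAsFactors = FALSE)
  structure(list(edges = edges, nodes = nodes,
                 spec = library_spec(500, 50, 100), min_support = 3L),
            class = "link_graph")
}

edge_row <- function(a, end_a, b, end_b, gap, sd) {
  data.frame(a = a, end_a = end_a, b = b, end_b = end_b,
             orientation = NA_character_, gap_mean = gap, gap_sd = sd,
             support = 5L, stringsAsFactors = FALSE)
}

test_that("bubble clustering needs shared flanks, orientation and distance", {
  # H1, H2 agree on both flanks -> one cluster; H3 disagrees in
  # orientation at its only shared flank -> excluded
  e <- rbind(edge_row("H1", "L", "U1", "R", 150, 30),
             edge_row("H2", "L", "U1", "R", 140, 35),
             edge_row("H1", "R", "U2", "L", 200, 30),
             edge_row("H2", "R", "U2", "L", 190, 30),
             edge_row("H3", "L", "U1", "L", 150, 30))
  cl <- cluster_bubbles(fixture_graph(e))
  expect_length(cl, 1)
  expect_identical(cl[[1]]$members, c("H1", "H2"))
  expect_identical(cl[[1]]$flanks, c("U1", "U2"))
  expect_false(cl[[1]]$multi_member)
})

test_that("distant gap intervals prevent co-clustering", {
  e <- rbind(edge_row("H1", "L", "U1", "R", 100, 10),
             edge_row("H2", "L", "U1", "R", 500, 10))
  expect_length(cluster_bubbles(fixture_graph(e)), 0)
  # same means, wide SDs -> intervals overlap -> cluster
  e2 <- rbind(edge_row("H1", "L", "U1", "R", 100, 80),
              edge_row("H2", "L", "U1", "R", 500, 80))
  expect_length(cluster_bubbles(fixture_graph(e2)), 1)
})

test_that("three mutually consistent contigs form one multi-member cluster", {
  e <- rbind(edge_row("H1", "L", "U1", "R", 150, 30),
             edge_row("H2", "L", "U1", "R", 140, 30),
             edge_row("H3", "L", "U1", "R", 145, 30))
  cl <- cluster_bubbles(fixture_graph(e))
  expect_length(cl, 1)
  expect_identical(cl[[1]]$members, c("H1", "H2", "H3"))
  expect_true(cl[[1]]$multi_member)
})

test_that("collapse keeps the longer member and reports the removal", {
  ctg <- contig_set(c(H1 = random_seq(1200, 207), H2 = random_seq(1100, 208),
                      U1 = random_seq(5000, 209)),
                    depth = c(30, 30, 60))
  cl <- list(list(members = c("H1", "H2"), flanks = "U1",
                  identity = NA, multi_member = FALSE))
  res <- collapse_bubbles(ctg, cl)
  expect_identical(res$report$removed_id, "H2")
  expect_identical(res$report$retained_id, "H1")
  expect_identical(sort(res$contigs$id), c("H1", "U1"))
  # removal never increases assembly size; retained >= removed
  expect_lte(sum(res$contigs$length), sum(ctg$length))
  expect_gte(res$report$retained_length, res$report$removed_length)
})

test_that("collapse tie-breaks are depth, then lexicographic id", {
  ctg <- contig_set(c(Hb = random_seq(1000, 210), Ha = random_seq(1000, 211)),
                    depth = c(35, 30))
  cl <- list(list(members = c("Ha", "Hb"), flanks = character(0),
                  identity = NA, multi_member = FALSE))
  expect_identical(collapse_bubbles(ctg, cl)$report$retained_id, "Hb")
  ctg$depth <- c(30, 30)
  expect_identical(collapse_bubbles(ctg, cl)$report$retained_id, "Ha")
})

test_that("an empty cluster list is the identity; overlap is an error", {
  ctg <- two_contigs()
  res <- collapse_bubbles(ctg, list())
  expect_identical(res$contigs, ctg)
  expect_equal(nrow(res$report), 0)
  ov <- list(list(members = c("A", "B"), multi_member = FALSE),
             list(members = c("B", "A"), multi_member = FALSE))
  expect_error(collapse_bubbles(ctg, ov), "overlap")
})
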