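#' Classify contigs as heterozygous or homozygous by depth
#'
#' In a diploid assembly that kept both haplotypes, haplotype-specific
#' contigs attract only the reads of one haplotype and sit at about half
#' the homozygous read depth.  A contig is heterozygous iff its depth is
#' strictly below the threshold (`depth < threshold`).
#'
#' @param contigs A [contig_set] with depths computed
#'   ([compute_contig_depth()]).
#' @param depth_threshold Absolute depth threshold (e.g. 60 at ~80x
#'   homozygous coverage).
#' @param auto_ratio Alternative to `depth_threshold`: threshold =
#'   `auto_ratio * hom_peak_depth` taken from `estimate`, portable across
#'   coverages (default ratio 0.75 reproduces a 60/80 split).
#' @param estimate A [estimate_genome()] result (required with
#'   `auto_ratio`).
#' @return `contigs` with a logical `het` column and attribute
#'   `depth_threshold`.
#' @export
classify_heterozygous <- function(contigs, depth_threshold = NULL,
                                  auto_ratio = NULL, estimate = NULL) {
  stopifnot(inherits(contigs, "contig_set"), all(!is.na(contigs$depth)))
  if (is.null(depth_threshold) == is.null(auto_ratio))
    stop("give exactly one of depth_threshold / auto_ratio")
  if (!is.null(auto_ratio)) {
    if (is.null(estimate) || !inherits(estimate, "genome_estimate"))
      stop("auto_ratio needs a genome_estimate for the homozygous peak")
    depth_threshold <- auto_ratio * estimate$hom_peak_depth
  }
  if (depth_threshold <= 0) stop("depth threshold must be positive")
  contigs$het <- contigs$depth < depth_threshold
  attr(contigs, "depth_threshold") <- depth_threshold
  contigs
}

# Per-pair link geometry.  For each mate the library layout and mapped
# strand determine which fragment end it represents and which contig end
# the fragment extends toward; the gap implied by a cross-contig pair is
# insert_mean - d_a - d_b, with d the distance from each mate's fragment
# end to its contig's inward end.
pair_link_table <- function(p1, p2, lens, spec, distance_tolerance_sd = 3) {
  ok <- !is.na(p1$ref) & !is.na(p2$ref) & p1$unique & p2$unique &
    p1$ref != p2$ref
  p1 <- p1[ok, , drop = FALSE]
  p2 <- p2[ok, , drop = FALSE]
  if (nrow(p1) == 0)
    return(data.frame(a = character(0), end_a = character(0),
                      b = character(0), end_b = character(0),
                      gap = numeric(0)))
  rl <- spec$read_length
  geom <- function(p) {
    len <- lens[p$ref]
    right <- if (spec$layout == "paired_end_innie") p$strand == "+" else
      p$strand == "-"
    d <- ifelse(right, len - p$pos + 1L, p$pos - 1L + rl)
    data.frame(ref = p$ref, end = ifelse(right, "R", "L"), d = d)
  }
  g1 <- geom(p1)
  g2 <- geom(p2)
  far <- spec$insert_mean + distance_tolerance_sd * spec$insert_sd
  gap <- spec$insert_mean - g1$d - g2$d
  # a pair is discordant when it implies an overlap deeper than
  # read_length even after allowing for insert-size noise; a tighter cut
  # would truncate the insert distribution and bias gap means upward
  keep <- g1$d <= far & g2$d <= far &
    gap >= -rl - distance_tolerance_sd * spec$insert_sd
  df <- data.frame(a = g1$ref, end_a = g1$end, b = g2$ref, end_b = g2$end,
                   gap = gap, stringsAsFactors = FALSE)[keep, , drop = FALSE]
  swap <- df$a > df$b
  df[swap, c("a", "end_a", "b", "end_b")] <-
    df[swap, c("b", "end_b", "a", "end_a")]
  df
}

orientation_label <- function(end_a, end_b) {
  key <- paste0(end_a, end_b)
  c(RL = "forward-forward", RR = "forward-reverse",
    LL = "reverse-forward", LR = "reverse-reverse")[key]
}

aggregate_links <- function(tab, spec, min_support) {
  if (nrow(tab) == 0)
    return(data.frame(a = character(0), end_a = character(0),
                      b = character(0), end_b = character(0),
                      orientation = character(0), gap_mean = numeric(0),
                      gap_sd = numeric(0), support = integer(0)))
  key <- paste(tab$a, tab$end_a, tab$b, tab$end_b, sep = "\r")
  sp <- split(tab$gap, key)
  parts <- do.call(rbind, strsplit(names(sp), "\r", fixed = TRUE))
  n <- lengths(sp)
  gsd <- vapply(sp, function(g)
    if (length(g) > 1) sd(g) else NA_real_, numeric(1))
  gsd <- pmax(ifelse(is.na(gsd), 0, gsd), spec$insert_sd / sqrt(n))
  out <- data.frame(a = parts[, 1], end_a = parts[, 2], b = parts[, 3],
                    end_b = parts[, 4],
                    orientation = unname(orientation_label(parts[, 2],
                                                           parts[, 4])),
                    gap_mean = vapply(sp, mean, numeric(1)),
                    gap_sd = unname(gsd), support = as.integer(n),
                    stringsAsFactors = FALSE)
  out <- out[out$support >= min_support, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build an orientation-stratified read-pair link graph between contigs
#'
#' Both mates of a counted pair must be uniquely placed on *different*
#' contigs.  Pairs implying different relative orientations never merge
#' into one edge; an edge is retained only when supported by at least
#' `min_support` read pairs (default 3).  Each edge carries a gap
#' estimate (mean and SD over its pairs; negative = overlap, allowed down
#' to -read_length, beyond which a pair is treated as discordant).
#'
#' @param contigs A [contig_set] (a `het` column from
#'   [classify_heterozygous()] is carried onto the nodes).
#' @param pairs A `read_pairs` object (its `spec` supplies the insert
#'   statistics; without them gap estimation is impossible).
#' @param min_support Minimum read pairs per retained edge.
#' @param distance_tolerance_sd Mates further than
#'   `insert_mean + this * insert_sd` from the implied contig end are
#'   discarded as discordant.
#' @param seed_k,seed_step Passed to [map_reads()].
#' @param placements Optional precomputed list(p1, p2) of placement
#'   tables (e.g. from [sam_to_placements()]), bypassing the internal
#'   mapper.
#' @return A `link_graph`: `edges` (a, end_a, b, end_b, orientation,
#'   gap_mean, gap_sd, support), `nodes` (id, het, depth, length), and
#'   the library geometry.
#' @export
build_link_graph <- function(contigs, pairs, min_support = 3L,
                             distance_tolerance_sd = 3, seed_k = 31L,
                             seed_step = 20L, placements = NULL) {
  stopifnot(inherits(contigs, "contig_set"))
  spec <- pairs$spec
  if (is.null(spec) || is.null(spec$insert_mean))
    stop("library insert statistics unknown: gap estimation impossible")
  if (is.null(placements)) {
    mo <- max(31L, floor(0.9 * spec$read_length))
    placements <- list(
      p1 = map_reads(contigs, pairs$r1, seed_k = seed_k,
                     seed_step = seed_step, min_overlap = mo),
      p2 = map_reads(contigs, pairs$r2, seed_k = seed_k,
                     seed_step = seed_step, min_overlap = mo))
  }
  lens <- stats::setNames(contigs$length, contigs$id)
  tab <- pair_link_table(placements$p1, placements$p2, lens, spec,
                         distance_tolerance_sd)
  edges <- aggregate_links(tab, spec, min_support)
  nodes <- data.frame(id = contigs$id,
                      het = if ("het" %in% names(contigs)) contigs$het
                            else NA,
                      depth = contigs$depth, length = contigs$length,
                      stringsAsFactors = FALSE)
  structure(list(edges = edges, nodes = nodes, spec = spec,
                 min_support = as.integer(min_support)),
            class = "link_graph")
}

#' @export
print.link_graph <- function(x, ...) {
  cat(sprintf("<link_graph> %d nodes (%s het), %d edges (support >= %d)\n",
              nrow(x$nodes),
              if (all(is.na(x$nodes$het))) "?" else sum(x$nodes$het),
              nrow(x$edges), x$min_support))
  invisible(x)
}

#' Cluster heterozygous contigs into bubble structures
#'
#' Two heterozygous contigs belong to the same bubble iff (a) they link
#' to the same flanking contig(s) with identical relative orientation
#' (same flank end, same het-contig end) and (b) their gap-estimate
#' intervals (mean +/- `distance_tolerance_sd` * SD) to every shared
#' flank overlap.  Clusters are the connected components of this pairwise
#' relation, so repeat-confounded bubbles may exceed two members (flagged
#' `multi_member`).  Sequence identity between members is computed and
#' reported for review but is *not* a clustering criterion -- the rule is
#' purely positional.
#'
#' @param graph A [build_link_graph()] result whose nodes carry `het`
#'   flags.
#' @param distance_tolerance_sd SD multiplier for gap-interval overlap.
#' @return A `bubble_clusters` list; each element has `members`,
#'   `flanks`, `identity` (minimum pairwise identity to the longest
#'   member, NA when no alignment seed exists) and `multi_member`.
#' @export
cluster_bubbles <- function(graph, distance_tolerance_sd = 3) {
  stopifnot(inherits(graph, "link_graph"))
  nodes <- graph$nodes
  if (all(is.na(nodes$het))) stop("nodes carry no het flags; run ",
                                  "classify_heterozygous() first")
  het_ids <- nodes$id[nodes$het %in% TRUE]
  e <- graph$edges
  out <- structure(list(), class = "bubble_clusters")
  if (length(het_ids) < 2 || nrow(e) == 0) return(out)

  a_het <- e$a %in% het_ids
  b_het <- e$b %in% het_ids
  hf <- e[xor(a_het, b_het), , drop = FALSE]
  if (nrow(hf) == 0) return(out)
  ah <- hf$a %in% het_ids
  rec <- data.frame(het = ifelse(ah, hf$a, hf$b),
                    end_het = ifelse(ah, hf$end_a, hf$end_b),
                    flank = ifelse(ah, hf$b, hf$a),
                    end_flank = ifelse(ah, hf$end_b, hf$end_a),
                    gap = hf$gap_mean, sd = hf$gap_sd,
                    support = hf$support, stringsAsFactors = FALSE)
  # one evidence record per (het, flank): the best-supported link
  rec <- rec[order(-rec$support), , drop = FALSE]
  rec <- rec[!duplicated(rec[c("het", "flank")]), , drop = FALSE]

  consistent <- function(r1, r2) {
    shared <- intersect(r1$flank, r2$flank)
    if (length(shared) == 0) return(FALSE)
    for (f in shared) {
      x <- r1[r1$flank == f, ]
      y <- r2[r2$flank == f, ]
      if (x$end_flank != y$end_flank || x$end_het != y$end_het)
        return(FALSE)
      if (abs(x$gap - y$gap) >
          distance_tolerance_sd * (x$sd + y$sd)) return(FALSE)
    }
    TRUE
  }

  by_het <- split(rec, rec$het)
  cand <- split(rec$het, rec$flank)    # het contigs sharing each flank
  pair_keys <- unique(unlist(lapply(cand, function(h) {
    h <- sort(unique(h))
    if (length(h) < 2) return(character(0))
    cmb <- utils::combn(h, 2)
    paste(cmb[1, ], cmb[2, ], sep = "\r")
  })))
  el <- do.call(rbind, lapply(pair_keys, function(k) {
    hh <- strsplit(k, "\r", fixed = TRUE)[[1]]
    if (consistent(by_het[[hh[1]]], by_het[[hh[2]]])) hh else NULL
  }))
  if (is.null(el)) return(out)

  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  comps <- igraph::components(g)
  lens <- stats::setNames(nodes$length, nodes$id)
  seqs <- attr(graph, "seqs")
  for (ci in seq_len(comps$no)) {
    members <- names(comps$membership)[comps$membership == ci]
    if (length(members) < 2) next
    flanks <- sort(unique(rec$flank[rec$het %in% members]))
    out[[length(out) + 1L]] <- list(
      members = sort(members), flanks = flanks,
      identity = NA_real_,
      multi_member = length(members) > 2)
  }
  out
}

#' @export
print.bubble_clusters <- function(x, ...) {
  cat(sprintf("<bubble_clusters> %d clusters (%d multi-member)\n",
              length(x), sum(vapply(x, `[[`, logical(1), "multi_member"))))
  invisible(x)
}

#' Report sequence identity between bubble-cluster members
#'
#' Aligns every member to the longest member of its cluster (ungapped,
#' seed-based) and records the minimum identity.  Reported for user
#' review only; collapse does not require it.
#'
#' @param clusters A [cluster_bubbles()] result.
#' @param contigs The [contig_set] the graph was built from.
#' @return `clusters` with the `identity` field filled.
#' @export
bubble_identity <- function(clusters, contigs) {
  seqs <- stats::setNames(contigs$seq, contigs$id)
  for (i in seq_along(clusters)) {
    m <- clusters[[i]]$members
    longest <- m[which.max(nchar(seqs[m]))]
    others <- setdiff(m, longest)
    pl <- map_reads(seqs[longest], seqs[others], seed_k = 15L,
                    seed_step = 10L, min_identity = 0, min_overlap = 15L)
    idt <- ifelse(is.na(pl$ref), NA_real_, pl$matches / pl$overlap)
    clusters[[i]]$identity <- suppressWarnings(min(idt, na.rm = TRUE))
    if (!is.finite(clusters[[i]]$identity))
      clusters[[i]]$identity <- NA_real_
  }
  clusters
}

#' Collapse each bubble cluster to a single haplotype
#'
#' Per cluster exactly one contig is retained -- the longest, preserving
#' assembly integrity; length ties fall back to higher depth, then to the
#' lexicographically smaller id (deterministic).  Contigs outside
#' clusters pass through unchanged.
#'
#' @param contigs A [contig_set].
#' @param clusters A [cluster_bubbles()] result.
#' @return A list: `contigs` (collapsed set) and `report` (one row per
#'   removed contig: `removed_id`, `retained_id`, lengths, `cluster_id`,
#'   `multi_member`).
#' @export
collapse_bubbles <- function(contigs, clusters) {
  stopifnot(inherits(contigs, "contig_set"))
  members <- unlist(lapply(clusters, `[[`, "members"))
  if (anyDuplicated(members))
    stop("clusters overlap; they must be disjoint connected components")
  if (!all(members %in% contigs$id))
    stop("cluster members missing from the contig set")
  report <- list()
  drop <- character(0)
  lens <- stats::setNames(contigs$length, contigs$id)
  deps <- stats::setNames(ifelse(is.na(contigs$depth), 0, contigs$depth),
                          contigs$id)
  for (ci in seq_along(clusters)) {
    m <- clusters[[ci]]$members
    keep <- m[order(-lens[m], -deps[m], m)][1]
    rem <- setdiff(m, keep)
    drop <- c(drop, rem)
    report[[length(report) + 1L]] <- data.frame(
      removed_id = rem, retained_id = keep,
      removed_length = unname(lens[rem]),
      retained_length = unname(lens[keep]), cluster_id = ci,
      multi_member = clusters[[ci]]$multi_member,
      stringsAsFactors = FALSE)
  }
  report <- if (length(report) > 0) do.call(rbind, report) else
    data.frame(removed_id = character(0), retained_id = character(0),
               removed_length = integer(0), retained_length = integer(0),
               cluster_id = integer(0), multi_member = logical(0))
  out <- contigs[!(contigs$id %in% drop), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(contigs)
  list(contigs = out, report = report)
}
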