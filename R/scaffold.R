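#' Mask duplicated contigs before scaffolding
#'
#' A contig is masked iff it has *both* (a) high depth -- more than
#' `high_depth_ratio` times the homozygous peak (default 1.75, between 1x
#' unique and 2x two-copy coverage) -- and (b) conflicting connections:
#' at least two link-graph neighbours at the same contig end whose
#' implied placements cannot coexist (their occupancy intervals, gap to
#' gap + neighbour length widened by the gap-SD tolerance, overlap).
#' Masked contigs are excluded from scaffolding and emitted as unplaced.
#'
#' @param contigs A [contig_set] with depths.
#' @param graph A [build_link_graph()] result.
#' @param estimate A [estimate_genome()] result, or the homozygous peak
#'   depth as a number.
#' @param high_depth_ratio Depth multiplier defining "high depth".
#' @param distance_tolerance_sd SD multiplier when testing interval
#'   overlap.
#' @return A `mask_report` data frame: `contig_id`, `high_depth`,
#'   `conflicting`, `masked` (the conjunction).
#' @export
mask_duplicated_contigs <- function(contigs, graph, estimate,
                                    high_depth_ratio = 1.75,
                                    distance_tolerance_sd = 3) {
  stopifnot(inherits(contigs, "contig_set"), inherits(graph, "link_graph"))
  peak <- if (inherits(estimate, "genome_estimate"))
    estimate$hom_peak_depth else as.numeric(estimate)
  high <- !is.na(contigs$depth) & contigs$depth > high_depth_ratio * peak

  lens <- stats::setNames(contigs$length, contigs$id)
  e <- graph$edges
  conflicting <- stats::setNames(rep(FALSE, nrow(contigs)), contigs$id)
  if (nrow(e) > 0) {
    touch <- rbind(
      data.frame(id = e$a, end = e$end_a, nb = e$b,
                 gap = e$gap_mean, sd = e$gap_sd),
      data.frame(id = e$b, end = e$end_b, nb = e$a,
                 gap = e$gap_mean, sd = e$gap_sd))
    for (grp in split(touch, paste(touch$id, touch$end))) {
      if (length(unique(grp$nb)) < 2) next
      lo <- grp$gap - distance_tolerance_sd * grp$sd
      hi <- grp$gap + lens[grp$nb] + distance_tolerance_sd * grp$sd
      o <- order(lo)
      if (any(lo[o][-1] < cummax(hi[o])[-length(o)]))
        conflicting[grp$id[1]] <- TRUE
    }
  }
  out <- data.frame(contig_id = contigs$id, high_depth = unname(high),
                    conflicting = unname(conflicting[contigs$id]),
                    masked = unname(high & conflicting[contigs$id]),
                    stringsAsFactors = FALSE)
  class(out) <- c("mask_report", "data.frame")
  out
}

new_scaffold_entry <- function(contig_id, orient = "+") {
  data.frame(contig_id = contig_id, orient = orient, gap_after = NA_real_,
             fill = NA_character_, stringsAsFactors = FALSE)
}

rev_scaffold_df <- function(df) {
  n <- nrow(df)
  g <- df$gap_after
  f <- df$fill
  df <- df[n:1, , drop = FALSE]
  df$orient <- ifelse(df$orient == "+", "-", "+")
  if (n > 1) {
    df$gap_after <- c(rev(g[-n]), NA_real_)
    fr <- rev(f[-n])
    fr[!is.na(fr)] <- revcomp(fr[!is.na(fr)])
    df$fill <- c(fr, NA_character_)
  }
  rownames(df) <- NULL
  df
}

render_scaffold_df <- function(df, seqmap) {
  n <- nrow(df)
  parts <- character(2L * n - 1L)
  for (i in seq_len(n)) {
    s <- seqmap[[df$contig_id[i]]]
    parts[2L * i - 1L] <- if (df$orient[i] == "+") s else revcomp(s)
    if (i < n) {
      parts[2L * i] <- if (!is.na(df$fill[i])) df$fill[i] else
        strrep("N", max(1L, as.integer(round(df$gap_after[i]))))
    }
  }
  paste(parts, collapse = "")
}

#' Order and orient contigs into scaffolds, library by library
#'
#' The hierarchical strategy: libraries are processed in ascending insert
#' size, and in each round the current scaffolds' ends are joined
#' greedily (highest support first) using that library's link graph.
#' Later, longer libraries can only join -- never break -- earlier joins,
#' so short-range order is fixed before long-range links are consulted.
#' An end whose two best candidate joins are equally supported is left
#' unjoined and logged as ambiguous.
#'
#' @param contigs A [contig_set].
#' @param libraries A `read_pairs` object or list of them (sorted by
#'   insert size internally; a reordering is messaged).
#' @param min_support Minimum read pairs per join.
#' @param distance_tolerance_sd SD multiplier for discordant-pair
#'   filtering.
#' @param mask Optional [mask_duplicated_contigs()] report; masked
#'   contigs are left unplaced.
#' @param seed_k,seed_step Passed to [map_reads()].
#' @param sort_libraries Enforce ascending insert-size order (default).
#'   `FALSE` processes libraries as given -- only useful for comparing
#'   processing orders.
#' @return A `scaffold_set`: `scaffolds` (list of placement data frames
#'   with `contig_id`, `orient`, `gap_after`, `fill`), `unplaced`
#'   (masked contig ids), `contigs` (the input set) and a join `log`.
#' @export
hierarchical_scaffold <- function(contigs, libraries, min_support = 3L,
                                  distance_tolerance_sd = 3, mask = NULL,
                                  seed_k = 31L, seed_step = 20L,
                                  sort_libraries = TRUE) {
  stopifnot(inherits(contigs, "contig_set"), nrow(contigs) > 0)
  if (inherits(libraries, "read_pairs")) libraries <- list(libraries)
  ins <- vapply(libraries, function(l) l$spec$insert_mean, numeric(1))
  if (sort_libraries && is.unsorted(ins)) {
    message("libraries reordered by ascending insert size")
    libraries <- libraries[order(ins)]
  }
  unplaced <- character(0)
  if (!is.null(mask)) unplaced <- mask$contig_id[mask$masked]
  active <- contigs[!(contigs$id %in% unplaced), , drop = FALSE]
  seqmap <- as.list(stats::setNames(active$seq, active$id))

  cur <- lapply(active$id, function(id) list(
    df = new_scaffold_entry(id),
    left_tag = paste0(id, ":L"), right_tag = paste0(id, ":R")))
  tag2cur <- new.env(parent = emptyenv())
  for (i in seq_along(cur)) {
    assign(cur[[i]]$left_tag, i, envir = tag2cur)
    assign(cur[[i]]$right_tag, i, envir = tag2cur)
  }
  log <- character(0)

  for (lib in libraries) {
    spec <- lib$spec
    live <- which(!vapply(cur, is.null, logical(1)))
    rendered <- vapply(live, function(i)
      render_scaffold_df(cur[[i]]$df, seqmap), character(1))
    names(rendered) <- as.character(live)
    mo <- max(31L, floor(0.9 * spec$read_length))
    p1 <- map_reads(rendered, lib$r1, seed_k = seed_k,
                    seed_step = seed_step, min_overlap = mo)
    p2 <- map_reads(rendered, lib$r2, seed_k = seed_k,
                    seed_step = seed_step, min_overlap = mo)
    lens <- stats::setNames(nchar(rendered), names(rendered))
    tab <- pair_link_table(p1, p2, lens, spec, distance_tolerance_sd)
    edges <- aggregate_links(tab, spec, min_support)
    if (nrow(edges) == 0) next

    # ends whose top two candidate joins tie in support are ambiguous
    endkey <- c(paste0(edges$a, ":", edges$end_a),
                paste0(edges$b, ":", edges$end_b))
    sup <- c(edges$support, edges$support)
    amb <- vapply(split(sup, endkey), function(s)
      length(s) > 1 && sort(s, decreasing = TRUE)[1] ==
        sort(s, decreasing = TRUE)[2], logical(1))
    ambiguous <- names(amb)[amb]
    if (length(ambiguous) > 0)
      log <- c(log, sprintf("insert %g: ambiguous end %s",
                            spec$insert_mean, ambiguous))

    edges <- edges[order(-edges$support, edges$gap_sd, edges$a,
                         edges$end_a, edges$b, edges$end_b), , drop = FALSE]
    # snapshot the exposure tags of this round's scaffold ends: merges
    # during the loop must not re-interpret edge endpoints
    tags <- lapply(cur, function(s) if (is.null(s)) NULL else
      c(L = s$left_tag, R = s$right_tag))
    for (i in seq_len(nrow(edges))) {
      ed <- edges[i, ]
      ta <- tags[[as.integer(ed$a)]]
      tb <- tags[[as.integer(ed$b)]]
      if (is.null(ta) || is.null(tb)) next
      tagA <- ta[[ed$end_a]]
      tagB <- tb[[ed$end_b]]
      if (paste0(ed$a, ":", ed$end_a) %in% ambiguous ||
          paste0(ed$b, ":", ed$end_b) %in% ambiguous) next
      if (!exists(tagA, envir = tag2cur) ||
          !exists(tagB, envir = tag2cur)) next
      ia <- get(tagA, envir = tag2cur)
      ib <- get(tagB, envir = tag2cur)
      if (ia == ib) next
      s1 <- cur[[ia]]
      s2 <- cur[[ib]]
      if (s1$right_tag != tagA) {
        s1 <- list(df = rev_scaffold_df(s1$df), left_tag = s1$right_tag,
                   right_tag = s1$left_tag)
      }
      if (s2$left_tag != tagB) {
        s2 <- list(df = rev_scaffold_df(s2$df), left_tag = s2$right_tag,
                   right_tag = s2$left_tag)
      }
      df <- s1$df
      df$gap_after[nrow(df)] <- ed$gap_mean
      df <- rbind(df, s2$df)
      merged <- list(df = df, left_tag = s1$left_tag,
                     right_tag = s2$right_tag)
      cur[[ia]] <- merged
      cur[ib] <- list(NULL)        # keep the slot; indices must not shift
      rm(list = c(tagA, tagB), envir = tag2cur)
      assign(merged$left_tag, ia, envir = tag2cur)
      assign(merged$right_tag, ia, envir = tag2cur)
      log <- c(log, sprintf(
        "insert %g: joined via %s:%s--%s:%s (support %d, gap %.0f)",
        spec$insert_mean, tagA, ed$end_a, tagB, ed$end_b, ed$support,
        ed$gap_mean))
    }
  }

  scafs <- Filter(Negate(is.null), cur)
  dfs <- lapply(scafs, `[[`, "df")
  tot <- vapply(dfs, function(d)
    sum(nchar(unlist(seqmap[d$contig_id]))), numeric(1))
  dfs <- dfs[order(-tot)]
  names(dfs) <- sprintf("scf%05d", seq_along(dfs))
  structure(list(scaffolds = dfs, unplaced = unplaced, contigs = contigs,
                 log = log),
            class = "scaffold_set")
}

#' @export
print.scaffold_set <- function(x, ...) {
  n_ctg <- sum(vapply(x$scaffolds, nrow, integer(1)))
  cat(sprintf("<scaffold_set> %d scaffolds holding %d contigs (%d unplaced)\n",
              length(x$scaffolds), n_ctg, length(x$unplaced)))
  invisible(x)
}

#' Render scaffolds to sequences
#'
#' Contigs are emitted in order and orientation; unfilled gaps become N
#' runs of length `max(1, round(gap_estimate))`, filled gaps their fill
#' sequence.
#'
#' @param sset A [hierarchical_scaffold()] result.
#' @return Named character vector of scaffold sequences.
#' @export
render_scaffolds <- function(sset) {
  stopifnot(inherits(sset, "scaffold_set"))
  seqmap <- as.list(stats::setNames(sset$contigs$seq, sset$contigs$id))
  vapply(sset$scaffolds, render_scaffold_df, character(1), seqmap = seqmap)
}

#' Write scaffold structure as AGP v2.1
#'
#' One `W` line per contig placement and one gap line per junction: `N`
#' for gaps with a positive size estimate, `U` for gaps rendered at the
#' 1 bp minimum because the estimate was negative or unavailable.
#' Filled gaps are written as `N` lines of the fill length (the AGP
#' describes scaffold structure; rendered sequence carries the fill).
#'
#' @param sset A [hierarchical_scaffold()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_agp <- function(sset, path) {
  stopifnot(inherits(sset, "scaffold_set"))
  lens <- stats::setNames(sset$contigs$length, sset$contigs$id)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##agp-version\t2.1", con)
  for (sn in names(sset$scaffolds)) {
    df <- sset$scaffolds[[sn]]
    pos <- 1L
    part <- 1L
    for (i in seq_len(nrow(df))) {
      clen <- lens[[df$contig_id[i]]]
      writeLines(paste(sn, pos, pos + clen - 1L, part, "W",
                       df$contig_id[i], 1L, clen, df$orient[i],
                       sep = "\t"), con)
      pos <- pos + clen
      part <- part + 1L
      if (i < nrow(df)) {
        est <- df$gap_after[i]
        glen <- if (!is.na(df$fill[i])) max(1L, nchar(df$fill[i])) else
          max(1L, as.integer(round(est)))
        type <- if (!is.na(df$fill[i]) || (!is.na(est) && est >= 1))
          "N" else "U"
        writeLines(paste(sn, pos, pos + glen - 1L, part, type, glen,
                         "scaffold", "yes", "paired-ends", sep = "\t"), con)
        pos <- pos + glen
        part <- part + 1L
      }
    }
  }
  invisible(path)
}

#' Close scaffold gaps by local reassembly from anchored read pairs
#'
#' For each gap, reads whose own or whose mate's unique placement lies
#' within one insert length of the gap are pooled; a flank-anchored
#' greedy k-mer walk extends inward from both sides, and the gap is
#' replaced only when the two walks overlap exactly over at least k-1
#' bases (or one walk spans the gap into the other flank).  Bases
#' outside N runs are never modified; unclosable gaps remain as N runs.
#' Iterates until no gap changes (at most `max_iterations` rounds).
#'
#' @param sset A [hierarchical_scaffold()] result.
#' @param reads A short-insert `read_pairs` object or list of them.
#' @param k Walk k-mer size (default 31).
#' @param max_iterations Maximum closing rounds.
#' @param flank Flank length consulted on each side of a gap, bp.
#' @param min_count Minimum read k-mer multiplicity supporting a walk
#'   step (default 2, suppressing error k-mers).
#' @param seed_k,seed_step Passed to [map_reads()].
#' @return A list: `scaffolds` (updated `scaffold_set`) and `report`
#'   (per gap: scaffold, junction, estimated size, status, fill length,
#'   candidate read count).
#' @export
close_gaps <- function(sset, reads, k = 31L, max_iterations = 3L,
                       flank = 300L, min_count = 2L, seed_k = 31L,
                       seed_step = 20L) {
  stopifnot(inherits(sset, "scaffold_set"))
  if (inherits(reads, "read_pairs")) reads <- list(reads)
  report <- NULL

  for (iter in seq_len(max_iterations)) {
    rendered <- render_scaffolds(sset)
    lens <- stats::setNames(sset$contigs$length, sset$contigs$id)
    changed <- 0L
    report <- list()
    # pool unique placements of every library, tagged by pair
    anchors <- list()
    for (li in seq_along(reads)) {
      lib <- reads[[li]]
      mo <- max(31L, floor(0.9 * lib$spec$read_length))
      p1 <- map_reads(rendered, lib$r1, seed_k = seed_k,
                      seed_step = seed_step, min_overlap = mo)
      p2 <- map_reads(rendered, lib$r2, seed_k = seed_k,
                      seed_step = seed_step, min_overlap = mo)
      anchors[[li]] <- list(p1 = p1, p2 = p2, lib = lib)
    }
    win <- max(vapply(reads, function(l)
      l$spec$insert_mean + 3 * l$spec$insert_sd, numeric(1)))

    for (sn in names(sset$scaffolds)) {
      df <- sset$scaffolds[[sn]]
      if (nrow(df) < 2) next
      seq_sc <- rendered[[sn]]
      pos <- 1L
      for (i in seq_len(nrow(df) - 1L)) {
        clen <- lens[[df$contig_id[i]]]
        gstart <- pos + clen
        glen <- if (!is.na(df$fill[i])) nchar(df$fill[i]) else
          max(1L, as.integer(round(df$gap_after[i])))
        gend <- gstart + glen - 1L
        pos <- gstart + glen
        if (!is.na(df$fill[i])) {             # closed in an earlier round
          report[[length(report) + 1L]] <- data.frame(
            scaffold = sn, junction = i, gap_estimate = df$gap_after[i],
            status = "closed", fill_length = nchar(df$fill[i]),
            n_candidate_reads = NA_integer_, stringsAsFactors = FALSE)
          next
        }

        cand <- character(0)
        for (an in anchors) {
          near1 <- !is.na(an$p1$ref) & an$p1$ref == sn & an$p1$unique &
            an$p1$ref_end >= gstart - win & an$p1$ref_start <= gend + win
          near2 <- !is.na(an$p2$ref) & an$p2$ref == sn & an$p2$unique &
            an$p2$ref_end >= gstart - win & an$p2$ref_start <= gend + win
          sel <- near1 | near2
          cand <- c(cand, unname(an$lib$r1[sel]), unname(an$lib$r2[sel]))
        }
        lf <- substring(seq_sc, max(1L, gstart - flank), gstart - 1L)
        lf <- sub(".*N", "", lf)
        rf <- substring(seq_sc, gend + 1L,
                        min(nchar(seq_sc), gend + flank))
        rf <- sub("N.*", "", rf)
        fill <- if (length(cand) > 0)
          cpp_fill_gap(lf, rf, cand, as.integer(k),
                       as.integer(glen + 1000L), as.integer(min_count))
        else NULL
        closed <- !is.null(fill)
        if (closed) {
          df$fill[i] <- fill
          changed <- changed + 1L
        }
        report[[length(report) + 1L]] <- data.frame(
          scaffold = sn, junction = i,
          gap_estimate = df$gap_after[i],
          status = if (closed) "closed" else "open",
          fill_length = if (closed) nchar(fill) else NA_integer_,
          n_candidate_reads = length(cand), stringsAsFactors = FALSE)
      }
      sset$scaffolds[[sn]] <- df
    }
    if (changed == 0L) break
  }
  report <- if (length(report) > 0) do.call(rbind, report) else
    data.frame(scaffold = character(0), junction = integer(0),
               gap_estimate = numeric(0), status = character(0),
               fill_length = integer(0), n_candidate_reads = integer(0))
  list(scaffolds = sset, report = report)
}
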