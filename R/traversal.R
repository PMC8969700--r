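## Closed-walk traversal: master circles, sub-genome enumeration,
## recombination products, sequence emission and digest prediction.
##
## A closed oriented walk through the terminus graph is one circular genome
## configuration.  The master configuration traverses every repeat twice and
## every other contig once; recombination at a direct repeat splits a master
## into two sub-circles, at an inverted repeat it inverts the inter-mate
## segment.  Enumeration is exhaustive backtracking under per-contig
## traversal budgets with canonical-form deduplication.

WALK_KINDS <- c("master_configuration", "small_subcircle",
                "intermediate_subcircle", "other")

#' Construct and validate a closed walk
#'
#' @param graph an assembly graph.
#' @param steps data.frame (contig_id, orientation) in traversal order; the
#'   walk closes from the last step back to the first.
#' @return a `mito_walk`: steps, junction overlap lengths (one per junction,
#'   the last closing the circle), total length in bp, kind.
#' @export
make_walk <- function(graph, steps) {
  n <- nrow(steps)
  stopifnot(n >= 1)
  ov <- integer(n)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    e <- find_overlap_edge(graph,
                           steps$contig_id[i], exit_side(steps$orientation[i]),
                           steps$contig_id[j], entry_side(steps$orientation[j]))
    if (is.null(e))
      stop("make_walk: no overlap edge for junction ", steps$contig_id[i],
           steps$orientation[i], " -> ", steps$contig_id[j],
           steps$orientation[j])
    ov[i] <- e$overlap_length
  }
  lens <- vapply(steps$contig_id,
                 function(id) graph$contigs[[id]]$length, integer(1))
  w <- structure(list(steps = steps, junction_overlaps = ov,
                      length = sum(lens) - sum(ov), kind = "other"),
                 class = "mito_walk")
  w$kind <- classify_walk(w, graph)
  w
}

find_overlap_edge <- function(graph, c1, s1, c2, s2) {
  o <- orient_edge_endpoints(c1, s1, c2, s2)
  e <- graph$edges
  hit <- e$kind == "overlap" & e$c1 == o$c1 & e$s1 == o$s1 &
    e$c2 == o$c2 & e$s2 == o$s2
  if (!any(hit)) return(NULL)
  e[which(hit)[1], ]
}

#' @export
print.mito_walk <- function(x, ...) {
  cat("mito_walk (", x$kind, "): ",
      paste0(x$steps$contig_id, x$steps$orientation, collapse = " "),
      " | ", x$length, " bp\n", sep = "")
  invisible(x)
}

#' Canonical form of a closed oriented walk
#'
#' The lexicographically smallest string over all rotations of the oriented
#' step sequence and of its reverse complement (reversed order, flipped
#' orientations), making walk identity invariant under rotation and strand.
#'
#' @param steps data.frame (contig_id, orientation).
#' @return a single string key.
#' @export
canonical_walk_key <- function(steps) {
  fwd <- paste0(steps$contig_id, steps$orientation)
  rev_ <- paste0(rev(steps$contig_id), flip_orientation(rev(steps$orientation)))
  n <- length(fwd)
  best <- NULL
  for (v in list(fwd, rev_)) {
    for (r in seq_len(n)) {
      rot <- paste(c(v[r:n], v[seq_len(r - 1L)]), collapse = ";")
      if (is.null(best) || rot < best) best <- rot
    }
  }
  best
}

classify_walk <- function(walk, graph) {
  roles <- vapply(graph$contigs, `[[`, character(1), "role")
  reps <- names(roles)[roles == "repeat"]
  others <- names(roles)[roles != "repeat"]
  cnt <- table(factor(walk$steps$contig_id, levels = names(roles)))
  if (all(cnt[reps] == 2) && all(cnt[others] == 1))
    return("master_configuration")
  visited_others <- others[cnt[others] > 0]
  proper_subset <- length(visited_others) < length(others) &&
    all(cnt[visited_others] == 1)
  if (all(cnt[reps] <= 1) && proper_subset) return("small_subcircle")
  if (length(reps) && all(cnt[reps] >= 1) && proper_subset)
    return("intermediate_subcircle")
  "other"
}

walk_adjacency <- function(graph) {
  oe <- overlap_edges_of(graph)
  adj <- list()
  push <- function(c1, s1, c2, s2, ov, eid) {
    k <- terminus_key(c1, s1)
    adj[[k]] <<- rbind(adj[[k]], data.frame(
      contig = c2, side = s2, overlap_length = ov, edge_id = eid,
      stringsAsFactors = FALSE))
  }
  for (i in seq_len(nrow(oe))) {
    push(oe$c1[i], oe$s1[i], oe$c2[i], oe$s2[i], oe$overlap_length[i], i)
    if (!(oe$c1[i] == oe$c2[i] && oe$s1[i] == oe$s2[i]))
      push(oe$c2[i], oe$s2[i], oe$c1[i], oe$s1[i], oe$overlap_length[i], i)
  }
  ## deterministic neighbour order
  lapply(adj, function(d) d[order(terminus_key(d$contig, d$side)), ,
                            drop = FALSE])
}

## Exhaustive backtracking over closed walks under per-contig budgets.
## Walks are deduplicated by canonical form; each canonical walk is found
## from its lexicographically smallest member contig, so extension to
## contigs below the start id is pruned.
enumerate_closed_walks <- function(graph, budgets, max_walks = 10000L,
                                   require_distinct_edges = TRUE) {
  adj <- walk_adjacency(graph)
  ids <- sort(names(graph$contigs))
  seen <- new.env(parent = emptyenv())
  walks <- list()
  over_cap <- FALSE
  record <- function(steps_c, steps_o) {
    st <- data.frame(contig_id = steps_c, orientation = steps_o,
                     stringsAsFactors = FALSE)
    key <- canonical_walk_key(st)
    if (!is.null(seen[[key]])) return()
    seen[[key]] <- TRUE
    walks[[length(walks) + 1L]] <<- st
    if (length(walks) > max_walks) over_cap <<- TRUE
  }
  for (start in ids) {
    if (over_cap) break
    counts <- setNames(integer(length(ids)), ids)
    ## depth-first over oriented steps; iterative stack to avoid deep
    ## recursion limits
    dfs <- function(steps_c, steps_o, counts, first_edge) {
      if (over_cap) return()
      cur <- length(steps_c)
      ek <- terminus_key(steps_c[cur], exit_side(steps_o[cur]))
      nb <- adj[[ek]]
      if (is.null(nb)) return()
      for (i in seq_len(nrow(nb))) {
        nc <- nb$contig[i]; ns <- nb$side[i]; eid <- nb$edge_id[i]
        if (nc == start && ns == "head") {
          ## closing junction back to the start terminus; a single-step walk
          ## closes through its only (self) edge, so the first and last
          ## traversed edges coincide -- allowed only when the distinct-edge
          ## start rule is off (master reconstruction)
          if (cur > 1L || !require_distinct_edges)
            record(steps_c, steps_o)
        }
        if (nc < start) next
        if (counts[nc] >= budgets[nc]) next
        counts2 <- counts; counts2[nc] <- counts2[nc] + 1L
        dfs(c(steps_c, nc), c(steps_o, orientation_from_entry(ns)),
            counts2, if (is.null(first_edge)) eid else first_edge)
      }
    }
    if (budgets[start] < 1L) next
    counts[start] <- 1L
    dfs(start, "+", counts, NULL)
  }
  if (over_cap)
    stop("enumerate_closed_walks: more than ", max_walks,
         " walks; raise max_walks to enumerate this graph")
  lapply(walks, function(st) make_walk(graph, st))
}

#' Traversal rules
#'
#' @param repeat_budget traversals allowed per repeat contig (default 2).
#' @param unique_budget traversals allowed per non-repeat contig (default 1).
#' @param max_walks enumeration cap; exceeding it is an error, never silent
#'   truncation (default 10000).
#' @export
traversal_rules <- function(repeat_budget = 2L, unique_budget = 1L,
                            max_walks = 10000L) {
  stopifnot(repeat_budget >= 1, unique_budget >= 1)
  list(repeat_budget = as.integer(repeat_budget),
       unique_budget = as.integer(unique_budget),
       max_walks = as.integer(max_walks))
}

budget_vector <- function(graph, rules) {
  roles <- vapply(graph$contigs, `[[`, character(1), "role")
  setNames(ifelse(roles == "repeat", rules$repeat_budget,
                  rules$unique_budget), names(roles))
}

#' Reconstruct the master configuration
#'
#' Searches for a closed walk containing every contig, with every repeat
#' traversed at least twice, starting and ending at the same vertex.  If no
#' such walk exists at base budgets (each repeat twice, everything else
#' once), budgets are escalated stepwise -- first allowing non-repeat
#' contigs a second traversal, then a repeat a third -- and the elements
#' exceeding base budget are reported.  Among admissible walks the one with
#' the fewest total steps (then smallest canonical form) is returned.
#'
#' @param graph a connected curated graph with repeat roles assigned.
#' @param rules a [traversal_rules()].
#' @return a `mito_walk` with attribute `over_budget` (character vector of
#'   contigs traversed more often than the base budget allows).
#' @export
reconstruct_master <- function(graph, rules = traversal_rules()) {
  st <- graph_stats(graph)
  if (st$n_components > 1)
    stop("reconstruct_master: graph has ", st$n_components,
         " components; the master circle needs a connected graph")
  roles <- vapply(graph$contigs, `[[`, character(1), "role")
  base <- budget_vector(graph, rules)
  escalations <- list(
    base,
    ifelse(roles == "repeat", rules$repeat_budget, rules$unique_budget + 1L),
    ifelse(roles == "repeat", rules$repeat_budget + 1L, rules$unique_budget),
    ifelse(roles == "repeat", rules$repeat_budget + 1L,
           rules$unique_budget + 1L))
  best_partial <- NULL
  for (budgets in escalations) {
    budgets <- setNames(as.integer(budgets), names(roles))
    walks <- enumerate_closed_walks(graph, budgets,
                                    max_walks = rules$max_walks,
                                    require_distinct_edges = FALSE)
    if (!length(walks)) next
    covering <- Filter(function(w) {
      cnt <- table(factor(w$steps$contig_id, levels = names(roles)))
      all(cnt >= 1) && all(cnt[roles == "repeat"] >= 2)
    }, walks)
    if (length(covering)) {
      sizes <- vapply(covering, function(w) nrow(w$steps), integer(1))
      cand <- covering[sizes == min(sizes)]
      keys <- vapply(cand, function(w) canonical_walk_key(w$steps),
                     character(1))
      w <- cand[[which.min(rank(keys))]]
      cnt <- table(factor(w$steps$contig_id, levels = names(roles)))
      over <- names(roles)[as.integer(cnt) > base[names(roles)]]
      attr(w, "over_budget") <- sort(over)
      w$kind <- "master_configuration"
      return(w)
    }
    cov_n <- vapply(walks, function(w) length(unique(w$steps$contig_id)),
                    integer(1))
    cand <- walks[[which.max(cov_n)]]
    if (is.null(best_partial) ||
        length(unique(cand$steps$contig_id)) >
        length(unique(best_partial$steps$contig_id)))
      best_partial <- cand
  }
  stop("reconstruct_master: no closed walk covers all contigs with every ",
       "repeat traversed twice, even after budget escalation; best partial ",
       "cover visits ",
       if (is.null(best_partial)) 0L else
         length(unique(best_partial$steps$contig_id)),
       "/", length(roles), " contigs")
}

#' Enumerate all sub-genome configurations
#'
#' Exhaustive backtracking over closed walks that start and end at the same
#' vertex through different edges, traversing each repeat at most
#' `repeat_budget` times (default twice) and each other contig at most
#' once.  Walks are deduplicated by canonical form and classified as master
#' configuration, small sub-circle, intermediate sub-circle, or other.
#'
#' @param graph a curated graph with repeat roles assigned.
#' @param rules a [traversal_rules()].
#' @return list of `mito_walk` objects sorted by kind then canonical key.
#' @export
enumerate_subgenomes <- function(graph, rules = traversal_rules()) {
  budgets <- budget_vector(graph, rules)
  walks <- enumerate_closed_walks(graph, budgets,
                                  max_walks = rules$max_walks,
                                  require_distinct_edges = TRUE)
  keys <- vapply(walks, function(w) canonical_walk_key(w$steps), character(1))
  kinds <- vapply(walks, `[[`, character(1), "kind")
  walks[order(match(kinds, WALK_KINDS), keys)]
}

#' Apply a recombination event at a repeat pair within a walk
#'
#' Direct mode splits a walk traversing the repeat twice in the same
#' orientation into two sub-circles that exchange flanks; total bp is
#' conserved.  Inverted mode reverses (and flips) the segment between the
#' two mates, returning a single walk of unchanged length.
#'
#' @param graph the assembly graph the walk lives in.
#' @param walk a `mito_walk` traversing the repeat twice.
#' @param rrp_id the repeat contig id.
#' @param mode "direct" or "inverted".
#' @return list of `mito_walk` objects (two for direct, one for inverted).
#' @export
apply_recombination <- function(graph, walk, rrp_id, mode = c("direct",
                                                              "inverted")) {
  mode <- match.arg(mode)
  pos <- which(walk$steps$contig_id == rrp_id)
  if (length(pos) < 2)
    stop("apply_recombination: repeat ", rrp_id,
         " is traversed fewer than twice in this walk")
  p1 <- pos[1]; p2 <- pos[2]
  st <- walk$steps
  same_orientation <- st$orientation[p1] == st$orientation[p2]
  if (mode == "direct") {
    if (!same_orientation)
      stop("apply_recombination: the two mates of ", rrp_id,
           " have opposite orientations in this walk; a direct exchange ",
           "would break the junctions (use mode = 'inverted')")
    a <- st[p1:(p2 - 1L), , drop = FALSE]
    b <- st[c(seq(p2, nrow(st)), if (p1 > 1) seq_len(p1 - 1L)), ,
            drop = FALSE]
    return(list(make_walk(graph, a), make_walk(graph, b)))
  }
  if (same_orientation)
    stop("apply_recombination: the two mates of ", rrp_id,
         " have the same orientation in this walk; an inversion would ",
         "break the junctions (use mode = 'direct')")
  if (p2 - p1 < 2)
    stop("apply_recombination: no segment between the two mates to invert")
  inner <- st[(p1 + 1L):(p2 - 1L), , drop = FALSE]
  inner <- data.frame(contig_id = rev(inner$contig_id),
                      orientation = flip_orientation(rev(inner$orientation)),
                      stringsAsFactors = FALSE)
  out <- rbind(st[seq_len(p1), , drop = FALSE], inner,
               st[seq(p2, nrow(st)), , drop = FALSE])
  list(make_walk(graph, out))
}

#' Emit the circular sequence of a walk
#'
#' Concatenates the oriented step sequences, trimming each junction's
#' overlap once (including the closing junction), and verifies that every
#' junction's overlapping bases actually match.
#'
#' @param graph assembly graph whose contigs carry sequences.
#' @param walk a `mito_walk`.
#' @return a DNA string of length `walk$length`.
#' @export
emit_sequence <- function(graph, walk) {
  st <- walk$steps
  seqs <- character(nrow(st))
  for (i in seq_len(nrow(st))) {
    ct <- graph$contigs[[st$contig_id[i]]]
    if (is.null(ct$sequence))
      stop("emit_sequence: contig ", st$contig_id[i], " has no sequence")
    seqs[i] <- if (st$orientation[i] == "+") ct$sequence else
      revcomp(ct$sequence)
  }
  ov <- walk$junction_overlaps
  n <- length(seqs)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    o <- ov[i]
    if (substring(seqs[i], nchar(seqs[i]) - o + 1L) !=
        substring(seqs[j], 1L, o))
      stop("emit_sequence: junction ", st$contig_id[i], st$orientation[i],
           " -> ", st$contig_id[j], st$orientation[j],
           " has incompatible overlapping bases")
  }
  out <- seqs[1]
  if (n > 1) for (i in 2:n) out <- paste0(out, substring(seqs[i], ov[i - 1L] + 1L))
  ## trim the closing junction's overlap off the end
  substring(out, 1L, nchar(out) - ov[n])
}

#' Are two circular sequences identical up to rotation / reverse complement?
#'
#' @param a,b DNA strings.
#' @return TRUE or FALSE.
#' @export
same_circular_sequence <- function(a, b) {
  if (nchar(a) != nchar(b)) return(FALSE)
  doubled <- paste0(a, a)
  grepl(b, doubled, fixed = TRUE) || grepl(revcomp(b), doubled, fixed = TRUE)
}

#' Predict restriction fragments of a (circular) sequence
#'
#' Cuts at every occurrence of the recognition site (forward strand; the
#' reverse complement is searched too when the site is not palindromic) and
#' returns fragment intervals.  Without any site the whole molecule is one
#' fragment.
#'
#' @param sequence DNA string.
#' @param site recognition motif, e.g. "AAGCTT".
#' @param circular treat the sequence as circular (default TRUE).
#' @return data.frame (start, end, length), 1-based; circular fragments may
#'   wrap (end < start).
#' @export
predict_digest_fragments <- function(sequence, site, circular = TRUE) {
  n <- nchar(sequence)
  find_all <- function(motif) {
    hay <- if (circular) paste0(sequence,
                                substring(sequence, 1, nchar(motif) - 1L))
    else sequence
    out <- integer(); from <- 1L
    repeat {
      p <- regexpr(motif, substring(hay, from), fixed = TRUE)
      if (p < 0) break
      out <- c(out, from + p - 1L)
      from <- from + p
    }
    out[out <= n]
  }
  cuts <- find_all(site)
  rc <- revcomp(site)
  if (rc != site) cuts <- sort(unique(c(cuts, find_all(rc))))
  if (!length(cuts)) {
    return(data.frame(start = 1L, end = n, length = n))
  }
  cuts <- sort(unique(cuts))
  if (circular) {
    starts <- cuts
    ends <- c(cuts[-1] - 1L, cuts[1] - 1L)
    ends[ends == 0L] <- n
    lens <- ifelse(ends >= starts, ends - starts + 1L,
                   n - starts + 1L + ends)
  } else {
    starts <- c(1L, cuts[cuts > 1])
    ends <- c(cuts[cuts > 1] - 1L, n)
    lens <- ends - starts + 1L
  }
  data.frame(start = starts, end = ends, length = lens)
}

#' Which fragments does a probe interval detect?
#'
#' @param fragments data.frame from [predict_digest_fragments()].
#' @param probe_start,probe_end probe interval on the same coordinates,
#'   1-based inclusive.
#' @param genome_length total sequence length (needed for wrapped
#'   fragments).
#' @return the subset of `fragments` overlapping the probe.
#' @export
probe_detects <- function(fragments, probe_start, probe_end, genome_length) {
  covers <- function(start, end, p) {
    if (end >= start) p >= start & p <= end
    else p >= start | p <= end   # wrapped fragment
  }
  pts <- probe_start:probe_end
  hit <- vapply(seq_len(nrow(fragments)), function(i) {
    any(covers(fragments$start[i], fragments$end[i], pts))
  }, logical(1))
  fragments[hit, , drop = FALSE]
}
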