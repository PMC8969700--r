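## CRC stoichiometry from spanning reads.
##
## Large-insert mate pairs and long reads that bracket a repeat tell which
## of its four junction variants a molecule carried.  Because graph contigs
## can be shorter than the insert, mates are anchored to contig chains: the
## maximal runs of non-repeat contigs between two repeat pairs.  Per repeat,
## counts over the four variants give shares, a read sum, and a usage factor
## (read sum over the smallest read sum among evaluated junction
## candidates).

#' Build contig chains between repeat pairs
#'
#' Non-repeat contigs joined by unambiguous junctions (one overlap edge per
#' terminus) are chained until a repeat contig, a fork or a dead end is met.
#' Every non-repeat contig belongs to exactly one chain.  A chain of a
#' single contig directly bracketed by repeats is flagged: spanning reads
#' anchor to less sequence there, deflating its counts.
#'
#' @param graph an assembly graph with repeat roles assigned
#'   (see [detect_double_forks()]).
#' @return list of chains: members (data.frame contig_id, orientation),
#'   bounded_by (left/right repeat id or "end"), circular, flagged.
#' @export
build_contig_chains <- function(graph) {
  roles <- vapply(graph$contigs, `[[`, character(1), "role")
  uniq <- names(roles)[roles != "repeat"]
  oe <- overlap_edges_of(graph)
  deg <- table(c(terminus_key(oe$c1, oe$s1), terminus_key(oe$c2, oe$s2)))
  link <- oe$c1 %in% uniq & oe$c2 %in% uniq & oe$c1 != oe$c2 &
    deg[terminus_key(oe$c1, oe$s1)] == 1 &
    deg[terminus_key(oe$c2, oe$s2)] == 1
  le <- oe[link, , drop = FALSE]
  ig <- igraph::graph_from_data_frame(
    d = data.frame(from = le$c1, to = le$c2, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = uniq, stringsAsFactors = FALSE))
  memb <- igraph::components(ig)$membership[uniq]
  chains <- list()
  repeat_at <- function(contig, side) {
    nb <- terminus_neighbors(graph, contig, side)
    reps <- unique(nb$contig[roles[nb$contig] == "repeat"])
    if (length(reps)) sort(reps)[1] else "end"
  }
  for (grp in split(uniq, memb)) {
    sub <- le[le$c1 %in% grp | le$c2 %in% grp, , drop = FALSE]
    circular <- FALSE
    if (nrow(sub)) {
      d <- table(c(sub$c1, sub$c2))
      circular <- all(d[grp] == 2)
    }
    if (circular) {
      ## whole-component ring of unique contigs (no repeat bounds it)
      k <- paste(terminus_key(sub$c1, sub$s1), terminus_key(sub$c2, sub$s2))
      sub <- sub[-which.max(rank(k)), , drop = FALSE]
    }
    members <- walk_path(grp, sub)
    first <- members[1, ]; last <- members[nrow(members), ]
    chains[[length(chains) + 1L]] <- list(
      members = members,
      bounded_by = c(
        left = if (circular) "circular" else
          repeat_at(first$contig_id, entry_side(first$orientation)),
        right = if (circular) "circular" else
          repeat_at(last$contig_id, exit_side(last$orientation))),
      circular = circular,
      flagged = nrow(members) == 1L && !circular)
  }
  ## deterministic order by first member id
  chains[order(vapply(chains, function(ch) ch$members$contig_id[1],
                      character(1)))]
}

## order the contigs of one path component, orienting members as traversed
walk_path <- function(grp, sub) {
  if (!nrow(sub)) {
    return(data.frame(contig_id = grp[1], orientation = "+",
                      stringsAsFactors = FALSE))
  }
  d <- table(c(sub$c1, sub$c2))
  ends <- grp[is.na(d[grp]) | d[grp] == 1]
  cur <- sort(ends)[1]
  cur_entry <- NULL
  used <- rep(FALSE, nrow(sub))
  members <- data.frame(contig_id = character(), orientation = character(),
                        stringsAsFactors = FALSE)
  repeat {
    ei <- which(!used & (sub$c1 == cur | sub$c2 == cur))[1]
    if (is.null(cur_entry)) {
      exit_s <- if (sub$c1[ei] == cur) sub$s1[ei] else sub$s2[ei]
      ori <- if (exit_s == "tail") "+" else "-"
    } else {
      ori <- orientation_from_entry(cur_entry)
    }
    members <- rbind(members, data.frame(contig_id = cur, orientation = ori,
                                         stringsAsFactors = FALSE))
    if (is.na(ei)) break
    used[ei] <- TRUE
    cur_entry <- if (sub$c1[ei] == cur) sub$s2[ei] else sub$s1[ei]
    cur <- if (sub$c1[ei] == cur) sub$c2[ei] else sub$c1[ei]
  }
  members
}

chain_lookup <- function(chains) {
  map <- list()
  for (i in seq_along(chains)) {
    for (id in chains[[i]]$members$contig_id) map[[id]] <- i
  }
  map
}

#' Count mate pairs supporting each CRC variant
#'
#' Each CRC variant extends into the contig chain attached to its head-side
#' fork terminus and the chain attached to its tail-side terminus.  A pair
#' supports the variant when its two mates (on different contigs) lie in
#' those two chain flanks at distances from the repeat compatible with the
#' library insert: the implied molecule span (flank distance + repeat
#' length + flank distance) must not exceed `max_span`.  Anchoring each
#' fork branch to a specific chain end keeps variants apart even when both
#' branches of a side fall into one chain (inverted repeats) and rejects
#' pairs that merely span a junction inside a chain.  Pairs matching more
#' than one variant of a repeat are dropped as ambiguous for that repeat;
#' each pair counts once per repeat.
#'
#' @param placements data.frame (read_id, mate, contig_id, start, end,
#'   strand, identity); mate is 1 or 2.
#' @param chains from [build_contig_chains()].
#' @param rrps repeat-pair records from [detect_double_forks()].
#' @param graph the assembly graph (chain layout and junction overlaps).
#' @param max_span largest plausible molecule span in bp for a spanning
#'   pair (default 6500, matching a 5 kb insert library).
#' @return list per repeat id: named integer counts per CRC key (plus
#'   attribute n_ambiguous); attribute n_unpaired on the list.
#' @export
count_matepair_support <- function(placements, chains, rrps, graph,
                                   max_span = 6500) {
  lk <- chain_lookup(chains)
  layouts <- lapply(chains, function(ch) molecule_layout(graph, ch$members))
  sp <- split(placements, placements$read_id)
  pairs <- lapply(sp, function(p) {
    if (length(unique(p$mate)) < 2) return(NULL)
    m <- sort(unique(p$mate))
    i1 <- which(p$mate == m[1])[1]; i2 <- which(p$mate == m[2])[1]
    list(contig = c(p$contig_id[i1], p$contig_id[i2]),
         mid = c((p$start[i1] + p$end[i1]) / 2,
                 (p$start[i2] + p$end[i2]) / 2))
  })
  unpaired <- sum(vapply(pairs, is.null, logical(1)))
  pairs <- pairs[!vapply(pairs, is.null, logical(1))]
  pairs <- pairs[vapply(pairs, function(x) x$contig[1] != x$contig[2],
                        logical(1))]
  ## branch descriptor: the chain and the chain end a fork terminus faces
  branch_of <- function(X, sx) {
    ci <- lk[[X]]
    if (is.null(ci)) return(NULL)
    mem <- chains[[ci]]$members
    first <- mem[1, ]; last <- mem[nrow(mem), ]
    end <- if (last$contig_id == X && exit_side(last$orientation) == sx)
      "last"
    else if (first$contig_id == X && entry_side(first$orientation) == sx)
      "first"
    else NA_character_
    if (is.na(end)) return(NULL)
    list(chain = ci, end = end)
  }
  ## distance from the branch's repeat-facing chain end to a mate
  mate_dist <- function(br, contig, mid) {
    ly <- layouts[[br$chain]]
    si <- which(ly$steps$contig_id == contig)[1]
    if (is.na(si)) return(NA_real_)
    g <- if (ly$steps$orientation[si] == "+") ly$pos[si] + mid - 1
    else ly$pos[si] + ly$lens[si] - mid
    if (br$end == "last") ly$total - g else g - 1
  }
  out <- list()
  for (rid in names(rrps)) {
    rrp <- rrps[[rid]]
    crcs <- enumerate_crcs(rrp)
    left_branch <- lapply(seq_len(nrow(crcs)), function(i)
      branch_of(crcs$left[i], exit_side(crcs$left_orientation[i])))
    right_branch <- lapply(seq_len(nrow(crcs)), function(i)
      branch_of(crcs$right[i], entry_side(crcs$right_orientation[i])))
    keys <- unique(crcs$key)
    counts <- setNames(integer(length(keys)), keys)
    ambiguous <- 0L
    for (pr in pairs) {
      hit_keys <- character()
      for (i in seq_len(nrow(crcs))) {
        bl <- left_branch[[i]]; br <- right_branch[[i]]
        if (is.null(bl) || is.null(br)) next
        for (ord in list(c(1L, 2L), c(2L, 1L))) {
          d1 <- mate_dist(bl, pr$contig[ord[1]], pr$mid[ord[1]])
          d2 <- mate_dist(br, pr$contig[ord[2]], pr$mid[ord[2]])
          if (is.na(d1) || is.na(d2)) next
          if (d1 + rrp$length + d2 <= max_span) {
            hit_keys <- c(hit_keys, crcs$key[i])
            break
          }
        }
      }
      hit_keys <- unique(hit_keys)
      if (length(hit_keys) == 1L) counts[hit_keys] <- counts[hit_keys] + 1L
      else if (length(hit_keys) > 1L) ambiguous <- ambiguous + 1L
    }
    attr(counts, "n_ambiguous") <- ambiguous
    out[[rid]] <- counts
  }
  attr(out, "n_unpaired") <- unpaired
  out
}

#' Chain and filter long-read alignments
#'
#' Per-read alignment hits are sorted by read start, floored on hit length,
#' collapsed over consecutive identical contig ids, and the resulting chain
#' is retained only for reads that align almost fully (covered fraction at
#' least `min_covered`), at `min_identity` percent identity or better, and
#' are at least `min_read_length` long.  Sub-threshold reads are classified
#' nuclear-like and excluded.
#'
#' @param hits data.frame (read_id, contig_id, q_start, q_end, identity,
#'   read_length); q coordinates are on the read, 1-based inclusive.
#' @param hit_floor keep hits strictly longer than this many bp
#'   (default 100; 170/180 are stricter dialects for cross-mapping
#'   diagnostics).
#' @param min_identity percent (default 95).
#' @param min_read_length bp (default 5000).
#' @param min_covered aligned fraction of the read (default 0.99).
#' @return data.frame (read_id, chain, n_hits, covered_fraction,
#'   mean_identity, read_length, kept, reason); `chain` is the
#'   comma-joined contig id sequence.
#' @export
chain_and_filter_ccs <- function(hits, hit_floor = 100L, min_identity = 95,
                                 min_read_length = 5000L, min_covered = 0.99) {
  hits$hit_len <- abs(hits$q_end - hits$q_start) + 1L
  hits <- hits[hits$hit_len > hit_floor, , drop = FALSE]
  hits <- hits[order(hits$read_id, pmin(hits$q_start, hits$q_end)), ,
               drop = FALSE]
  rows <- lapply(split(hits, hits$read_id), function(h) {
    ids <- h$contig_id
    keep <- c(TRUE, ids[-1] != ids[-length(ids)])
    chain <- ids[keep]
    ## covered fraction from the union of read intervals
    lo <- pmin(h$q_start, h$q_end); hi <- pmax(h$q_start, h$q_end)
    o <- order(lo)
    lo <- lo[o]; hi <- hi[o]
    cov <- 0L; cur_lo <- lo[1]; cur_hi <- hi[1]
    for (i in seq_along(lo)[-1]) {
      if (lo[i] <= cur_hi + 1L) cur_hi <- max(cur_hi, hi[i])
      else { cov <- cov + cur_hi - cur_lo + 1L; cur_lo <- lo[i]; cur_hi <- hi[i] }
    }
    cov <- cov + cur_hi - cur_lo + 1L
    rl <- h$read_length[1]
    covered <- cov / rl
    mid <- mean(h$identity)
    kept <- covered >= min_covered && mid >= min_identity &&
      rl >= min_read_length
    reason <- if (kept) "" else if (covered < min_covered) "partial_alignment_nuclear_like"
    else if (mid < min_identity) "low_identity" else "short_read"
    data.frame(read_id = h$read_id[1], chain = paste(chain, collapse = ","),
               n_hits = nrow(h), covered_fraction = covered,
               mean_identity = mid, read_length = rl, kept = kept,
               reason = reason, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(read_id = character(), chain = character(),
                      n_hits = integer(), covered_fraction = numeric(),
                      mean_identity = numeric(), read_length = integer(),
                      kept = logical(), reason = character(),
                      stringsAsFactors = FALSE)
  out
}

#' Count long-read chains supporting each CRC variant
#'
#' A chain supports a variant when the variant's left-repeat-right id triple
#' (or its reverse) occurs as a contiguous subsequence of the chain.
#'
#' @param chains data.frame from [chain_and_filter_ccs()]; only `kept` rows
#'   are used.
#' @param crcs data.frame from [enumerate_crcs()].
#' @return named integer vector of counts per CRC key.
#' @export
count_longread_support <- function(chains, crcs) {
  keys <- unique(crcs$key)
  counts <- setNames(integer(length(keys)), keys)
  kept <- chains[chains$kept, , drop = FALSE]
  triples <- unique(crcs[, c("left", "repeat_id", "right", "key")])
  for (ci in seq_len(nrow(kept))) {
    ids <- strsplit(kept$chain[ci], ",", fixed = TRUE)[[1]]
    if (length(ids) < 3) next
    for (ti in seq_len(nrow(triples))) {
      fwd <- c(triples$left[ti], triples$repeat_id[ti], triples$right[ti])
      rev3 <- rev(fwd)
      n_occ <- 0L
      for (p in seq_len(length(ids) - 2L)) {
        w <- ids[p:(p + 2L)]
        if (all(w == fwd) || all(w == rev3)) n_occ <- n_occ + 1L
      }
      counts[triples$key[ti]] <- counts[triples$key[ti]] + n_occ
    }
  }
  counts
}

#' Summarise CRC stoichiometry per repeat pair
#'
#' Shares are integer-rounded percentages of the repeat's read sum; the
#' usage factor is the read sum divided by `divisor`, rounded to one decimal
#' half away from zero.  The divisor defaults to the smallest read sum among
#' the evaluated repeats; pass an explicit value when dismissed junction
#' candidates (false positives outside the table) define a smaller minimum.
#' A repeat is grouped "dominant" when its two largest shares are both at
#' least `dominance_top` percent and its two smallest at most
#' `dominance_bottom` percent, else "balanced".
#'
#' @param counts list per repeat id of named counts per CRC key.
#' @param divisor explicit usage-factor divisor or NULL.
#' @param dominance_top,dominance_bottom dominance thresholds in percent
#'   (defaults 25 and 15).
#' @return list(rows, crc, divisor): per-repeat summary, long per-CRC table
#'   and the divisor actually used.
#' @export
summarize_stoichiometry <- function(counts, divisor = NULL,
                                    dominance_top = 25,
                                    dominance_bottom = 15) {
  stopifnot(length(counts) >= 1)
  sums <- vapply(counts, sum, numeric(1))
  used_divisor <- divisor %||%
    (if (any(sums > 0)) min(sums[sums > 0]) else NA_real_)
  rows <- list(); crc <- list()
  for (rid in names(counts)) {
    ct <- counts[[rid]]
    rs <- sum(ct)
    flagged <- rs == 0
    shares <- if (flagged) rep(NA_real_, length(ct)) else
      round_half_up(100 * ct / rs)
    group <- NA_character_
    if (!flagged && length(ct) >= 4) {
      s <- sort(shares, decreasing = TRUE)
      group <- if (all(s[1:2] >= dominance_top) &&
                   all(s[(length(s) - 1):length(s)] <= dominance_bottom))
        "dominant" else "balanced"
    } else if (!flagged) {
      group <- "balanced"
    }
    rows[[rid]] <- data.frame(
      rrp_id = rid, read_sum = rs,
      usage_factor = if (flagged) NA_real_ else
        round_half_up(rs / used_divisor, 1),
      group = group, flagged = flagged, stringsAsFactors = FALSE)
    crc[[rid]] <- data.frame(rrp_id = rid, crc_key = names(ct),
                             count = as.integer(ct), share = shares,
                             stringsAsFactors = FALSE)
  }
  list(rows = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       crc = do.call(rbind, c(crc, list(make.row.names = FALSE))),
       divisor = used_divisor)
}
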