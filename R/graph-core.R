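## Terminus-graph domain model.
##
## A contig contributes two vertices (its head and tail termini) joined by a
## "contig" edge (or "repeat" edge once classified).  Exact end overlaps
## between two contigs are undirected "overlap" edges between the touching
## termini.  Direction never lives in the graph; it emerges in walks.

CONTIG_ORIGINS <- c("mitochondrial", "plastidial", "nuclear", "unknown")
CONTIG_ROLES <- c("unique", "repeat", "unclassified")
EDGE_KINDS <- c("contig", "repeat", "overlap")

#' Create a contig record
#'
#' @param id contig identifier (unique within a graph).
#' @param length length in bp; inferred from `sequence` when omitted.
#' @param sequence optional DNA string (stored strand).
#' @param mean_coverage mean read coverage (reads x bp / bp).
#' @param origin one of mitochondrial, plastidial, nuclear, unknown.
#' @param is_hcc whether the contig passes the high-confidence criteria.
#' @param role structural role: unique, repeat or unclassified.
#' @param members for merged contigs, a data.frame (contig_id, orientation)
#'   listing the collapsed members in order.
#' @return a `mito_contig` list.
#' @export
mito_contig <- function(id, length = NULL, sequence = NULL,
                        mean_coverage = NA_real_, origin = "unknown",
                        is_hcc = FALSE, role = "unclassified",
                        members = NULL) {
  if (is.null(length)) {
    if (is.null(sequence)) stop("contig '", id, "': need length or sequence")
    length <- nchar(sequence)
  }
  origin <- match.arg(origin, CONTIG_ORIGINS)
  role <- match.arg(role, CONTIG_ROLES)
  structure(list(id = as.character(id), length = as.integer(length),
                 sequence = sequence, mean_coverage = as.numeric(mean_coverage),
                 origin = origin, is_hcc = isTRUE(is_hcc), role = role,
                 members = members),
            class = "mito_contig")
}

empty_edges <- function() {
  data.frame(kind = character(), c1 = character(), s1 = character(),
             c2 = character(), s2 = character(),
             overlap_length = integer(), circular_candidate = logical(),
             stringsAsFactors = FALSE)
}

## Canonical endpoint order so undirected edges compare equal.
orient_edge_endpoints <- function(c1, s1, c2, s2) {
  k1 <- terminus_key(c1, s1)
  k2 <- terminus_key(c2, s2)
  swap <- k2 < k1
  list(c1 = ifelse(swap, c2, c1), s1 = ifelse(swap, s2, s1),
       c2 = ifelse(swap, c1, c2), s2 = ifelse(swap, s1, s2))
}

#' Build an assembly graph over contig termini
#'
#' @param contigs a list of [mito_contig()] records.
#' @param overlap_edges optional data.frame with columns c1, s1, c2, s2,
#'   overlap_length describing exact end overlaps (sides are head/tail).
#' @return an `assembly_graph` object.  One contig edge per contig is created
#'   automatically; duplicate overlap edges on the same terminus pair keep the
#'   longest overlap and the discarded ones are recorded in
#'   `attr(graph, "dropped_duplicate_edges")`.
#' @export
assembly_graph <- function(contigs, overlap_edges = NULL) {
  stopifnot(is.list(contigs))
  if (length(contigs) && is.null(names(contigs))) {
    names(contigs) <- vapply(contigs, `[[`, character(1), "id")
  }
  g <- structure(list(contigs = contigs, edges = empty_edges()),
                 class = "assembly_graph")
  for (id in names(contigs)) {
    kind <- if (identical(contigs[[id]]$role, "repeat")) "repeat" else "contig"
    g$edges <- rbind(g$edges, data.frame(
      kind = kind, c1 = id, s1 = "head", c2 = id, s2 = "tail",
      overlap_length = NA_integer_, circular_candidate = FALSE,
      stringsAsFactors = FALSE))
  }
  dropped <- empty_edges()
  if (!is.null(overlap_edges) && nrow(overlap_edges)) {
    oe <- orient_edge_endpoints(overlap_edges$c1, overlap_edges$s1,
                                overlap_edges$c2, overlap_edges$s2)
    add <- data.frame(kind = "overlap", c1 = oe$c1, s1 = oe$s1,
                      c2 = oe$c2, s2 = oe$s2,
                      overlap_length = as.integer(overlap_edges$overlap_length),
                      circular_candidate = oe$c1 == oe$c2,
                      stringsAsFactors = FALSE)
    ## keep the longest overlap per terminus pair, deterministically
    key <- paste(terminus_key(add$c1, add$s1), terminus_key(add$c2, add$s2))
    add <- add[order(key, -add$overlap_length), , drop = FALSE]
    dup <- duplicated(paste(terminus_key(add$c1, add$s1),
                            terminus_key(add$c2, add$s2)))
    dropped <- add[dup, , drop = FALSE]
    g$edges <- rbind(g$edges, add[!dup, , drop = FALSE])
  }
  rownames(g$edges) <- NULL
  attr(g, "dropped_duplicate_edges") <- dropped
  g
}

#' @export
print.assembly_graph <- function(x, ...) {
  st <- graph_stats(x)
  cat("assembly_graph:", length(x$contigs), "contigs /", st$n_vertices,
      "termini;", sum(x$edges$kind == "overlap"), "overlap edges;",
      st$n_repeat_contigs, "repeat contigs;", st$n_components,
      "component(s);", st$total_bp, "bp represented\n")
  invisible(x)
}

overlap_edges_of <- function(graph) {
  graph$edges[graph$edges$kind == "overlap", , drop = FALSE]
}

## Overlap edges incident to a terminus.
edges_at_terminus <- function(graph, contig_id, side) {
  e <- overlap_edges_of(graph)
  hit <- (e$c1 == contig_id & e$s1 == side) | (e$c2 == contig_id & e$s2 == side)
  e[hit, , drop = FALSE]
}

#' Neighbours of one contig terminus
#'
#' @param graph an assembly graph.
#' @param contig_id,side the terminus queried.
#' @return data.frame (contig, side, overlap_length) of the termini linked to
#'   the query terminus by overlap edges.
#' @export
terminus_neighbors <- function(graph, contig_id, side) {
  e <- edges_at_terminus(graph, contig_id, side)
  if (!nrow(e)) {
    return(data.frame(contig = character(), side = character(),
                      overlap_length = integer(), stringsAsFactors = FALSE))
  }
  from1 <- e$c1 == contig_id & e$s1 == side
  out <- data.frame(contig = ifelse(from1, e$c2, e$c1),
                    side = ifelse(from1, e$s2, e$s1),
                    overlap_length = e$overlap_length,
                    stringsAsFactors = FALSE)
  ## a self edge (circular candidate) appears once from each of its ends
  self <- e$c1 == contig_id & e$s1 == side & e$c2 == contig_id & e$s2 == side
  if (any(self)) out <- rbind(out, data.frame(contig = contig_id, side = side,
                                              overlap_length = e$overlap_length[self],
                                              stringsAsFactors = FALSE))
  out[order(terminus_key(out$contig, out$side)), , drop = FALSE]
}

#' Validate the structural invariants of an assembly graph
#'
#' Checks contig fields, edge endpoint existence, the one-contig-edge-per-
#' contig rule and overlap-edge sanity.  Violations are reported, never
#' raised.
#'
#' @param graph an assembly graph.
#' @return character vector of human-readable violations; empty when valid.
#' @export
validate_graph <- function(graph) {
  v <- character()
  ids <- names(graph$contigs)
  for (id in ids) {
    ct <- graph$contigs[[id]]
    if (ct$length < 1) v <- c(v, sprintf("contig %s: length < 1", id))
    if (!is.null(ct$sequence) && nchar(ct$sequence) != ct$length)
      v <- c(v, sprintf("contig %s: sequence length != length field", id))
    if (!is.na(ct$mean_coverage) && ct$mean_coverage < 0)
      v <- c(v, sprintf("contig %s: negative coverage", id))
  }
  e <- graph$edges
  bad_ref <- !(e$c1 %in% ids) | !(e$c2 %in% ids)
  for (i in which(bad_ref))
    v <- c(v, sprintf("edge %d (%s %s:%s--%s:%s): endpoint contig missing",
                      i, e$kind[i], e$c1[i], e$s1[i], e$c2[i], e$s2[i]))
  ce <- e[e$kind %in% c("contig", "repeat"), , drop = FALSE]
  cnt <- table(factor(ce$c1[ce$c1 == ce$c2], levels = ids))
  for (id in ids[cnt != 1])
    v <- c(v, sprintf("contig %s: has %d contig/repeat edges, expected 1",
                      id, cnt[[id]]))
  bad_span <- ce$c1 != ce$c2 | ce$s1 == ce$s2
  for (i in which(bad_span))
    v <- c(v, sprintf("contig edge %s:%s--%s:%s does not join head and tail of one contig",
                      ce$c1[i], ce$s1[i], ce$c2[i], ce$s2[i]))
  oe <- overlap_edges_of(graph)
  if (nrow(oe)) {
    if (any(is.na(oe$overlap_length) | oe$overlap_length < 1))
      v <- c(v, "overlap edge with overlap_length < 1 or missing")
    self <- oe$c1 == oe$c2
    for (i in which(self & !oe$circular_candidate))
      v <- c(v, sprintf("self overlap %s:%s--%s:%s not flagged circular_candidate",
                        oe$c1[i], oe$s1[i], oe$c2[i], oe$s2[i]))
    key <- paste(terminus_key(oe$c1, oe$s1), terminus_key(oe$c2, oe$s2))
    for (k in unique(key[duplicated(key)]))
      v <- c(v, sprintf("duplicate overlap edges on terminus pair %s", k))
  }
  v
}

contig_component_membership <- function(graph) {
  ids <- names(graph$contigs)
  if (!length(ids)) return(integer())
  oe <- overlap_edges_of(graph)
  ig <- igraph::graph_from_data_frame(
    d = data.frame(from = oe$c1, to = oe$c2, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = ids, stringsAsFactors = FALSE))
  igraph::components(ig)$membership[ids]
}

## Overlap edges whose two termini each touch exactly one overlap edge and
## whose contigs are two distinct non-repeat contigs: the unambiguous
## junctions a chain-collapse may merge.  Their overlap bp is redundant
## between the two contigs, so represented bp subtracts it.
collapsible_edges <- function(graph) {
  oe <- overlap_edges_of(graph)
  if (!nrow(oe)) return(oe)
  deg <- table(c(terminus_key(oe$c1, oe$s1), terminus_key(oe$c2, oe$s2)))
  roles <- vapply(graph$contigs, `[[`, character(1), "role")
  keep <- oe$c1 != oe$c2 &
    deg[terminus_key(oe$c1, oe$s1)] == 1 &
    deg[terminus_key(oe$c2, oe$s2)] == 1 &
    roles[oe$c1] != "repeat" & roles[oe$c2] != "repeat"
  oe[keep, , drop = FALSE]
}

#' Summary statistics of an assembly graph
#'
#' `total_bp` is the represented (non-redundant) sequence length: the sum of
#' contig lengths minus the overlap bp of unambiguous degree-2 junctions
#' between non-repeat contigs, so that collapsing chains with
#' [simplify_graph()] conserves it.
#'
#' @param graph an assembly graph.
#' @return list with n_vertices, n_edges_by_kind, n_components,
#'   n_repeat_contigs, total_bp.
#' @export
graph_stats <- function(graph) {
  n_contigs <- length(graph$contigs)
  kinds <- table(factor(graph$edges$kind, levels = EDGE_KINDS))
  lens <- vapply(graph$contigs, `[[`, integer(1), "length")
  roles <- vapply(graph$contigs, `[[`, character(1), "role")
  coll <- collapsible_edges(graph)
  list(n_vertices = 2L * n_contigs,
       n_edges_by_kind = kinds,
       n_components = if (n_contigs) max(contig_component_membership(graph)) else 0L,
       n_repeat_contigs = sum(roles == "repeat"),
       total_bp = sum(lens) - sum(coll$overlap_length))
}

#' Collapse unambiguous contig chains into merged contigs
#'
#' Every maximal run of non-repeat contigs joined by junctions where both
#' termini have a single overlap edge is replaced by one merged contig
#' ("super contig").  Repeat contigs are never absorbed.  Represented bp
#' (`graph_stats()$total_bp`) and component count are conserved, and the
#' operation is idempotent.  A fully collapsible circular component is merged
#' into a single contig carrying a self overlap flagged as circular
#' candidate.
#'
#' @param graph a valid assembly graph.
#' @return a new assembly graph; merged contigs record their `members`.
#' @export
simplify_graph <- function(graph) {
  coll <- collapsible_edges(graph)
  if (!nrow(coll)) return(graph)

  ## contigs chained by collapsible edges form simple paths or cycles
  ig <- igraph::graph_from_data_frame(
    d = data.frame(from = coll$c1, to = coll$c2, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = sort(unique(c(coll$c1, coll$c2))),
                          stringsAsFactors = FALSE))
  memb <- igraph::components(ig)$membership
  drop_keys <- character()   # edges removed because a cycle must stay open
  groups <- split(names(memb), memb)

  new_contigs <- list()
  replaced <- character()
  terminus_map <- list()  # old terminus key -> c(new_contig, new_side)
  extra_self_edges <- empty_edges()

  coll_key <- paste(terminus_key(coll$c1, coll$s1), terminus_key(coll$c2, coll$s2))

  for (grp in groups) {
    sub <- coll[coll$c1 %in% grp | coll$c2 %in% grp, , drop = FALSE]
    deg <- table(c(sub$c1, sub$c2))
    is_cycle <- all(deg[grp] == 2)
    cycle_edge <- NULL
    if (is_cycle) {
      ## open the cycle at the lexicographically largest junction
      k <- paste(terminus_key(sub$c1, sub$s1), terminus_key(sub$c2, sub$s2))
      drop_i <- which.max(rank(k))
      cycle_edge <- sub[drop_i, , drop = FALSE]
      drop_keys <- c(drop_keys, k[drop_i])
      sub <- sub[-drop_i, , drop = FALSE]
      if (!nrow(sub)) next  # 2-contig cycle degenerates: nothing left to merge
      deg <- table(c(sub$c1, sub$c2))
    }
    ends <- grp[is.na(deg[grp]) | deg[grp] == 1]
    start <- sort(ends)[1]
    ## walk the path, orienting members as traversed
    members <- data.frame(contig_id = character(), orientation = character(),
                          stringsAsFactors = FALSE)
    junction_ov <- integer()
    cur <- start
    cur_entry <- NULL  # side through which we entered cur (NULL at path start)
    used <- rep(FALSE, nrow(sub))
    repeat {
      ei <- which(!used & (sub$c1 == cur | sub$c2 == cur))[1]
      if (is.null(cur_entry)) {
        ## orient the first member so the walk leaves through the edge side
        exit_s <- if (sub$c1[ei] == cur) sub$s1[ei] else sub$s2[ei]
        ori <- if (exit_s == "tail") "+" else "-"
      } else {
        ori <- orientation_from_entry(cur_entry)
      }
      members <- rbind(members, data.frame(contig_id = cur, orientation = ori,
                                           stringsAsFactors = FALSE))
      if (is.na(ei)) break
      used[ei] <- TRUE
      junction_ov <- c(junction_ov, sub$overlap_length[ei])
      cur_entry <- if (sub$c1[ei] == cur) sub$s2[ei] else sub$s1[ei]
      cur <- if (sub$c1[ei] == cur) sub$c2[ei] else sub$c1[ei]
    }
    mem_contigs <- lapply(members$contig_id, function(i) graph$contigs[[i]])
    lens <- vapply(mem_contigs, `[[`, integer(1), "length")
    new_len <- sum(lens) - sum(junction_ov)
    covs <- vapply(mem_contigs, `[[`, numeric(1), "mean_coverage")
    seqs <- lapply(mem_contigs, `[[`, "sequence")
    new_seq <- NULL
    if (!any(vapply(seqs, is.null, logical(1)))) {
      oriented <- mapply(function(s, o) if (o == "+") s else revcomp(s),
                         seqs, members$orientation)
      new_seq <- oriented[1]
      for (j in seq_along(junction_ov)) {
        new_seq <- paste0(new_seq, substring(oriented[j + 1], junction_ov[j] + 1))
      }
    }
    new_id <- paste(members$contig_id, collapse = "~")
    new_contigs[[new_id]] <- mito_contig(
      id = new_id, length = new_len, sequence = new_seq,
      mean_coverage = if (all(is.na(covs))) NA_real_ else
        sum(covs * lens, na.rm = TRUE) / sum(lens[!is.na(covs)]),
      origin = mem_contigs[[1]]$origin,
      is_hcc = any(vapply(mem_contigs, `[[`, logical(1), "is_hcc")),
      role = "unique",
      members = members)
    replaced <- c(replaced, members$contig_id)
    ## outer termini of the path map onto the merged contig's termini
    first <- members[1, ]; last <- members[nrow(members), ]
    terminus_map[[terminus_key(first$contig_id, entry_side(first$orientation))]] <-
      c(new_id, "head")
    terminus_map[[terminus_key(last$contig_id, exit_side(last$orientation))]] <-
      c(new_id, "tail")
    if (is_cycle && !is.null(cycle_edge)) {
      extra_self_edges <- rbind(extra_self_edges, cycle_edge)
    }
  }

  kept_contigs <- graph$contigs[setdiff(names(graph$contigs), replaced)]
  all_contigs <- c(kept_contigs, new_contigs)

  oe <- overlap_edges_of(graph)
  key <- paste(terminus_key(oe$c1, oe$s1), terminus_key(oe$c2, oe$s2))
  oe <- oe[!(key %in% coll_key), , drop = FALSE]
  oe <- rbind(oe, extra_self_edges)
  remap <- function(cv, sv) {
    for (i in seq_along(cv)) {
      m <- terminus_map[[terminus_key(cv[i], sv[i])]]
      if (!is.null(m)) { cv[i] <- m[1]; sv[i] <- m[2] }
    }
    list(c = cv, s = sv)
  }
  if (nrow(oe)) {
    m1 <- remap(oe$c1, oe$s1); m2 <- remap(oe$c2, oe$s2)
    oe <- data.frame(c1 = m1$c, s1 = m1$s, c2 = m2$c, s2 = m2$s,
                     overlap_length = oe$overlap_length,
                     stringsAsFactors = FALSE)
  }
  out <- assembly_graph(all_contigs, overlap_edges = oe)
  out
}
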