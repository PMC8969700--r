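## Scriptable graph curation with a replayable log.
##
## Raw terminus graphs carry plastid subgraphs attached through shared or
## misassembled contigs, near-duplicate fragments shorter than twice the
## assembly k-mer, and low-coverage nuclear contamination.  Each curation
## step is an explicit, logged action so a curated graph can be reproduced
## exactly by replaying the log on the original graph.

curation_log_df <- function() {
  data.frame(step = integer(), kind = character(), target = character(),
             reason = character(), evidence = character(),
             n_contigs_after = integer(), n_overlap_edges_after = integer(),
             stringsAsFactors = FALSE)
}

log_action <- function(log, graph, kind, target, reason = "", evidence = "") {
  rbind(log, data.frame(
    step = nrow(log) + 1L, kind = kind, target = target, reason = reason,
    evidence = evidence, n_contigs_after = length(graph$contigs),
    n_overlap_edges_after = sum(graph$edges$kind == "overlap"),
    stringsAsFactors = FALSE))
}

drop_contigs <- function(graph, ids) {
  graph$contigs[ids] <- NULL
  e <- graph$edges
  graph$edges <- e[!(e$c1 %in% ids | e$c2 %in% ids), , drop = FALSE]
  graph
}

#' Remove the plastid boundary and disconnect the plastid subgraph
#'
#' Contigs with a sufficient plastid-reference hit are flagged plastidial.
#' Among them, those directly linked by an overlap edge to a non-plastid
#' contig are removed; the remaining plastid subgraph is thereby
#' disconnected and falls out of high-confidence reachability.
#'
#' @param graph an assembly graph.
#' @param plastid_hits data.frame (contig_id, reference_id, covered_fraction,
#'   identity).
#' @param min_covered_fraction fraction of a contig's bases that must be
#'   covered by plastid-reference hits to call it plastidial (default 0.8).
#' @return list(graph, log, plastid_ids, removed).
#' @export
remove_plastid_subgraph <- function(graph, plastid_hits,
                                    min_covered_fraction = 0.8) {
  log <- curation_log_df()
  if (is.null(plastid_hits) || !nrow(plastid_hits))
    return(list(graph = graph, log = log, plastid_ids = character(),
                removed = character()))
  stopifnot(all(plastid_hits$covered_fraction >= 0),
            all(plastid_hits$covered_fraction <= 1))
  called <- unique(plastid_hits$contig_id[
    plastid_hits$covered_fraction >= min_covered_fraction])
  called <- intersect(called, names(graph$contigs))
  for (id in called) graph$contigs[[id]]$origin <- "plastidial"
  if (length(called) == length(graph$contigs) && length(called))
    warning("remove_plastid_subgraph: every contig is plastidial; ",
            "mitochondrial graph is empty")
  boundary <- character()
  for (id in called) {
    nb <- unique(c(terminus_neighbors(graph, id, "head")$contig,
                   terminus_neighbors(graph, id, "tail")$contig))
    if (length(setdiff(nb, called))) boundary <- c(boundary, id)
  }
  boundary <- sort(boundary)
  for (id in boundary) {
    graph <- drop_contigs(graph, id)
    log <- log_action(log, graph, "remove_plastid_boundary", id,
                      reason = "plastid contig adjacent to non-plastid subgraph",
                      evidence = "plastid_reference_hit")
  }
  list(graph = graph, log = log, plastid_ids = called, removed = boundary)
}

#' Prune contained short fragments and low-coverage contigs
#'
#' Removes (a) contigs shorter than twice the largest assembly k-mer that are
#' fully contained in another contig (containments come from end-to-end hit
#' filtering) and (b) contigs whose coverage falls below `cov_floor`,
#' treating them as likely nuclear.  `cov_floor = NULL` defaults to 10
#' percent of the median graph-contig coverage.
#'
#' @param graph an assembly graph.
#' @param contained data.frame (contig_id, container_id) from
#'   [filter_end_to_end()].
#' @param k_max largest k-mer used by the assembly (bp).
#' @param cov_floor absolute coverage floor, or NULL for the default.
#' @return list(graph, log, removed, cov_floor).
#' @export
prune_small_lowcov <- function(graph, contained, k_max, cov_floor = NULL) {
  log <- curation_log_df()
  lens <- vapply(graph$contigs, `[[`, integer(1), "length")
  covs <- vapply(graph$contigs, `[[`, numeric(1), "mean_coverage")
  if (is.null(cov_floor)) cov_floor <- 0.1 * median(covs, na.rm = TRUE)
  small <- names(graph$contigs)[lens < 2L * k_max]
  small <- intersect(small, unique(contained$contig_id))
  lowcov <- names(graph$contigs)[!is.na(covs) & covs < cov_floor]
  for (id in sort(small)) {
    if (!id %in% names(graph$contigs)) next
    graph <- drop_contigs(graph, id)
    log <- log_action(log, graph, "remove_contig", id,
                      reason = sprintf("shorter than 2*k_max (%d bp) and contained", 2L * k_max),
                      evidence = "containment")
  }
  for (id in sort(setdiff(lowcov, small))) {
    if (!id %in% names(graph$contigs)) next
    graph <- drop_contigs(graph, id)
    log <- log_action(log, graph, "remove_contig", id,
                      reason = sprintf("coverage below floor %.1f (nuclear-like)", cov_floor),
                      evidence = "low_coverage")
  }
  list(graph = graph, log = log,
       removed = union(small, lowcov), cov_floor = cov_floor)
}

#' Create a curation action
#'
#' @param kind one of remove_plastid_boundary, remove_contig, remove_edge,
#'   split_contig, trim_contig.
#' @param target contig id; for remove_edge `"c1:s1--c2:s2"`; for
#'   split_contig `"contig@pos"` (1-based last base of the left part); for
#'   trim_contig `"contig@side@bp"`.
#' @param reason,evidence free-text provenance.
#' @export
curation_action <- function(kind, target, reason = "", evidence = "") {
  kind <- match.arg(kind, c("remove_plastid_boundary", "remove_contig",
                            "remove_edge", "split_contig", "trim_contig"))
  list(kind = kind, target = target, reason = reason, evidence = evidence)
}

parse_edge_target <- function(target) {
  parts <- strsplit(target, "--", fixed = TRUE)[[1]]
  if (length(parts) != 2) stop("bad edge target: ", target)
  t1 <- strsplit(parts[1], ":", fixed = TRUE)[[1]]
  t2 <- strsplit(parts[2], ":", fixed = TRUE)[[1]]
  list(c1 = t1[1], s1 = t1[2], c2 = t2[1], s2 = t2[2])
}

apply_one_action <- function(graph, action, idx) {
  fail <- function(msg) stop("curation action ", idx, " (", action$kind, " ",
                             action$target, "): ", msg, call. = FALSE)
  if (action$kind %in% c("remove_contig", "remove_plastid_boundary")) {
    if (!action$target %in% names(graph$contigs)) fail("unknown contig")
    graph <- drop_contigs(graph, action$target)
  } else if (action$kind == "remove_edge") {
    tp <- parse_edge_target(action$target)
    o <- orient_edge_endpoints(tp$c1, tp$s1, tp$c2, tp$s2)
    e <- graph$edges
    hit <- e$kind == "overlap" & e$c1 == o$c1 & e$s1 == o$s1 &
      e$c2 == o$c2 & e$s2 == o$s2
    if (!any(hit)) fail("no such overlap edge")
    graph$edges <- e[!hit, , drop = FALSE]
  } else if (action$kind == "split_contig") {
    parts <- strsplit(action$target, "@", fixed = TRUE)[[1]]
    id <- parts[1]; pos <- as.integer(parts[2])
    if (!id %in% names(graph$contigs)) fail("unknown contig")
    ct <- graph$contigs[[id]]
    if (is.na(pos) || pos < 1 || pos >= ct$length) fail("split position out of range")
    left <- mito_contig(paste0(id, ".1"), length = pos,
                        sequence = if (!is.null(ct$sequence)) substring(ct$sequence, 1, pos),
                        mean_coverage = ct$mean_coverage, origin = ct$origin,
                        role = "unclassified")
    right <- mito_contig(paste0(id, ".2"), length = ct$length - pos,
                         sequence = if (!is.null(ct$sequence)) substring(ct$sequence, pos + 1),
                         mean_coverage = ct$mean_coverage, origin = ct$origin,
                         role = "unclassified")
    ## edges on the old head move to the left part, old tail to the right;
    ## the two halves share no overlap (a split severs a misassembly)
    e <- graph$edges
    ov <- e$kind == "overlap"
    e$c1[ov & e$c1 == id & e$s1 == "head"] <- left$id
    e$c2[ov & e$c2 == id & e$s2 == "head"] <- left$id
    e$c1[ov & e$c1 == id & e$s1 == "tail"] <- right$id
    e$c2[ov & e$c2 == id & e$s2 == "tail"] <- right$id
    keep_ov <- e[ov & (e$c1 != id & e$c2 != id), c("c1", "s1", "c2", "s2",
                                                   "overlap_length")]
    contigs <- graph$contigs
    contigs[[id]] <- NULL
    contigs[[left$id]] <- left
    contigs[[right$id]] <- right
    graph <- assembly_graph(contigs, overlap_edges = keep_ov)
  } else if (action$kind == "trim_contig") {
    parts <- strsplit(action$target, "@", fixed = TRUE)[[1]]
    id <- parts[1]; side <- parts[2]; bp <- as.integer(parts[3])
    if (!id %in% names(graph$contigs)) fail("unknown contig")
    if (!side %in% TERMINUS_SIDES) fail("bad side")
    ct <- graph$contigs[[id]]
    if (is.na(bp) || bp < 1 || bp >= ct$length) fail("trim length out of range")
    ct$length <- ct$length - bp
    if (!is.null(ct$sequence)) {
      ct$sequence <- if (side == "head") substring(ct$sequence, bp + 1)
      else substring(ct$sequence, 1, ct$length)
    }
    graph$contigs[[id]] <- ct
    ## overlaps on the trimmed side no longer hold
    e <- graph$edges
    drop <- e$kind == "overlap" &
      ((e$c1 == id & e$s1 == side) | (e$c2 == id & e$s2 == side))
    graph$edges <- e[!drop, , drop = FALSE]
  }
  graph
}

#' Apply an ordered curation script
#'
#' Actions are applied in order; every action is logged together with graph
#' stats after it, so replaying the returned log on the original graph
#' reproduces the same final graph deterministically.
#'
#' @param graph an assembly graph.
#' @param actions list of [curation_action()] records.
#' @return list(graph, log).
#' @export
apply_curation_script <- function(graph, actions) {
  log <- curation_log_df()
  for (i in seq_along(actions)) {
    a <- actions[[i]]
    graph <- apply_one_action(graph, a, i)
    log <- log_action(log, graph, a$kind, a$target, a$reason %||% "",
                      a$evidence %||% "")
  }
  list(graph = graph, log = log)
}

#' Assign per-contig origins and summarise read shares
#'
#' Graph membership is the primary criterion: contigs in the final graph are
#' mitochondrial, contigs with a plastid-reference hit (and not in the graph)
#' are plastidial, and everything else is nuclear.
#'
#' @param graph the final curated assembly graph.
#' @param all_contigs list of every assembly contig (graph members included).
#' @param plastid_hits data.frame (contig_id, covered_fraction, ...) or NULL.
#' @param read_counts optional named numeric of reads per contig; when given
#'   the summary reports the read fraction per origin.
#' @param min_covered_fraction plastid-call threshold (default 0.8).
#' @return list(origins = named character, summary = data.frame).
#' @export
assign_origins <- function(graph, all_contigs, plastid_hits = NULL,
                           read_counts = NULL, min_covered_fraction = 0.8) {
  if (length(all_contigs) && is.null(names(all_contigs)))
    names(all_contigs) <- vapply(all_contigs, `[[`, character(1), "id")
  ids <- names(all_contigs)
  graph_members <- unique(unlist(lapply(graph$contigs, function(ct) {
    if (is.null(ct$members)) ct$id else ct$members$contig_id
  })))
  origins <- setNames(rep("nuclear", length(ids)), ids)
  if (!is.null(plastid_hits) && nrow(plastid_hits)) {
    pl <- unique(plastid_hits$contig_id[
      plastid_hits$covered_fraction >= min_covered_fraction])
    origins[intersect(pl, ids)] <- "plastidial"
  }
  origins[intersect(graph_members, ids)] <- "mitochondrial"
  summary <- data.frame(origin = c("mitochondrial", "plastidial", "nuclear"),
                        n_contigs = NA_integer_, reads = NA_real_,
                        read_share = NA_real_, stringsAsFactors = FALSE)
  summary$n_contigs <- vapply(summary$origin,
                              function(o) sum(origins == o), integer(1))
  if (!is.null(read_counts)) {
    rc <- setNames(rep(0, length(ids)), ids)
    rc[intersect(names(read_counts), ids)] <-
      read_counts[intersect(names(read_counts), ids)]
    tot <- sum(rc)
    summary$reads <- vapply(summary$origin,
                            function(o) sum(rc[origins == o]), numeric(1))
    summary$read_share <- if (tot > 0) summary$reads / tot else 0
  }
  list(origins = origins, summary = summary)
}
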