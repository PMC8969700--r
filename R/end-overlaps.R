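## End-overlap detection and seeded graph construction.
##
## Contigs from a De Bruijn assembly of a recombining circular genome end
## where repeats begin; neighbouring contigs share an exact end overlap
## (k-1 bp for k-mer assemblies).  The builder filters all-vs-all alignment
## hits down to significant end-to-end hits, converts them into terminus
## adjacency, and grows the graph breadth-first from high-confidence contigs
## (HCCs) only, so that low-confidence contigs enter only when connected.

#' Parameters for end-overlap detection and filtering
#'
#' @param min_overlap minimum accepted end-to-end hit length in bp
#'   (default 49).
#' @param end_window how far from a contig end (bp) an aligned interval may
#'   lie and still count as terminal (default 300; assemblers emitting padded
#'   ends may need 600).
#' @param min_identity minimum percent identity; the built-in exact detector
#'   always emits 100.
#' @return an `overlap_params` list.
#' @export
overlap_params <- function(min_overlap = 49L, end_window = 300L,
                         min_identity = 100) {
  stopifnot(min_overlap >= 1, end_window >= min_overlap)
  structure(list(min_overlap = as.integer(min_overlap),
                 end_window = as.integer(end_window),
                 min_identity = min_identity),
            class = "overlap_params")
}

#' High-confidence contig criteria
#'
#' Coverage/length mode calls a contig high-confidence when it is strictly
#' longer than `min_length` and has coverage strictly above `min_coverage`.
#' Consensus mode instead requires the contig to be recovered by every other
#' assembly (90 percent of its bases covered by hits below the e-value cap).
#'
#' @param mode "coverage_length" or "consensus".
#' @param min_length bp threshold (default 1000).
#' @param min_coverage coverage threshold (default 3000).
#' @param consensus_coverage_fraction fraction of bases that must be covered
#'   in consensus mode (default 0.90).
#' @param consensus_max_evalue e-value cap for consensus hits (default 1e-40).
#' @export
hcc_criteria <- function(mode = c("coverage_length", "consensus"),
                         min_length = 1000L, min_coverage = 3000,
                         consensus_coverage_fraction = 0.90,
                         consensus_max_evalue = 1e-40) {
  mode <- match.arg(mode)
  stopifnot(min_length > 0, min_coverage > 0,
            consensus_coverage_fraction > 0, consensus_max_evalue > 0)
  structure(list(mode = mode, min_length = as.integer(min_length),
                 min_coverage = min_coverage,
                 consensus_coverage_fraction = consensus_coverage_fraction,
                 consensus_max_evalue = consensus_max_evalue),
            class = "hcc_criteria")
}

overlap_hit_df <- function() {
  data.frame(query_id = character(), subject_id = character(),
             identity = numeric(), aln_length = integer(),
             q_start = integer(), q_end = integer(),
             s_start = integer(), s_end = integer(),
             evalue = numeric(), stringsAsFactors = FALSE)
}

#' Detect exact end overlaps between contigs
#'
#' Built-in substitute for an external all-vs-all aligner, exploiting the
#' fact that De Bruijn contigs overlap neighbours exactly.  For every ordered
#' contig pair and both strands it reports the maximal exact shared block of
#' at least `min_overlap` bp that lies at an end of both contigs (within
#' `end_window`).  Hits are reported symmetrically (A vs B and B vs A) in
#' 1-based inclusive coordinates; minus-strand hits carry `s_start > s_end`.
#'
#' @param contigs list of [mito_contig()] with sequences.
#' @param params an [overlap_params()].
#' @return data.frame of overlap hits (12-column tabular alignment dialect
#'   fields present: query_id, subject_id, identity, aln_length, q_start,
#'   q_end, s_start, s_end, evalue).
#' @export
detect_end_overlaps <- function(contigs, params = overlap_params()) {
  if (length(contigs) && is.null(names(contigs)))
    names(contigs) <- vapply(contigs, `[[`, character(1), "id")
  for (id in names(contigs)) {
    if (is.null(contigs[[id]]$sequence))
      stop("detect_end_overlaps: contig '", id, "' has no sequence")
  }
  ids <- sort(names(contigs))
  hits <- list()
  add_hit <- function(q, s, qs, qe, ss, se, len) {
    hits[[length(hits) + 1L]] <<- data.frame(
      query_id = q, subject_id = s, identity = 100, aln_length = len,
      q_start = qs, q_end = qe, s_start = ss, s_end = se, evalue = 0,
      stringsAsFactors = FALSE)
  }
  max_exact <- function(a, b) {
    ## maximal L with suffix(a, L) == prefix(b, L), L in [min_overlap, cap]
    cap <- min(params$end_window, nchar(a), nchar(b))
    if (cap < params$min_overlap) return(0L)
    for (L in seq(cap, params$min_overlap)) {
      if (substring(a, nchar(a) - L + 1L) == substring(b, 1L, L)) return(L)
    }
    0L
  }
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (j <= i) next
      A <- ids[i]; B <- ids[j]
      sa <- contigs[[A]]$sequence; sb <- contigs[[B]]$sequence
      la <- nchar(sa); lb <- nchar(sb)
      rb <- revcomp(sb)
      ## tail(A) -- head(B), plus strand
      L <- max_exact(sa, sb)
      if (L) { add_hit(A, B, la - L + 1L, la, 1L, L, L)
               add_hit(B, A, 1L, L, la - L + 1L, la, L) }
      ## head(A) -- tail(B), plus strand
      L <- max_exact(sb, sa)
      if (L) { add_hit(A, B, 1L, L, lb - L + 1L, lb, L)
               add_hit(B, A, lb - L + 1L, lb, 1L, L, L) }
      ## tail(A) -- tail(B), minus strand: suffix(A) == revcomp(suffix(B))
      L <- max_exact(sa, rb)
      if (L) { add_hit(A, B, la - L + 1L, la, lb, lb - L + 1L, L)
               add_hit(B, A, lb - L + 1L, lb, la, la - L + 1L, L) }
      ## head(A) -- head(B), minus strand: prefix(A) == revcomp(prefix(B))
      L <- max_exact(rb, sa)
      if (L) { add_hit(A, B, 1L, L, L, 1L, L)
               add_hit(B, A, 1L, L, L, 1L, L) }
    }
  }
  ## self-overlap of a circular singleton: suffix == prefix of one contig
  for (A in ids) {
    sa <- contigs[[A]]$sequence
    la <- nchar(sa)
    cap <- min(params$end_window, la %/% 2L)
    if (cap >= params$min_overlap) {
      for (L in seq(cap, params$min_overlap)) {
        if (substring(sa, la - L + 1L) == substring(sa, 1L, L)) {
          add_hit(A, A, la - L + 1L, la, 1L, L, L)
          break
        }
      }
    }
  }
  if (!length(hits)) return(overlap_hit_df())
  out <- do.call(rbind, hits)
  out[order(out$query_id, out$subject_id, out$q_start), , drop = FALSE]
}

near_end <- function(start, end, len, window) {
  ## which contig end (if any) the 1-based inclusive interval is terminal to
  lo <- min(start, end); hi <- max(start, end)
  head_ok <- lo <= window
  tail_ok <- len - hi < window
  ## prefer the end the interval actually touches most closely
  if (head_ok && (!tail_ok || (lo - 1L) <= (len - hi))) return("head")
  if (tail_ok) return("tail")
  NA_character_
}

#' Filter alignment hits to terminus adjacency
#'
#' Keeps hits of at least `min_overlap` bp whose aligned interval is terminal
#' (within `end_window` of an end) on both contigs and converts each into an
#' overlap edge between the touching termini.  Plus-strand hits join opposite
#' sides (tail--head / head--tail); minus-strand hits join equal sides
#' (tail--tail / head--head).  Hits spanning an entire contig are set aside
#' as containments: a contained contig is not an end-to-end neighbour, but
#' the containment list feeds curation.
#'
#' @param hits data.frame as produced by [detect_end_overlaps()] or read from
#'   tabular alignment output.
#' @param contigs contig list (for lengths).
#' @param params an [overlap_params()].
#' @return list with `adjacency` (data.frame c1, s1, c2, s2, overlap_length)
#'   and `contained` (data.frame contig_id, container_id).
#' @export
filter_end_to_end <- function(hits, contigs, params = overlap_params()) {
  if (length(contigs) && is.null(names(contigs)))
    names(contigs) <- vapply(contigs, `[[`, character(1), "id")
  lens <- vapply(contigs, `[[`, integer(1), "length")
  adjacency <- list()
  contained <- list()
  if (nrow(hits)) {
    unknown <- setdiff(unique(c(hits$query_id, hits$subject_id)), names(lens))
    if (length(unknown))
      stop("filter_end_to_end: hits reference unknown contigs: ",
           paste(unknown, collapse = ", "))
    hits <- hits[order(hits$query_id, hits$subject_id, hits$q_start), ,
                 drop = FALSE]
  }
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    if (h$aln_length < params$min_overlap) next
    if (h$identity < params$min_identity) next
    ql <- lens[[h$query_id]]; sl <- lens[[h$subject_id]]
    q_span <- abs(h$q_end - h$q_start) + 1L
    s_span <- abs(h$s_end - h$s_start) + 1L
    if (q_span >= ql || s_span >= sl) {
      inner <- if (q_span >= ql) h$query_id else h$subject_id
      outer <- if (q_span >= ql) h$subject_id else h$query_id
      contained[[length(contained) + 1L]] <-
        data.frame(contig_id = inner, container_id = outer,
                   stringsAsFactors = FALSE)
      next
    }
    minus <- h$s_start > h$s_end
    q_side <- near_end(h$q_start, h$q_end, ql, params$end_window)
    s_side <- near_end(h$s_start, h$s_end, sl, params$end_window)
    if (is.na(q_side) || is.na(s_side)) next
    ## interval must be fully inside the window of its end on both contigs
    q_lo <- min(h$q_start, h$q_end); q_hi <- max(h$q_start, h$q_end)
    s_lo <- min(h$s_start, h$s_end); s_hi <- max(h$s_start, h$s_end)
    in_window <- function(lo, hi, len, side) {
      if (side == "head") hi <= params$end_window
      else lo > len - params$end_window
    }
    if (!in_window(q_lo, q_hi, ql, q_side)) next
    if (!in_window(s_lo, s_hi, sl, s_side)) next
    ## strand rule: plus joins opposite sides, minus joins equal sides
    if (!minus && q_side == s_side) next
    if (minus && q_side != s_side) next
    adjacency[[length(adjacency) + 1L]] <- data.frame(
      c1 = h$query_id, s1 = q_side, c2 = h$subject_id, s2 = s_side,
      overlap_length = as.integer(h$aln_length), stringsAsFactors = FALSE)
  }
  adj <- if (length(adjacency)) {
    raw <- do.call(rbind, adjacency)
    o <- orient_edge_endpoints(raw$c1, raw$s1, raw$c2, raw$s2)
    unique(data.frame(c1 = o$c1, s1 = o$s1, c2 = o$c2, s2 = o$s2,
                      overlap_length = raw$overlap_length,
                      stringsAsFactors = FALSE))
  } else
    data.frame(c1 = character(), s1 = character(), c2 = character(),
               s2 = character(), overlap_length = integer(),
               stringsAsFactors = FALSE)
  cont <- if (length(contained)) unique(do.call(rbind, contained)) else
    data.frame(contig_id = character(), container_id = character(),
               stringsAsFactors = FALSE)
  list(adjacency = adj, contained = cont)
}

#' Select high-confidence contigs
#'
#' @param contigs contig list.
#' @param criteria an [hcc_criteria()].
#' @param consensus_found optional named logical (contig id -> recovered by
#'   all other assemblies), required in consensus mode; computing it from raw
#'   cross-assembly hit tables is the caller's job.
#' @return character vector of HCC ids.
#' @export
select_hccs <- function(contigs, criteria = hcc_criteria(),
                        consensus_found = NULL) {
  if (length(contigs) && is.null(names(contigs)))
    names(contigs) <- vapply(contigs, `[[`, character(1), "id")
  if (criteria$mode == "consensus") {
    if (is.null(consensus_found))
      stop("select_hccs: consensus mode needs the consensus_found vector")
    return(sort(names(which(consensus_found[names(contigs)]))))
  }
  lens <- vapply(contigs, `[[`, integer(1), "length")
  covs <- vapply(contigs, `[[`, numeric(1), "mean_coverage")
  if (any(is.na(covs)))
    stop("select_hccs: missing coverage for ",
         paste(names(contigs)[is.na(covs)], collapse = ", "))
  sort(names(contigs)[lens > criteria$min_length & covs > criteria$min_coverage])
}

#' Build the terminus graph by HCC-seeded breadth-first expansion
#'
#' Starting from the termini of all high-confidence contigs, the adjacency
#' list is expanded breadth-first; a low-confidence contig is integrated only
#' if reached from an HCC, everything unreachable is discarded.  The search
#' stops when no overlap leads to a new contig.
#'
#' @param contigs contig list.
#' @param adjacency data.frame (c1, s1, c2, s2, overlap_length) from
#'   [filter_end_to_end()].
#' @param hccs character vector of high-confidence contig ids.
#' @return an `assembly_graph` over the reached contigs.
#' @export
build_graph <- function(contigs, adjacency, hccs) {
  if (length(contigs) && is.null(names(contigs)))
    names(contigs) <- vapply(contigs, `[[`, character(1), "id")
  if (!length(hccs)) stop("build_graph: no entry points (empty HCC set)")
  missing <- setdiff(hccs, names(contigs))
  if (length(missing))
    stop("build_graph: unknown HCC ids: ", paste(missing, collapse = ", "))
  reached <- sort(unique(hccs))
  frontier <- reached
  while (length(frontier)) {
    nbr <- unique(c(adjacency$c2[adjacency$c1 %in% frontier],
                    adjacency$c1[adjacency$c2 %in% frontier]))
    frontier <- sort(setdiff(nbr, reached))
    reached <- c(reached, frontier)
  }
  reached <- sort(reached)
  keep <- adjacency[adjacency$c1 %in% reached & adjacency$c2 %in% reached, ,
                    drop = FALSE]
  sub <- contigs[reached]
  for (id in hccs) sub[[id]]$is_hcc <- TRUE
  assembly_graph(sub, overlap_edges = keep)
}
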