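# Fixtures built in code, plus independent oracles used by several test
# files.

# Ring in the style of the maize worked example: repeat "a" with head fork
# {c1, c8} and tail fork {c2, c9}, closed through c2-c8 and c9-c1, so the
# master is c1 a c2 c8 a c9.
maize_ring_graph <- function(contig_len = 1000L, repeat_len = 500L,
                           overlap = 50L) {
  contigs <- list(
    mito_contig("a", length = repeat_len, mean_coverage = 8000),
    mito_contig("c1", length = contig_len, mean_coverage = 4000),
    mito_contig("c2", length = contig_len, mean_coverage = 4000),
    mito_contig("c8", length = contig_len, mean_coverage = 4000),
    mito_contig("c9", length = contig_len, mean_coverage = 4000))
  names(contigs) <- vapply(contigs, `[[`, character(1), "id")
  edges <- data.frame(
    c1 = c("c1", "c8", "a", "a", "c2", "c9"),
    s1 = c("tail", "tail", "tail", "tail", "tail", "tail"),
    c2 = c("a", "a", "c2", "c9", "c8", "c1"),
    s2 = c("head", "head", "head", "head", "head", "head"),
    overlap_length = overlap, stringsAsFactors = FALSE)
  assembly_graph(contigs, overlap_edges = edges)
}

# Assembly graph built directly from a planted genome's truth topology
# (all lengths known, no sequences); roles pre-assigned from the truth.
truth_topology_graph <- function(genome, contig_len = 1000L) {
  ids <- genome$truth$contig_ids
  contigs <- lapply(ids, function(id)
    mito_contig(id, length = if (startsWith(id, "r"))
      genome$repeat_lengths[[id]] else contig_len))
  names(contigs) <- ids
  g <- assembly_graph(contigs, overlap_edges = genome$truth$edges)
  detect_double_forks(g)$graph
}

# Run the full construction pipeline on a planted genome.
planted_to_graph <- function(genome, ...) {
  contigs <- fragment_to_contigs(genome, ...)
  flt <- filter_end_to_end(detect_end_overlaps(contigs), contigs)
  gr <- build_graph(contigs, flt$adjacency, select_hccs(contigs))
  detect_double_forks(gr)
}

# Independent exhaustive closed-walk oracle: plain recursion from every
# start terminus in both orientations, no pruning, its own canonical form.
oracle_closed_walks <- function(graph, repeat_budget = 2L,
                                unique_budget = 1L,
                                require_distinct = TRUE) {
  oe <- graph$edges[graph$edges$kind == "overlap", , drop = FALSE]
  roles <- vapply(graph$contigs, `[[`, character(1), "role")
  budget <- setNames(ifelse(roles == "repeat", repeat_budget, unique_budget),
                     names(roles))
  nbrs <- function(cc, ss) {
    out <- list()
    for (i in seq_len(nrow(oe))) {
      if (oe$c1[i] == cc && oe$s1[i] == ss)
        out[[length(out) + 1L]] <- list(c = oe$c2[i], s = oe$s2[i])
      else if (oe$c2[i] == cc && oe$s2[i] == ss)
        out[[length(out) + 1L]] <- list(c = oe$c1[i], s = oe$s1[i])
    }
    out
  }
  canon <- function(cv, ov) {
    items <- paste0(cv, ov)
    ritems <- paste0(rev(cv), ifelse(rev(ov) == "+", "-", "+"))
    n <- length(items)
    best <- NULL
    for (v in list(items, ritems)) for (r in seq_len(n)) {
      cand <- paste(c(v[r:n], v[seq_len(r - 1L)]), collapse = ",")
      if (is.null(best) || cand < best) best <- cand
    }
    best
  }
  found <- new.env(parent = emptyenv())
  go <- function(cv, ov, cnt) {
    cc <- cv[length(cv)]
    exit_s <- if (ov[length(ov)] == "+") "tail" else "head"
    entry0 <- if (ov[1] == "+") "head" else "tail"
    for (nb in nbrs(cc, exit_s)) {
      if (nb$c == cv[1] && nb$s == entry0 &&
          (!require_distinct || length(cv) > 1L)) {
        found[[canon(cv, ov)]] <- TRUE
      }
      if (cnt[nb$c] + 1L <= budget[nb$c]) {
        cnt2 <- cnt; cnt2[nb$c] <- cnt2[nb$c] + 1L
        go(c(cv, nb$c), c(ov, if (nb$s == "head") "+" else "-"), cnt2)
      }
    }
  }
  for (cc in names(roles)) {
    if (budget[cc] < 1L) next
    for (oo in c("+", "-")) {
      cnt <- setNames(integer(length(roles)), names(roles))
      cnt[cc] <- 1L
      go(cc, oo, cnt)
    }
  }
  sort(ls(found))
}

oracle_canonical_key <- function(steps) {
  # the oracle's canonical form applied to a package walk, for set
  # comparison
  items <- paste0(steps$contig_id, steps$orientation)
  ritems <- paste0(rev(steps$contig_id),
                   ifelse(rev(steps$orientation) == "+", "-", "+"))
  n <- length(items)
  best <- NULL
  for (v in list(items, ritems)) for (r in seq_len(n)) {
    cand <- paste(c(v[r:n], v[seq_len(r - 1L)]), collapse = ",")
    if (is.null(best) || cand < best) best <- cand
  }
  best
}

# Exhaustive optimal 1-D k-means: optimal clusters are contiguous in sorted
# order, so try every composition of the sorted values into k runs.
oracle_kmeans_1d <- function(x, k) {
  sx <- sort(x)
  n <- length(sx)
  cuts <- utils::combn(n - 1L, k - 1L)
  best_ss <- Inf
  best <- NULL
  for (j in seq_len(ncol(cuts))) {
    b <- c(0L, cuts[, j], n)
    ss <- 0
    grp <- integer(n)
    for (g in seq_len(k)) {
      idx <- (b[g] + 1L):b[g + 1L]
      ss <- ss + sum((sx[idx] - mean(sx[idx]))^2)
      grp[idx] <- g
    }
    if (ss < best_ss - 1e-9) { best_ss <- ss; best <- grp }
  }
  list(ss = best_ss, groups = best, sorted = sx)
}

# Brute-force window scan: a repeated block of >= min_len implies a
# duplicated min_len-window (within the forward strand, or between forward
# and reverse-complement windows at different loci).
oracle_has_repeat <- function(sequence, min_len) {
  n <- nchar(sequence)
  st <- seq_len(n - min_len + 1L)
  wf <- substring(sequence, st, st + min_len - 1L)
  if (anyDuplicated(wf) > 0L) return(TRUE)
  rc <- mitograph::revcomp(sequence)
  wr <- substring(rc, st, st + min_len - 1L)
  m <- match(wf, wr)
  hit <- !is.na(m) & (n - (m + min_len - 1L) + 1L) != st
  any(hit)
}

within_ss <- function(x, groups) {
  sum(vapply(unique(groups), function(g) {
    v <- x[groups == g]
    sum((v - mean(v))^2)
  }, numeric(1)))
}
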