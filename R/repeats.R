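## Recombinogenic repeat pairs and their junction variants.
##
## A repeat present twice in a circular genome collapses into a single
## contig whose two termini each touch two alternative unique contigs: a
## "double fork".  The four head x tail combinations are the
## contig-repeat-contig (CRC) junction variants whose stoichiometry reflects
## recombination activity.  Size classes (SSR < ISR < LSR) come from 1-D
## k-means on repeat lengths.

REPEAT_CATEGORIES <- c("SSR", "ISR", "LSR")

#' Detect double forks and flag repeat contigs
#'
#' A contig is a recombinogenic repeat candidate when both of its termini
#' carry overlap edges to at least two distinct other contigs.  Contigs
#' forked on one side only are reported separately: they may force a second
#' traversal during reconstruction but are not repeat pairs.
#'
#' @param graph a curated assembly graph.
#' @return list with `graph` (roles updated: repeat / unique), `rrps` (list
#'   of repeat-pair records: repeat_contig_id, length, category, fork_head,
#'   fork_tail data.frames) and `single_forks` (character vector).
#' @export
detect_double_forks <- function(graph) {
  ids <- names(graph$contigs)
  rrps <- list()
  single <- character()
  fork <- function(id, side) {
    nb <- terminus_neighbors(graph, id, side)
    nb[nb$contig != id, , drop = FALSE]
  }
  for (id in ids) {
    fh <- fork(id, "head")
    ft <- fork(id, "tail")
    ## fork size counts distinct neighbour termini (vertices): the two
    ## termini of one flanking contig are two alternatives
    nh <- nrow(unique(fh[, c("contig", "side")]))
    nt <- nrow(unique(ft[, c("contig", "side")]))
    if (nh >= 2 && nt >= 2) {
      graph$contigs[[id]]$role <- "repeat"
      rrps[[id]] <- list(repeat_contig_id = id,
                         length = graph$contigs[[id]]$length,
                         category = "unassigned",
                         fork_head = fh, fork_tail = ft)
    } else {
      graph$contigs[[id]]$role <- "unique"
      if (nh >= 2 || nt >= 2) single <- c(single, id)
    }
  }
  graph$edges$kind[graph$edges$kind %in% c("contig", "repeat")] <-
    ifelse(graph$edges$c1[graph$edges$kind %in% c("contig", "repeat")] %in%
             names(rrps), "repeat", "contig")
  list(graph = graph, rrps = rrps, single_forks = sort(single))
}

crc_key <- function(left, rep_id, right) {
  a <- paste(left, rep_id, right, sep = ",")
  b <- paste(right, rep_id, left, sep = ",")
  if (a <= b) a else b
}

#' Enumerate the contig-repeat-contig variants of a double fork
#'
#' Takes the Cartesian product of the head-side and tail-side fork members;
#' a 2x2 fork yields exactly four CRCs.  Orientations are induced by the
#' overlap-edge terminus rule: the left contig is read toward the repeat,
#' the repeat forward (head to tail), the right contig away from it.  The
#' canonical key is the lexicographically smaller of the id string and its
#' reversal, so a junction and its reverse complement count as one.
#'
#' @param rrp one repeat-pair record from [detect_double_forks()].
#' @param graph the assembly graph (unused fork data is re-checked against it).
#' @return data.frame with left/repeat/right ids and orientations plus `key`.
#' @export
enumerate_crcs <- function(rrp, graph = NULL) {
  fh <- unique(rrp$fork_head[, c("contig", "side")])
  ft <- unique(rrp$fork_tail[, c("contig", "side")])
  if (nrow(fh) < 2 || nrow(ft) < 2)
    stop("enumerate_crcs: degenerate fork at ", rrp$repeat_contig_id,
         " (need >= 2 distinct neighbour termini per side)")
  out <- expand.grid(h = seq_len(nrow(fh)), t = seq_len(nrow(ft)))
  crcs <- data.frame(
    left = fh$contig[out$h],
    ## left contig walks toward the repeat: it exits via the linked terminus
    left_orientation = ifelse(fh$side[out$h] == "tail", "+", "-"),
    repeat_id = rrp$repeat_contig_id,
    repeat_orientation = "+",
    right = ft$contig[out$t],
    ## right contig walks away from the repeat: it enters via the linked side
    right_orientation = ifelse(ft$side[out$t] == "head", "+", "-"),
    stringsAsFactors = FALSE)
  crcs$key <- mapply(crc_key, crcs$left, crcs$repeat_id, crcs$right)
  crcs[order(crcs$key), , drop = FALSE]
}

#' Scan a sequence for exact repeats
#'
#' Finds maximal exact repeated blocks of at least `min_len` bp on both
#' strands by seeding on shared `min_len`-mers and extending, then merges
#' the occurrences into non-redundant intervals with copy counts.
#'
#' @param sequence a DNA string.
#' @param min_len minimum repeat length in bp (default 50).
#' @param circular treat the sequence as circular (default FALSE).
#' @return data.frame (start, end, length, n_copies, strands) of merged
#'   repeat intervals, 1-based inclusive.
#' @export
scan_repeats <- function(sequence, min_len = 50L, circular = FALSE) {
  n <- nchar(sequence)
  empty <- data.frame(start = integer(), end = integer(), length = integer(),
                      n_copies = integer(), strands = character(),
                      stringsAsFactors = FALSE)
  if (n < 2L * min_len) return(empty)
  seq_fwd <- sequence
  if (circular) seq_fwd <- paste0(sequence, substring(sequence, 1, min_len - 1L))
  m <- nchar(seq_fwd)
  starts <- seq_len(m - min_len + 1L)
  kmers <- substring(seq_fwd, starts, starts + min_len - 1L)
  rc <- revcomp(seq_fwd)
  rc_kmers <- substring(rc, starts, starts + min_len - 1L)
  ## map each k-mer to forward positions; then pair up duplicates and
  ## forward/reverse co-occurrences
  pos_by_kmer <- split(starts, kmers)
  pairs <- list()
  for (p in pos_by_kmer[lengths(pos_by_kmer) > 1L]) {
    cmb <- utils::combn(p, 2)
    pairs[[length(pairs) + 1L]] <-
      data.frame(i = cmb[1, ], j = cmb[2, ], strand = "+",
                 stringsAsFactors = FALSE)
  }
  rc_pos_by_kmer <- split(starts, rc_kmers)
  shared <- intersect(names(pos_by_kmer), names(rc_pos_by_kmer))
  for (k in shared) {
    g <- expand.grid(i = pos_by_kmer[[k]], j = rc_pos_by_kmer[[k]])
    ## j is a position in the reverse complement; map to forward coordinates
    g$j <- m - (g$j + min_len - 1L) + 1L
    g <- g[g$i < g$j, , drop = FALSE]  # dedupe mirrored pairs
    if (nrow(g)) pairs[[length(pairs) + 1L]] <-
        data.frame(i = g$i, j = g$j, strand = "-", stringsAsFactors = FALSE)
  }
  if (!length(pairs)) return(empty)
  pr <- unique(do.call(rbind, pairs))
  ## collapse seeds on the same diagonal into maximal blocks
  pr$diag <- ifelse(pr$strand == "+", pr$j - pr$i, pr$j + pr$i)
  pr <- pr[order(pr$strand, pr$diag, pr$i), , drop = FALSE]
  blocks <- list()
  grp <- paste(pr$strand, pr$diag)
  for (g in split(pr, grp)) {
    i0 <- g$i[1]; prev <- g$i[1]
    for (r in seq_len(nrow(g))) {
      if (g$i[r] > prev + 1L) {
        blocks[[length(blocks) + 1L]] <-
          data.frame(i = i0, len = prev - i0 + min_len, j = g$j[g$i == i0][1],
                     strand = g$strand[1], stringsAsFactors = FALSE)
        i0 <- g$i[r]
      }
      prev <- g$i[r]
    }
    blocks[[length(blocks) + 1L]] <-
      data.frame(i = i0, len = prev - i0 + min_len, j = g$j[g$i == i0][1],
                 strand = g$strand[1], stringsAsFactors = FALSE)
  }
  bl <- do.call(rbind, blocks)
  bl <- bl[bl$len >= min_len, , drop = FALSE]
  if (!nrow(bl)) return(empty)
  ## occurrences: both mates of every block
  occ <- rbind(
    data.frame(start = bl$i, end = bl$i + bl$len - 1L, strand = "+",
               stringsAsFactors = FALSE),
    data.frame(start = ifelse(bl$strand == "+", bl$j,
                              bl$j - bl$len + min_len),
               end = ifelse(bl$strand == "+", bl$j + bl$len - 1L,
                            bl$j + min_len - 1L),
               strand = bl$strand, stringsAsFactors = FALSE))
  occ$start <- ((occ$start - 1L) %% n) + 1L
  occ$end <- ((occ$end - 1L) %% n) + 1L
  wrap <- occ$end < occ$start  # circular padding artefacts
  occ$end[wrap] <- n
  occ <- unique(occ[order(occ$start, occ$end), , drop = FALSE])
  ## merge overlapping occurrences into non-redundant intervals
  merged <- list()
  cur <- occ[1, ]
  cur$n_copies <- 1L
  strands <- cur$strand
  if (nrow(occ) > 1) for (r in 2:nrow(occ)) {
    if (occ$start[r] <= cur$end) {
      cur$end <- max(cur$end, occ$end[r])
      cur$n_copies <- cur$n_copies + 1L
      strands <- c(strands, occ$strand[r])
    } else {
      cur$strands <- paste(sort(unique(strands)), collapse = "/")
      merged[[length(merged) + 1L]] <- cur
      cur <- occ[r, ]; cur$n_copies <- 1L; strands <- cur$strand
    }
  }
  cur$strands <- paste(sort(unique(strands)), collapse = "/")
  merged[[length(merged) + 1L]] <- cur
  out <- do.call(rbind, merged)
  out$length <- out$end - out$start + 1L
  out[, c("start", "end", "length", "n_copies", "strands")]
}

#' Classify repeat lengths into size categories by 1-D k-means
#'
#' Runs k-means with `k` clusters (25 restarts under the given seed, lowest
#' within-cluster sum kept) on the repeat lengths and labels the clusters
#' SSR < ISR < LSR by ascending centre.
#'
#' @param lengths integer vector of repeat lengths in bp.
#' @param k number of clusters (default 3).
#' @param seed RNG seed for the restarts.
#' @return list(category = character per length, model = list(k, centers,
#'   ranges)).
#' @export
classify_repeat_sizes <- function(lengths, k = 3L, seed = 1L) {
  if (length(lengths) < k)
    stop("classify_repeat_sizes: need at least k = ", k, " lengths")
  if (length(unique(lengths)) < k)
    stop("classify_repeat_sizes: fewer than k distinct lengths; ",
         "the clustering is degenerate")
  has_seed <- exists(".Random.seed", envir = globalenv())
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_seed) assign(".Random.seed", old, envir = globalenv()),
          add = TRUE)
  set.seed(seed)
  km <- kmeans(as.numeric(lengths), centers = k, nstart = 25L)
  ord <- order(km$centers)
  labels <- if (k == 3L) REPEAT_CATEGORIES else paste0("C", seq_len(k))
  lab_by_cluster <- character(k)
  lab_by_cluster[ord] <- labels
  category <- lab_by_cluster[km$cluster]
  ranges <- lapply(labels, function(lb) range(lengths[category == lb]))
  names(ranges) <- labels
  list(category = category,
       model = list(k = k, centers = sort(as.numeric(km$centers)),
                    ranges = ranges))
}

#' Repeat-pair table
#'
#' @param rrps list of repeat-pair records (optionally after size
#'   classification).
#' @return data.frame (repeat_id, length, category, fork_head, fork_tail).
#' @export
rrp_table <- function(rrps) {
  do.call(rbind, lapply(rrps, function(r) data.frame(
    repeat_id = r$repeat_contig_id, length = r$length,
    category = r$category,
    fork_head = paste(sort(unique(r$fork_head$contig)), collapse = "|"),
    fork_tail = paste(sort(unique(r$fork_tail$contig)), collapse = "|"),
    stringsAsFactors = FALSE)))
}
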