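## Planted ground truth: circular genomes with repeat pairs, fragmentation
## into overlapping contigs, coverage tiers and simulated spanning reads.
##
## The generator emulates what a k-mer assembler produces from a recombining
## circular mitochondrial genome: contigs that break at repeat boundaries
## and share exactly k-1 bp at every junction, a repeat collapsed into a
## single contig, organelle coverage far above nuclear background, and
## mate-pair / long-read data whose spanning reads encode planted junction
## abundances.  Every artifact is deterministic under its seed.

#' Specify one planted repeat pair
#'
#' @param length repeat length in bp; NULL draws from the tier.
#' @param mode "direct" (both copies same strand) or "inverted".
#' @param tier "LSR" (825-1625 bp), "ISR" (239-479 bp) or "SSR"
#'   (150-200 bp); used when `length` is NULL.
#' @export
repeat_spec <- function(length = NULL, mode = c("direct", "inverted"),
                        tier = c("ISR", "LSR", "SSR")) {
  mode <- match.arg(mode)
  tier <- match.arg(tier)
  list(length = length, mode = mode, tier = tier)
}

REPEAT_TIER_RANGES <- list(LSR = c(825, 1625), ISR = c(239, 479),
                           SSR = c(150, 200))

circ_substr <- function(s, start, len) {
  n <- nchar(s)
  start <- ((start - 1L) %% n) + 1L
  if (start + len - 1L <= n) return(substring(s, start, start + len - 1L))
  paste0(substring(s, start, n), substring(s, 1L, start + len - 1L - n))
}

#' Plant a circular genome with repeat pairs
#'
#' Builds a random circular sequence of `n_unique` unique segments with each
#' repeat inserted twice (second copy reverse-complemented for inverted
#' mode), arranged so every repeat is flanked by distinct unique contigs on
#' both sides, i.e. collapses into a proper double fork.  Requires
#' `n_unique >= 2 * length(repeat_specs)`; extra unique contigs arise from
#' additional breakpoints inside segments.
#'
#' @param n_unique number of unique contigs (>= 2 per repeat).
#' @param repeat_specs list of [repeat_spec()]; may be empty for a plain
#'   ring.
#' @param seed RNG seed.
#' @param total_length circular genome length in bp; NULL draws uniformly
#'   from 50-450 kb.
#' @param k assembly k-mer size; junction overlaps are k-1 bp.
#' @param min_segment minimum unique contig span in bp (default 1500, so
#'   unique contigs pass the high-confidence length bar).
#' @return a `planted_genome`: sequence, elements table, k, and a `truth`
#'   list (expected contigs, edges, repeat ids, CRC keys, master walk and
#'   length).
#' @export
plant_genome <- function(n_unique = 4L, repeat_specs = list(), seed = 1L,
                         total_length = NULL, k = 90L, min_segment = 1500L) {
  set.seed(seed)
  m <- length(repeat_specs)
  if (m > 0 && n_unique < 2L * m)
    stop("plant_genome: need n_unique >= 2 per repeat (", n_unique, " < ",
         2L * m, ")")
  if (n_unique < 1L) stop("plant_genome: need at least one unique segment")
  rep_lens <- integer(m); rep_modes <- character(m)
  for (i in seq_len(m)) {
    sp <- repeat_specs[[i]]
    rep_lens[i] <- as.integer(sp$length %||%
      round(runif(1, REPEAT_TIER_RANGES[[sp$tier]][1],
                  REPEAT_TIER_RANGES[[sp$tier]][2])))
    rep_modes[i] <- sp$mode
    if (rep_lens[i] < k)
      stop("plant_genome: repeat ", i, " shorter than k (", rep_lens[i],
           " < ", k, "); junction overlaps would spill over")
  }
  if (is.null(total_length)) total_length <- round(runif(1, 50000, 450000))
  unique_total <- total_length - 2L * sum(rep_lens)
  if (unique_total < n_unique * min_segment)
    stop("plant_genome: total_length too small for ", n_unique,
         " segments of >= ", min_segment, " bp plus repeats")
  ## segment lengths: random split respecting the minimum
  w <- runif(n_unique)
  extra <- floor((unique_total - n_unique * min_segment) * w / sum(w))
  seg_lens <- min_segment + extra
  seg_lens[1] <- seg_lens[1] + (unique_total - sum(seg_lens))
  ## circle layout: 2m blocks of unique segments alternating with repeat
  ## copies (repeat j occupies slots j and j+m, so its flanks differ); with
  ## no repeats, one block holds every segment
  n_blocks <- max(2L * m, 1L)
  block_of <- rep(seq_len(n_blocks), length.out = n_unique)
  slot_repeat <- if (m) rep(seq_len(m), 2L) else integer()
  rep_seqs <- vapply(rep_lens, random_dna, character(1))
  elements <- list()
  genome <- character(0)
  pos <- 1L
  uid <- 0L
  push <- function(type, id, s, orientation = "+") {
    elements[[length(elements) + 1L]] <<- data.frame(
      type = type, id = id, start = pos, end = pos + nchar(s) - 1L,
      orientation = orientation, stringsAsFactors = FALSE)
    genome[length(genome) + 1L] <<- s
    pos <<- pos + nchar(s)
  }
  for (b in seq_len(n_blocks)) {
    for (si in which(block_of == b)) {
      uid <- uid + 1L
      push("unique", sprintf("u%02d", uid), random_dna(seg_lens[si]))
    }
    if (m) {
      j <- slot_repeat[b]
      inverted <- rep_modes[j] == "inverted" && b > m  # second copy flips
      push("repeat", paste0("r", j),
           if (inverted) revcomp(rep_seqs[j]) else rep_seqs[j],
           orientation = if (inverted) "-" else "+")
    }
  }
  elements <- do.call(rbind, elements)
  sequence <- paste(genome, collapse = "")
  truth <- planted_truth(elements, rep_lens, rep_modes, nchar(sequence), k)
  rep_ids <- vapply(seq_len(m), function(i) paste0("r", i), character(1))
  structure(list(sequence = sequence, elements = elements,
                 repeat_lengths = setNames(rep_lens, rep_ids),
                 repeat_modes = setNames(rep_modes, rep_ids),
                 k = as.integer(k), seed = seed,
                 truth = truth),
            class = "planted_genome")
}

planted_truth <- function(elements, rep_lens, rep_modes, genome_len, k) {
  n <- nrow(elements)
  nxt <- c(seq_len(n)[-1], 1L)
  exit_s <- ifelse(elements$type == "unique", "tail",
                   ifelse(elements$orientation == "+", "tail", "head"))
  entry_s <- ifelse(elements$type == "unique", "head",
                    ifelse(elements$orientation == "+", "head", "tail"))
  edges <- data.frame(c1 = elements$id, s1 = exit_s,
                      c2 = elements$id[nxt], s2 = entry_s[nxt],
                      overlap_length = k - 1L, stringsAsFactors = FALSE)
  rep_ids <- unique(elements$id[elements$type == "repeat"])
  crc_keys <- character()
  for (i in which(elements$type == "repeat")) {
    prev <- if (i == 1L) n else i - 1L
    nx <- if (i == n) 1L else i + 1L
    crc_keys <- c(crc_keys, crc_key(elements$id[prev], elements$id[i],
                                    elements$id[nx]))
  }
  master_steps <- data.frame(contig_id = elements$id,
                             orientation = elements$orientation,
                             stringsAsFactors = FALSE)
  list(contig_ids = unique(elements$id),
       n_contigs = length(unique(elements$id)),
       edges = edges,
       rrp_ids = rep_ids,
       crc_keys = sort(unique(crc_keys)),
       master_steps = master_steps,
       master_length = genome_len)
}

#' Fragment a planted genome into contigs with coverage
#'
#' Unique segments become contigs that carry k-1 bp of the preceding element
#' at their head and, when followed by a repeat copy, k-1 bp of the copy at
#' their tail; each repeat becomes one contig (forward strand).  Every
#' junction therefore shares exactly k-1 bp.  Coverage is assigned by
#' origin tier; optional decoy contigs emulate plastid/nuclear
#' contamination (unconnected, lower tiers).
#'
#' @param genome a `planted_genome`.
#' @param coverage named tiers, default c(mitochondrial = 5000,
#'   plastidial = 500, nuclear = 30).
#' @param n_plastid,n_nuclear decoy contig counts (default 0).
#' @param decoy_length decoy contig length in bp (default 2000).
#' @return named list of [mito_contig()] records.
#' @export
fragment_to_contigs <- function(genome,
                                coverage = c(mitochondrial = 5000,
                                             plastidial = 500, nuclear = 30),
                                n_plastid = 0L, n_nuclear = 0L,
                                decoy_length = 2000L) {
  k <- genome$k
  el <- genome$elements
  n <- nrow(el)
  seqs <- character(n)
  prv <- c(n, seq_len(n - 1L))
  nxt <- c(seq_len(n)[-1], 1L)
  contigs <- list()
  for (i in seq_len(n)) {
    if (el$type[i] == "repeat") {
      id <- el$id[i]
      if (!is.null(contigs[[id]])) next
      s <- circ_substr(genome$sequence, el$start[i], el$end[i] - el$start[i] + 1L)
      if (el$orientation[i] == "-") s <- revcomp(s)
      contigs[[id]] <- mito_contig(id, sequence = s,
                                   mean_coverage = coverage[["mitochondrial"]],
                                   origin = "unknown")
    } else {
      start <- el$start[i] - (k - 1L)
      len <- el$end[i] - el$start[i] + 1L + (k - 1L)
      if (el$type[nxt[i]] == "repeat") len <- len + (k - 1L)
      s <- circ_substr(genome$sequence, start, len)
      contigs[[el$id[i]]] <- mito_contig(el$id[i], sequence = s,
                                         mean_coverage = coverage[["mitochondrial"]],
                                         origin = "unknown")
    }
  }
  for (j in seq_len(n_plastid)) {
    id <- sprintf("pl%02d", j)
    contigs[[id]] <- mito_contig(id, sequence = random_dna(decoy_length),
                                 mean_coverage = coverage[["plastidial"]],
                                 origin = "unknown")
  }
  for (j in seq_len(n_nuclear)) {
    id <- sprintf("nc%02d", j)
    contigs[[id]] <- mito_contig(id, sequence = random_dna(decoy_length),
                                 mean_coverage = coverage[["nuclear"]],
                                 origin = "unknown")
  }
  contigs
}

## Linear/circular layout of a step sequence: where each oriented step sits
## on the emitted molecule (junction overlaps shared between neighbours).
molecule_layout <- function(graph, steps, circular = FALSE) {
  n <- nrow(steps)
  lens <- vapply(steps$contig_id, function(id) graph$contigs[[id]]$length,
                 integer(1))
  ov <- integer(n)
  lastj <- if (circular) n else n - 1L
  for (i in seq_len(lastj)) {
    j <- if (i == n) 1L else i + 1L
    e <- find_overlap_edge(graph, steps$contig_id[i],
                           exit_side(steps$orientation[i]),
                           steps$contig_id[j],
                           entry_side(steps$orientation[j]))
    if (is.null(e)) stop("molecule_layout: missing junction edge at step ", i)
    ov[i] <- e$overlap_length
  }
  pos <- cumsum(c(1L, head(lens, -1L) - head(ov, -1L)))
  total <- sum(lens) - sum(ov[seq_len(lastj)])
  list(steps = steps, pos = pos, lens = lens, total = total,
       circular = circular)
}

locate_on_molecule <- function(layout, p) {
  ## step index whose interval contains position p (first match)
  hit <- which(p >= layout$pos & p <= layout$pos + layout$lens - 1L)
  if (!length(hit)) return(NA_integer_)
  hit[1]
}

#' Simulate mate pairs and long reads over a molecule population
#'
#' Molecules are oriented step sequences (e.g. CRC junction molecules or
#' whole walks) with relative abundances.  Molecules are drawn proportional
#' to abundance times the number of admissible start positions, so junction
#' variant counts recover the planted abundances without length bias.
#' Placements are exact truth placements (identity as configured); mapping
#' noise is out of scope.
#'
#' @param graph assembly graph providing contig lengths and junctions.
#' @param molecules list of step data.frames (contig_id, orientation),
#'   treated as linear molecules.
#' @param abundances numeric vector summing to 1.
#' @param n_pairs,n_long read counts.
#' @param insert_mean,insert_sd mate-pair insert size model (default
#'   5000/300 bp).
#' @param read_length mate length in bp (default 150).
#' @param long_meanlog,long_sdlog log-normal long-read length model
#'   (defaults log(8000), 0.25).
#' @param identity percent identity stamped on long-read hits (default 100;
#'   set lower to emulate a uniform error rate).
#' @param seed RNG seed.
#' @return list(pairs, long_hits): placement and hit data.frames as consumed
#'   by [count_matepair_support()] and [chain_and_filter_ccs()].
#' @export
simulate_spanning_reads <- function(graph, molecules, abundances,
                                    n_pairs = 0L, n_long = 0L,
                                    insert_mean = 5000, insert_sd = 300,
                                    read_length = 150L,
                                    long_meanlog = log(8000),
                                    long_sdlog = 0.25,
                                    identity = 100, seed = 1L) {
  if (!length(molecules)) stop("simulate_spanning_reads: empty population")
  stopifnot(abs(sum(abundances) - 1) < 1e-6,
            length(abundances) == length(molecules))
  set.seed(seed)
  layouts <- lapply(molecules, function(st) molecule_layout(graph, st))
  totals <- vapply(layouts, `[[`, numeric(1), "total")
  pairs <- list()
  if (n_pairs > 0) {
    inserts <- pmax(2L * read_length,
                    round(rnorm(n_pairs, insert_mean, insert_sd)))
    for (r in seq_len(n_pairs)) {
      ins <- inserts[r]
      slots <- pmax(0, totals - ins + 1)
      wgt <- abundances * slots
      if (all(wgt == 0)) next
      mi <- sample.int(length(molecules), 1L, prob = wgt)
      ly <- layouts[[mi]]
      a <- sample.int(totals[mi] - ins + 1L, 1L)
      rid <- sprintf("mp%06d", r)
      for (mate in 1:2) {
        mstart <- if (mate == 1) a else a + ins - read_length
        mid <- mstart + read_length %/% 2L
        si <- locate_on_molecule(ly, mid)
        if (is.na(si)) next
        ## clamp to the step, then convert to contig coordinates (the
        ## stored strand), respecting the step orientation
        o1 <- max(0L, mstart - ly$pos[si])
        o2 <- min(ly$lens[si] - 1L, mstart + read_length - 1L - ly$pos[si])
        fwd <- ly$steps$orientation[si] == "+"
        cs <- if (fwd) o1 + 1L else ly$lens[si] - o2
        ce <- if (fwd) o2 + 1L else ly$lens[si] - o1
        pairs[[length(pairs) + 1L]] <- data.frame(
          read_id = rid, mate = mate,
          contig_id = ly$steps$contig_id[si],
          start = cs, end = ce,
          strand = if (xor(mate == 2, !fwd)) "-" else "+",
          identity = 100, stringsAsFactors = FALSE)
      }
    }
  }
  long_hits <- list()
  if (n_long > 0) {
    rl <- round(rlnorm(n_long, long_meanlog, long_sdlog))
    for (r in seq_len(n_long)) {
      len <- min(rl[r], max(totals))
      slots <- pmax(0, totals - len + 1)
      wgt <- abundances * slots
      if (all(wgt == 0)) next
      mi <- sample.int(length(molecules), 1L, prob = wgt)
      ly <- layouts[[mi]]
      a <- sample.int(totals[mi] - len + 1L, 1L)
      b <- a + len - 1L
      rid <- sprintf("lr%06d", r)
      for (si in seq_along(ly$pos)) {
        lo <- max(a, ly$pos[si])
        hi <- min(b, ly$pos[si] + ly$lens[si] - 1L)
        if (lo > hi) next
        long_hits[[length(long_hits) + 1L]] <- data.frame(
          read_id = rid, contig_id = ly$steps$contig_id[si],
          q_start = lo - a + 1L, q_end = hi - a + 1L,
          identity = identity, read_length = len,
          stringsAsFactors = FALSE)
      }
    }
  }
  empty_pairs <- data.frame(read_id = character(), mate = integer(),
                            contig_id = character(), start = integer(),
                            end = integer(), strand = character(),
                            identity = numeric(), stringsAsFactors = FALSE)
  empty_hits <- data.frame(read_id = character(), contig_id = character(),
                           q_start = integer(), q_end = integer(),
                           identity = numeric(), read_length = integer(),
                           stringsAsFactors = FALSE)
  list(pairs = if (length(pairs)) do.call(rbind, pairs) else empty_pairs,
       long_hits = if (length(long_hits)) do.call(rbind, long_hits) else
         empty_hits)
}

#' Build the four CRC junction molecules of a repeat pair
#'
#' For every head x tail fork combination, returns the linear molecule
#' left-chain -> repeat -> right-chain with consistent orientations, keyed
#' by canonical CRC string.  These are the molecules spanning reads
#' discriminate.
#'
#' @param graph assembly graph with repeat roles.
#' @param rrp one repeat-pair record.
#' @param chains from [build_contig_chains()].
#' @return named list of step data.frames.
#' @export
crc_molecules <- function(graph, rrp, chains) {
  crcs <- enumerate_crcs(rrp)
  lk <- chain_lookup(chains)
  reverse_steps <- function(mem) {
    data.frame(contig_id = rev(mem$contig_id),
               orientation = flip_orientation(rev(mem$orientation)),
               stringsAsFactors = FALSE)
  }
  ## pick the chain direction in which the branch contig sits at the
  ## junction-facing end with the orientation the CRC dictates; exactly one
  ## of the two directions satisfies both
  orient_chain <- function(chain, branch_contig, want_orientation, at_end) {
    for (f in list(chain$members, reverse_steps(chain$members))) {
      idx <- if (at_end == "last") nrow(f) else 1L
      if (f$contig_id[idx] == branch_contig &&
          f$orientation[idx] == want_orientation) return(f)
    }
    stop("crc_molecules: cannot orient chain toward ", branch_contig)
  }
  out <- list()
  for (i in seq_len(nrow(crcs))) {
    left <- orient_chain(chains[[lk[[crcs$left[i]]]]], crcs$left[i],
                         crcs$left_orientation[i], at_end = "last")
    right <- orient_chain(chains[[lk[[crcs$right[i]]]]], crcs$right[i],
                          crcs$right_orientation[i], at_end = "first")
    steps <- rbind(left,
                   data.frame(contig_id = crcs$repeat_id[i],
                              orientation = "+", stringsAsFactors = FALSE),
                   right)
    out[[crcs$key[i]]] <- steps
  }
  out
}
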