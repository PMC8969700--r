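test_that("walks validate junctions and compute lengths", {
  g <- detect_double_forks(maize_ring_graph())$graph
  master <- make_walk(g, data.frame(
    contig_id = c("c1", "a", "c2", "c8", "a", "c9"),
    orientation = "+", stringsAsFactors = FALSE))
  expect_equal(master$length, 4 * 1000 + 2 * 500 - 6 * 50)
  expect_equal(master$kind, "master_configuration")
  expect_error(make_walk(g, data.frame(contig_id = c("c1", "c2"),
                                       orientation = "+",
                                       stringsAsFactors = FALSE)),
               "no overlap edge")
})

test_that("canonical form is invariant under rotation and reverse complement", {
  steps <- data.frame(contig_id = c("c1", "a", "c2", "c8", "a", "c9"),
                      orientation = c("+", "+", "+", "+", "+", "-"),
                      stringsAsFactors = FALSE)
  k0 <- canonical_walk_key(steps)
  for (r in 1:5) {
    rot <- steps[c((r + 1):6, 1:r), ]
    expect_equal(canonical_walk_key(rot), k0)
  }
  rc <- data.frame(contig_id = rev(steps$contig_id),
                   orientation = ifelse(rev(steps$orientation) == "+",
                                        "-", "+"),
                   stringsAsFactors = FALSE)
  expect_equal(canonical_walk_key(rc), k0)
})

test_that("the worked double-fork example: 4 CRCs, direct recombination swaps flanks", {
  df <- detect_double_forks(maize_ring_graph())
  g <- df$graph
  crcs <- enumerate_crcs(df$rrps[["a"]])
  expect_equal(nrow(crcs), 4L)

  master <- reconstruct_master(g)
  expect_equal(master$kind, "master_configuration")
  subs <- apply_recombination(g, master, "a", mode = "direct")
  expect_length(subs, 2L)
  junctions <- vapply(subs, function(w) {
    p <- which(w$steps$contig_id == "a")
    n <- nrow(w$steps)
    prev <- if (p == 1) n else p - 1
    nxt <- if (p == n) 1 else p + 1
    crc_key(w$steps$contig_id[prev], "a", w$steps$contig_id[nxt])
  }, character(1))
  expect_setequal(junctions, c("c1,a,c9", "c2,a,c8"))
  # conservation of sequence content
  expect_equal(sum(vapply(subs, `[[`, numeric(1), "length")), master$length)
  expect_error(apply_recombination(g, subs[[1]], "a", "direct"),
               "fewer than twice")
})

test_that("inverted recombination flips the inter-mate segment", {
  g <- plant_genome(4, list(repeat_spec(length = 400, mode = "inverted")),
                    seed = 70, total_length = 40000)
  df <- planted_to_graph(g)
  master <- reconstruct_master(df$graph)
  pos <- which(master$steps$contig_id == "r1")
  expect_length(pos, 2L)
  expect_false(master$steps$orientation[pos[1]] ==
                 master$steps$orientation[pos[2]])
  out <- apply_recombination(df$graph, master, "r1", mode = "inverted")
  expect_length(out, 1L)
  expect_equal(out[[1]]$length, master$length)
  inner_before <- master$steps$contig_id[(pos[1] + 1):(pos[2] - 1)]
  pos2 <- which(out[[1]]$steps$contig_id == "r1")
  inner_after <- out[[1]]$steps$contig_id[(pos2[1] + 1):(pos2[2] - 1)]
  expect_equal(inner_after, rev(inner_before))
  expect_error(apply_recombination(df$graph, master, "r1", mode = "direct"),
               "opposite orientations")
})

test_that("enumeration matches the worked ring expectations", {
  # direct-repeat ring: one master and two small sub-circles
  g <- plant_genome(4, list(repeat_spec(length = 400, mode = "direct")),
                    seed = 71, total_length = 40000)
  df <- planted_to_graph(g)
  walks <- enumerate_subgenomes(df$graph)
  kinds <- vapply(walks, `[[`, character(1), "kind")
  expect_equal(sum(kinds == "master_configuration"), 1L)
  expect_equal(sum(kinds == "small_subcircle"), 2L)
  expect_length(walks, 3L)

  # inverted-repeat ring: two master configurations, no sub-circles
  gi <- plant_genome(4, list(repeat_spec(length = 400, mode = "inverted")),
                     seed = 72, total_length = 40000)
  dfi <- planted_to_graph(gi)
  walks_i <- enumerate_subgenomes(dfi$graph)
  kinds_i <- vapply(walks_i, `[[`, character(1), "kind")
  expect_equal(unname(table(factor(kinds_i, levels = WALK_KINDS))[1]), 2L)
  expect_length(walks_i, 2L)
})

test_that("enumeration equals the naive DFS oracle on random graphs", {
  for (seed in 301:320) {
    set.seed(seed)
    m <- sample(0:2, 1)
    n_u <- max(2 * m, 1) + sample(0:2, 1)
    specs <- replicate(m, repeat_spec(
      length = 200, mode = sample(c("direct", "inverted"), 1)),
      simplify = FALSE)
    g <- plant_genome(n_u, specs, seed = seed, total_length = 40000)
    graph <- truth_topology_graph(g)
    walks <- enumerate_subgenomes(graph)
    got <- sort(vapply(walks, function(w) oracle_canonical_key(w$steps),
                       character(1)))
    want <- oracle_closed_walks(graph)
    expect_equal(got, want, info = paste("seed", seed))
  }
})

test_that("every enumerated walk is valid and within budget", {
  g <- plant_genome(4, list(repeat_spec(length = 300),
                            repeat_spec(length = 350)),
                    seed = 73, total_length = 50000)
  df <- planted_to_graph(g)
  walks <- enumerate_subgenomes(df$graph)
  roles <- vapply(df$graph$contigs, `[[`, character(1), "role")
  for (w in walks) {
    expect_s3_class(make_walk(df$graph, w$steps), "mito_walk")
    cnt <- table(w$steps$contig_id)
    for (id in names(cnt)) {
      expect_lte(cnt[[id]], if (roles[[id]] == "repeat") 2L else 1L)
    }
  }
  expect_error(enumerate_subgenomes(df$graph, traversal_rules(max_walks = 2)),
               "max_walks")
})

test_that("master reconstruction escalates budgets when a repeat must be traversed thrice", {
  # three loops hanging off one repeat hub: covering all three unique
  # contigs needs the hub three times, beyond the base repeat budget of two
  contigs <- list(mito_contig("hub", length = 600),
                  mito_contig("x1", length = 2000),
                  mito_contig("x2", length = 2000),
                  mito_contig("x3", length = 2000))
  names(contigs) <- vapply(contigs, `[[`, character(1), "id")
  edges <- do.call(rbind, lapply(c("x1", "x2", "x3"), function(x) data.frame(
    c1 = c("hub", x), s1 = "tail", c2 = c(x, "hub"), s2 = "head",
    overlap_length = 50L, stringsAsFactors = FALSE)))
  g <- detect_double_forks(assembly_graph(contigs,
                                          overlap_edges = edges))$graph
  expect_equal(g$contigs[["hub"]]$role, "repeat")
  master <- reconstruct_master(g)
  expect_equal(attr(master, "over_budget"), "hub")
  expect_equal(sum(master$steps$contig_id == "hub"), 3L)
  expect_setequal(unique(master$steps$contig_id),
                  c("hub", "x1", "x2", "x3"))

  expect_error(reconstruct_master(assembly_graph(list(
    mito_contig("i1", length = 100), mito_contig("i2", length = 100)))),
    "components")
})

test_that("emitted sequences tile junction overlaps exactly once", {
  set.seed(74)
  ov <- 10L
  s1 <- random_dna(200)
  # B carries A's last 10 bp at its head and A's first 10 bp at its tail
  s2 <- paste0(substring(s1, 200 - ov + 1, 200), random_dna(160),
               substring(s1, 1, ov))
  # ring: s1 tail -> s2 head, s2 tail -> s1 head
  contigs <- list(A = mito_contig("A", sequence = s1),
                  B = mito_contig("B", sequence = s2))
  edges <- data.frame(c1 = c("A", "B"), s1 = "tail", c2 = c("B", "A"),
                      s2 = "head", overlap_length = ov,
                      stringsAsFactors = FALSE)
  g <- assembly_graph(contigs, overlap_edges = edges)
  w <- make_walk(g, data.frame(contig_id = c("A", "B"), orientation = "+",
                               stringsAsFactors = FALSE))
  out <- emit_sequence(g, w)
  expect_equal(nchar(out), nchar(s1) + nchar(s2) - 2 * ov)
  expect_equal(nchar(out), w$length)

  # incompatible junction bases are refused
  g$contigs[["B"]]$sequence <- paste0("NNNNNNNNNN",
                                      substring(s2, ov + 1))
  expect_error(emit_sequence(g, w), "incompatible")
})

test_that("master emission reproduces planted genomes up to rotation/RC", {
  for (seed in c(80, 81)) {
    mode <- if (seed %% 2 == 0) "direct" else "inverted"
    g <- plant_genome(4, list(repeat_spec(length = 500, mode = mode)),
                      seed = seed, total_length = 60000)
    df <- planted_to_graph(g)
    master <- reconstruct_master(df$graph)
    expect_equal(master$length, g$truth$master_length)
    # the planted arrangement is one of the (possibly several) masters
    truth_key <- canonical_walk_key(g$truth$master_steps)
    masters <- Filter(function(w) w$kind == "master_configuration",
                      enumerate_subgenomes(df$graph))
    keys <- vapply(masters, function(w) canonical_walk_key(w$steps),
                   character(1))
    expect_true(truth_key %in% keys)
    chosen <- masters[[match(truth_key, keys)]]
    emitted <- emit_sequence(df$graph, chosen)
    expect_true(same_circular_sequence(emitted, g$sequence))
  }
})

test_that("digest prediction conserves length and resolves CRC variants by probe", {
  set.seed(82)
  site <- "AAGCTT"
  clean <- function(n) {
    s <- random_dna(n)
    while (grepl(site, s, fixed = TRUE))
      s <- gsub(site, "AAGCTA", s, fixed = TRUE)
    s
  }
  genome <- paste0(site, clean(3000), site, clean(1500))
  fr <- predict_digest_fragments(genome, site, circular = TRUE)
  expect_equal(nrow(fr), 2L)
  expect_equal(sum(fr$length), nchar(genome))
  expect_equal(nrow(predict_digest_fragments(clean(2000), site)), 1L)

  # four junction variants sharing flanks; a probe on the repeat sees all
  # four fragment lengths, a probe on one unique flank sees two
  L0 <- clean(500); L3 <- clean(2000)
  R12 <- clean(700); R5 <- clean(3800)
  S <- clean(518)
  variants <- list(c0_12 = list(L = L0, R = R12), c0_5 = list(L = L0, R = R5),
                   c3_12 = list(L = L3, R = R12), c3_5 = list(L = L3, R = R5))
  repeat_probe_lengths <- integer()
  flank_probe_lengths <- integer()
  for (v in variants) {
    seq_v <- paste0(clean(400), site, v$L, S, v$R, site, clean(400))
    fr_v <- predict_digest_fragments(seq_v, site, circular = FALSE)
    # probe inside the repeat copy
    p0 <- 400 + 6 + nchar(v$L) + 100
    hit <- probe_detects(fr_v, p0, p0 + 50, nchar(seq_v))
    expect_equal(nrow(hit), 1L)
    repeat_probe_lengths <- c(repeat_probe_lengths, hit$length)
    # probe inside flank L0 detects only the variants carrying L0
    if (identical(v$L, L0)) {
      pf <- 400 + 6 + 20
      hf <- probe_detects(fr_v, pf, pf + 50, nchar(seq_v))
      flank_probe_lengths <- c(flank_probe_lengths, hf$length)
    }
  }
  expect_length(unique(repeat_probe_lengths), 4L)
  expect_length(flank_probe_lengths, 2L)
})
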