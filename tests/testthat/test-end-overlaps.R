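make_pair_with_overlap <- function(L, seed = 1, minus = FALSE,
                                   at = c("tail_head", "head_tail",
                                          "tail_tail", "head_head")) {
  # two 2-kb contigs sharing an exact L-bp end block
  at <- match.arg(at)
  set.seed(seed)
  a <- random_dna(2000)
  b <- random_dna(2000)
  block <- random_dna(L)
  if (at == "tail_head") {
    a <- paste0(substring(a, 1, 2000 - L), block)
    b <- paste0(if (minus) revcomp(block) else block, substring(b, L + 1))
  } else if (at == "tail_tail") {
    a <- paste0(substring(a, 1, 2000 - L), block)
    b <- paste0(substring(b, 1, 2000 - L),
                if (minus) revcomp(block) else block)
  } else if (at == "head_head") {
    a <- paste0(block, substring(a, L + 1))
    b <- paste0(if (minus) revcomp(block) else block, substring(b, L + 1))
  } else {
    a <- paste0(block, substring(a, L + 1))
    b <- paste0(substring(b, 1, 2000 - L),
                if (minus) revcomp(block) else block)
  }
  list(A = mito_contig("A", sequence = a, mean_coverage = 5000),
       B = mito_contig("B", sequence = b, mean_coverage = 5000))
}

test_that("exact end overlaps are found at the threshold and not below", {
  cp <- make_pair_with_overlap(89, seed = 11)
  hits <- detect_end_overlaps(cp)
  expect_true(nrow(hits) >= 2)  # symmetric A->B and B->A
  expect_true(all(hits$aln_length == 89))

  cp48 <- make_pair_with_overlap(48, seed = 12)
  expect_equal(nrow(detect_end_overlaps(cp48)), 0L)

  cp49 <- make_pair_with_overlap(49, seed = 13)
  expect_true(nrow(detect_end_overlaps(cp49)) >= 2)
})

test_that("interior shared blocks are not end-to-end hits", {
  set.seed(14)
  block <- random_dna(100)
  a <- paste0(random_dna(800), block, random_dna(800))
  b <- paste0(random_dna(700), block, random_dna(900))
  contigs <- list(A = mito_contig("A", sequence = a),
                  B = mito_contig("B", sequence = b))
  expect_equal(nrow(detect_end_overlaps(contigs)), 0L)
})

test_that("missing sequences are reported by contig id", {
  expect_error(detect_end_overlaps(list(X = mito_contig("X", length = 10))),
               "X")
})

test_that("the strand rule maps hits onto the correct termini", {
  cases <- list(
    list(at = "tail_head", minus = FALSE, s1 = "tail", s2 = "head"),
    list(at = "head_tail", minus = FALSE, s1 = "head", s2 = "tail"),
    list(at = "tail_tail", minus = TRUE, s1 = "tail", s2 = "tail"),
    list(at = "head_head", minus = TRUE, s1 = "head", s2 = "head"))
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    cp <- make_pair_with_overlap(120, seed = 20 + i, minus = cs$minus,
                                 at = cs$at)
    flt <- filter_end_to_end(detect_end_overlaps(cp), cp)
    adj <- flt$adjacency
    expect_equal(nrow(adj), 1L, info = cs$at)
    got <- adj[1, ]
    want <- orient_edge_endpoints("A", cs$s1, "B", cs$s2)
    expect_equal(got$c1, want$c1, info = cs$at)
    expect_equal(got$s1, want$s1, info = cs$at)
    expect_equal(got$c2, want$c2, info = cs$at)
    expect_equal(got$s2, want$s2, info = cs$at)
  }
})

test_that("the 49-bp overlap floor is applied at filtering too", {
  cp <- make_pair_with_overlap(60, seed = 30)
  hits <- detect_end_overlaps(cp)
  short <- hits; short$aln_length <- 48L
  expect_equal(nrow(filter_end_to_end(short, cp)$adjacency), 0L)
  atfloor <- hits; atfloor$aln_length <- 49L
  expect_equal(nrow(filter_end_to_end(atfloor, cp)$adjacency), 1L)
})

test_that("containments are set aside, not turned into adjacency", {
  set.seed(31)
  inner <- random_dna(400)
  outer <- paste0(random_dna(500), inner, random_dna(500))
  contigs <- list(inner = mito_contig("inner", sequence = inner),
                  outer = mito_contig("outer", sequence = outer))
  hits <- data.frame(query_id = "inner", subject_id = "outer",
                     identity = 100, aln_length = 400L,
                     q_start = 1L, q_end = 400L, s_start = 501L,
                     s_end = 900L, evalue = 0, stringsAsFactors = FALSE)
  flt <- filter_end_to_end(hits, contigs)
  expect_equal(nrow(flt$adjacency), 0L)
  expect_equal(flt$contained$contig_id, "inner")
  expect_equal(flt$contained$container_id, "outer")
})

test_that("high-confidence calls use strict length and coverage bounds", {
  contigs <- list(
    a = mito_contig("a", length = 1500, mean_coverage = 5000),
    b = mito_contig("b", length = 1000, mean_coverage = 5000),
    c = mito_contig("c", length = 1500, mean_coverage = 3000),
    d = mito_contig("d", length = 1001, mean_coverage = 3001))
  expect_setequal(select_hccs(contigs), c("a", "d"))
  expect_error(select_hccs(list(x = mito_contig("x", length = 2000))),
               "coverage")
  # consensus mode needs the recovery vector
  expect_error(select_hccs(contigs, hcc_criteria(mode = "consensus")),
               "consensus")
  found <- c(a = TRUE, b = FALSE, c = TRUE, d = FALSE)
  expect_setequal(
    select_hccs(contigs, hcc_criteria(mode = "consensus"),
                consensus_found = found), c("a", "c"))
})

test_that("coverage tiers separate organellar from nuclear contigs", {
  g <- plant_genome(4, list(repeat_spec(length = 300)), seed = 5,
                    total_length = 40000)
  contigs <- fragment_to_contigs(g, n_nuclear = 3)
  hccs <- select_hccs(contigs)
  expect_true(all(startsWith(hccs, "u")))
  expect_false(any(startsWith(hccs, "nc")))
})

test_that("graph construction is seeded at HCCs and integrates bridges only", {
  g <- plant_genome(4, list(repeat_spec(length = 300)), seed = 6,
                    total_length = 40000)
  contigs <- fragment_to_contigs(g, n_nuclear = 2)
  flt <- filter_end_to_end(detect_end_overlaps(contigs), contigs)
  hccs <- select_hccs(contigs)
  gr <- build_graph(contigs, flt$adjacency, hccs)
  # repeat contig is low-confidence (short) but bridges HCCs: integrated
  expect_true("r1" %in% names(gr$contigs))
  expect_false("r1" %in% hccs)
  # unconnected decoys are excluded
  expect_false(any(startsWith(names(gr$contigs), "nc")))
  expect_error(build_graph(contigs, flt$adjacency, character(0)),
               "entry points")
})

test_that("enlarging the HCC set never removes contigs from the graph", {
  g <- plant_genome(4, list(repeat_spec(length = 300)), seed = 8,
                    total_length = 40000)
  contigs <- fragment_to_contigs(g, n_nuclear = 1)
  flt <- filter_end_to_end(detect_end_overlaps(contigs), contigs)
  small <- select_hccs(contigs)[1]
  big <- c(select_hccs(contigs), "nc01")
  g_small <- build_graph(contigs, flt$adjacency, small)
  g_big <- build_graph(contigs, flt$adjacency, big)
  expect_true(all(names(g_small$contigs) %in% names(g_big$contigs)))
})

test_that("construction round-trips the planted topology, also reverse-complemented", {
  for (seed in c(101, 102, 103)) {
    g <- plant_genome(4, list(repeat_spec(length = 400, mode = "direct")),
                      seed = seed, total_length = 45000)
    df <- planted_to_graph(g)
    expect_setequal(names(df$graph$contigs), g$truth$contig_ids)
    expect_setequal(names(df$rrps), g$truth$rrp_ids)
    # graph isomorphic to truth: same edge multiset on terminus keys
    truth_g <- assembly_graph(
      lapply(df$graph$contigs, function(ct) ct),
      overlap_edges = g$truth$edges)
    edge_key <- function(gr) {
      oe <- gr$edges[gr$edges$kind == "overlap", ]
      sort(paste(oe$c1, oe$s1, oe$c2, oe$s2))
    }
    expect_equal(edge_key(df$graph), edge_key(truth_g))

    # reverse-complementing every contig must give an isomorphic graph
    rc_contigs <- lapply(fragment_to_contigs(g), function(ct) {
      ct$sequence <- revcomp(ct$sequence); ct
    })
    flt <- filter_end_to_end(detect_end_overlaps(rc_contigs), rc_contigs)
    gr_rc <- build_graph(rc_contigs, flt$adjacency, select_hccs(rc_contigs))
    st1 <- graph_stats(df$graph); st2 <- graph_stats(gr_rc)
    expect_equal(st1$n_vertices, st2$n_vertices)
    expect_equal(sum(gr_rc$edges$kind == "overlap"),
                 sum(df$graph$edges$kind == "overlap"))
    df_rc <- detect_double_forks(gr_rc)
    expect_setequal(names(df_rc$rrps), names(df$rrps))
  }
})
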