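test_that("contig chains end at repeat pairs and cover every unique contig", {
  # ring with 2 RRPs and 4 unique contigs: every chain is one contig,
  # bounded by repeats on both sides and flagged (repeat follows at once)
  g <- plant_genome(4, list(repeat_spec(length = 300),
                            repeat_spec(length = 400)),
                    seed = 50, total_length = 50000)
  df <- planted_to_graph(g)
  chains <- build_contig_chains(df$graph)
  expect_length(chains, 4L)
  for (ch in chains) {
    expect_equal(nrow(ch$members), 1L)
    expect_true(ch$flagged)
    expect_true(all(ch$bounded_by %in% c("r1", "r2")))
  }
  covered <- unlist(lapply(chains, function(ch) ch$members$contig_id))
  expect_setequal(covered, paste0("u0", 1:4))

  # multi-contig chains: 1 RRP, 4 unique contigs -> 2 chains of 2
  g2 <- plant_genome(4, list(repeat_spec(length = 300)), seed = 51,
                     total_length = 50000)
  df2 <- planted_to_graph(g2)
  chains2 <- build_contig_chains(df2$graph)
  expect_length(chains2, 2L)
  expect_true(all(vapply(chains2, function(ch) nrow(ch$members),
                         integer(1)) == 2L))
  expect_false(any(vapply(chains2, `[[`, logical(1), "flagged")))

  # no repeats: one circular chain spanning the component
  g3 <- plant_genome(3, list(), seed = 52, total_length = 30000)
  df3 <- planted_to_graph(g3)
  chains3 <- build_contig_chains(df3$graph)
  expect_length(chains3, 1L)
  expect_true(chains3[[1]]$circular)
  expect_equal(nrow(chains3[[1]]$members), 3L)
})

test_that("mate pairs on one contig are discarded; spanning pairs count once", {
  g <- plant_genome(4, list(repeat_spec(length = 300)), seed = 53,
                    total_length = 50000)
  df <- planted_to_graph(g)
  chains <- build_contig_chains(df$graph)
  placements <- data.frame(
    read_id = c("p1", "p1", "p2", "p2"),
    mate = c(1, 2, 1, 2),
    contig_id = c("u01", "u01", "u01", "u01"),
    start = c(100, 300, 100, 300), end = c(249, 449, 249, 449),
    strand = "+", identity = 100, stringsAsFactors = FALSE)
  cnt <- count_matepair_support(placements, chains, df$rrps, df$graph)
  expect_equal(sum(cnt$r1), 0L)
})

test_that("mate-pair and long-read pipelines recover planted shares and agree", {
  g <- plant_genome(4, list(repeat_spec(length = 400, mode = "direct")),
                    seed = 54, total_length = 60000)
  df <- planted_to_graph(g)
  chains <- build_contig_chains(df$graph)
  mols <- crc_molecules(df$graph, df$rrps[[1]], chains)
  shares <- c(0.47, 0.47, 0.03, 0.03)
  sim <- simulate_spanning_reads(df$graph, mols, shares,
                                 n_pairs = 6000, n_long = 1500, seed = 55)
  cnt <- count_matepair_support(sim$pairs, chains, df$rrps, df$graph)$r1
  expect_true(sum(cnt) > 200)
  est_mp <- cnt / sum(cnt)
  sd_mp <- sqrt(shares * (1 - shares) / sum(cnt))
  expect_true(all(abs(est_mp - shares) <= 3 * sd_mp + 1e-9))

  ccs <- chain_and_filter_ccs(sim$long_hits)
  lcnt <- count_longread_support(ccs, enumerate_crcs(df$rrps[[1]]))
  est_lr <- lcnt / sum(lcnt)
  sd_lr <- sqrt(shares * (1 - shares) / sum(lcnt))
  expect_true(all(abs(est_lr - shares) <= 3 * sd_lr + 1e-9))
  # the two estimators agree with each other
  expect_true(all(abs(est_mp - est_lr) < 0.08))

  s <- summarize_stoichiometry(list(r1 = cnt))
  expect_equal(s$rows$group, "dominant")
})

test_that("long-read chaining collapses duplicates and applies retention filters", {
  base <- data.frame(read_id = "ccs1",
                     contig_id = c("u01", "u01", "r1", "u02"),
                     q_start = c(1, 2000, 5100, 5400),
                     q_end = c(2050, 5200, 5500, 8000),
                     identity = 99, read_length = 8000,
                     stringsAsFactors = FALSE)
  res <- chain_and_filter_ccs(base)
  expect_equal(res$chain, "u01,r1,u02")   # neighbours collapsed
  expect_true(res$kept)

  low_id <- base; low_id$identity <- 94
  expect_false(chain_and_filter_ccs(low_id)$kept)
  expect_equal(chain_and_filter_ccs(low_id)$reason, "low_identity")

  short <- base
  short$read_length <- 4000
  short$q_start <- pmin(short$q_start, 4000); short$q_end <- pmin(short$q_end, 4000)
  expect_false(chain_and_filter_ccs(short)$kept)

  partial <- base; partial$q_end[4] <- 6000   # only 6000/8000 aligned
  res_p <- chain_and_filter_ccs(partial)
  expect_false(res_p$kept)
  expect_equal(res_p$reason, "partial_alignment_nuclear_like")

  # the hit-length floor drops sub-threshold fragments before chaining
  with_noise <- rbind(base, data.frame(
    read_id = "ccs1", contig_id = "u09", q_start = 3000, q_end = 3080,
    identity = 99, read_length = 8000, stringsAsFactors = FALSE))
  expect_false(grepl("u09", chain_and_filter_ccs(with_noise)$chain))
})

test_that("chain support is contiguous-subsequence matching in either direction", {
  crcs <- data.frame(left = "u1", repeat_id = "r", right = "u2",
                     left_orientation = "+", repeat_orientation = "+",
                     right_orientation = "+",
                     key = "u1,r,u2", stringsAsFactors = FALSE)
  mk <- function(chain) data.frame(read_id = "x", chain = chain, n_hits = 3,
                                   covered_fraction = 1, mean_identity = 100,
                                   read_length = 9000, kept = TRUE,
                                   reason = "", stringsAsFactors = FALSE)
  expect_equal(unname(count_longread_support(mk("u1,r,u2"), crcs)), 1L)
  expect_equal(unname(count_longread_support(mk("u2,r,u1"), crcs)), 1L)
  expect_equal(unname(count_longread_support(mk("u1,r,u9"), crcs)), 0L)
  expect_equal(unname(count_longread_support(mk("u0,u1,r,u2,u3"), crcs)), 1L)
})

test_that("the printed junction-count table reproduces exactly", {
  path <- system.file("extdata", "oelata_crc_counts.tsv",
                      package = "mitograph")
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  expected <- list(
    illumina = list(divisor = 21865,
                    usage = c(1.5, 2.8, 2.7, 2.8, 2.2),
                    read_sums = c(31715, 61460, 58028, 60890, 48376),
                    shares = c(1, 49, 47, 3, 5, 45, 48, 1, 1, 50, 45, 4,
                               47, 1, 1, 51, 2, 50, 48, 1)),
    pacbio = list(divisor = 665,
                  usage = c(2.2, 2.8, 2.8, 2.7, 1.7),
                  read_sums = c(1468, 1894, 1857, 1828, 1130),
                  shares = c(4, 39, 50, 6, 1, 47, 52, 0, 0, 52, 48, 0,
                             52, 0, 0, 48, 0, 52, 48, 0)))
  for (ds in names(expected)) {
    sub <- tab[tab$dataset == ds, ]
    counts <- lapply(seq_len(nrow(sub)), function(i)
      setNames(as.integer(sub[i, paste0("conf", 1:4)]), paste0("conf", 1:4)))
    names(counts) <- sub$rrp_id
    s <- summarize_stoichiometry(counts, divisor = expected[[ds]]$divisor)
    expect_equal(s$rows$usage_factor, expected[[ds]]$usage)
    expect_equal(s$rows$read_sum, expected[[ds]]$read_sums)
    expect_equal(s$crc$share, expected[[ds]]$shares)
    expect_true(all(s$rows$group == "dominant"))
  }
})

test_that("summary invariants: share sums, equal counts, zero rows", {
  s <- summarize_stoichiometry(list(r = c(a = 10, b = 10, c = 10, d = 10)))
  expect_equal(s$crc$share, rep(25, 4))
  expect_equal(s$rows$group, "balanced")
  expect_equal(s$rows$usage_factor, 1)

  set.seed(60)
  for (i in 1:10) {
    ct <- setNames(sample(0:5000, 4), letters[1:4])
    if (sum(ct) == 0) next
    s2 <- summarize_stoichiometry(list(r = ct))
    expect_true(sum(s2$crc$share) >= 98 && sum(s2$crc$share) <= 102)
    expect_equal(sum(s2$crc$count), s2$rows$read_sum)
  }

  s0 <- summarize_stoichiometry(list(r = c(a = 0, b = 0, c = 0, d = 0),
                                     q = c(a = 5, b = 5, c = 5, d = 5)))
  expect_true(s0$rows$flagged[s0$rows$rrp_id == "r"])
  expect_true(all(is.na(s0$crc$share[s0$crc$rrp_id == "r"])))
})
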