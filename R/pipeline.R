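## End-to-end pipeline: contigs -> terminus graph -> curation -> repeat
## pairs -> stoichiometry (when reads are given) -> master circle and
## sub-genome enumeration.

#' Pipeline configuration
#'
#' Unknown keys are rejected; every threshold defaults to the method's
#' standard value (49 bp minimum overlap, 300 bp end window, HCC bar 1 kb /
#' 3000x, long-read filters 95 percent / 5 kb, repeat budget 2).
#'
#' @param overlap an [overlap_params()].
#' @param hcc an [hcc_criteria()].
#' @param k_max largest assembly k-mer (bp), used by pruning (default 90).
#' @param cov_floor absolute low-coverage floor or NULL (10 percent of the
#'   median graph coverage).
#' @param min_plastid_fraction plastid-call threshold (default 0.8).
#' @param rules a [traversal_rules()].
#' @param divisor usage-factor divisor override or NULL.
#' @param collapse_chains collapse unambiguous chains before repeat
#'   detection (default FALSE; keeps raw contig identities for
#'   stoichiometry).
#' @param seed RNG seed recorded in the run log.
#' @param out_prefix when set, artifacts are written under this path prefix.
#' @export
pipeline_config <- function(overlap = overlap_params(), hcc = hcc_criteria(),
                            k_max = 90L, cov_floor = NULL,
                            min_plastid_fraction = 0.8,
                            rules = traversal_rules(), divisor = NULL,
                            collapse_chains = FALSE, seed = 1L,
                            out_prefix = NULL) {
  structure(list(overlap = overlap, hcc = hcc, k_max = as.integer(k_max),
                 cov_floor = cov_floor,
                 min_plastid_fraction = min_plastid_fraction,
                 rules = rules, divisor = divisor,
                 collapse_chains = isTRUE(collapse_chains),
                 seed = as.integer(seed), out_prefix = out_prefix),
            class = "pipeline_config")
}

#' Run the full assembly-to-configurations pipeline
#'
#' Stages: end-overlap detection (or externally supplied hits) ->
#' end-to-end filtering -> HCC selection -> seeded graph construction ->
#' curation (plastid removal, pruning, optional scripted actions) ->
#' double-fork detection -> contig chains -> stoichiometry (when placements
#' or long-read hits are given) -> master reconstruction -> sub-genome
#' enumeration.  Stage failures abort with the stage name; artifacts
#' produced so far are retained in the error's `partial` attribute.
#'
#' @param contigs named list of [mito_contig()] (sequences required unless
#'   `hits` are supplied).
#' @param config a [pipeline_config()].
#' @param hits optional precomputed alignment hit table.
#' @param plastid_hits optional plastid-reference hit table.
#' @param curation_actions optional list of [curation_action()].
#' @param pair_placements optional mate-pair placement table.
#' @param long_hits optional long-read hit table.
#' @return list of artifacts: graph, curated graph, rrps, chains,
#'   stoichiometry, master walk, enumeration, summary, log.
#' @export
run_pipeline <- function(contigs, config = pipeline_config(), hits = NULL,
                         plastid_hits = NULL, curation_actions = NULL,
                         pair_placements = NULL, long_hits = NULL) {
  art <- list(config = config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      err <- simpleError(paste0("pipeline stage '", name, "' failed: ",
                                conditionMessage(e)))
      attr(err, "partial") <- art
      stop(err)
    })
  }
  log <- list(seed = config$seed,
              params = list(min_overlap = config$overlap$min_overlap,
                            end_window = config$overlap$end_window,
                            hcc_min_length = config$hcc$min_length,
                            hcc_min_coverage = config$hcc$min_coverage))

  if (is.null(hits))
    hits <- stage("detect_end_overlaps",
                  detect_end_overlaps(contigs, config$overlap))
  art$hits <- hits
  flt <- stage("filter_end_to_end",
               filter_end_to_end(hits, contigs, config$overlap))
  art$adjacency <- flt$adjacency
  art$contained <- flt$contained
  hccs <- stage("select_hccs", select_hccs(contigs, config$hcc))
  art$hccs <- hccs
  graph <- stage("build_graph", build_graph(contigs, flt$adjacency, hccs))
  art$graph <- graph

  cur_log <- curation_log_df()
  if (!is.null(plastid_hits)) {
    res <- stage("remove_plastid_subgraph",
                 remove_plastid_subgraph(graph, plastid_hits,
                                         config$min_plastid_fraction))
    graph <- res$graph
    cur_log <- rbind(cur_log, res$log)
  }
  res <- stage("prune_small_lowcov",
               prune_small_lowcov(graph, flt$contained, config$k_max,
                                  config$cov_floor))
  graph <- res$graph
  cur_log <- rbind(cur_log, res$log)
  if (!is.null(curation_actions)) {
    res <- stage("apply_curation_script",
                 apply_curation_script(graph, curation_actions))
    graph <- res$graph
    cur_log <- rbind(cur_log, res$log)
  }
  if (config$collapse_chains)
    graph <- stage("simplify_graph", simplify_graph(graph))
  art$curation_log <- cur_log

  df <- stage("detect_double_forks", detect_double_forks(graph))
  graph <- df$graph
  art$curated_graph <- graph
  art$rrps <- df$rrps
  art$single_forks <- df$single_forks
  chains <- stage("build_contig_chains", build_contig_chains(graph))
  art$chains <- chains

  if ((!is.null(pair_placements) || !is.null(long_hits)) &&
      length(df$rrps)) {
    counts <- list()
    if (!is.null(pair_placements))
      counts$matepair <- stage("count_matepair_support",
                               count_matepair_support(pair_placements,
                                                      chains, df$rrps,
                                                      graph))
    if (!is.null(long_hits)) {
      ccs <- stage("chain_and_filter_ccs", chain_and_filter_ccs(long_hits))
      art$ccs_chains <- ccs
      counts$longread <- lapply(df$rrps, function(r)
        count_longread_support(ccs, enumerate_crcs(r)))
    }
    art$stoichiometry <- lapply(counts, summarize_stoichiometry,
                                divisor = config$divisor)
  } else {
    art$stoichiometry <- NULL
    log$stoichiometry <- "skipped (no read placements given)"
  }

  art$master <- stage("reconstruct_master",
                      reconstruct_master(graph, config$rules))
  art$enumeration <- stage("enumerate_subgenomes",
                           enumerate_subgenomes(graph, config$rules))
  kinds <- vapply(art$enumeration, `[[`, character(1), "kind")
  art$summary <- list(
    n_contigs = length(graph$contigs),
    n_rrps = length(df$rrps),
    n_single_forks = length(df$single_forks),
    n_chains = length(chains),
    master_length = art$master$length,
    n_walks = length(art$enumeration),
    n_by_kind = table(factor(kinds, levels = WALK_KINDS)))
  art$log <- log

  if (!is.null(config$out_prefix)) {
    p <- config$out_prefix
    write_graph_json(graph, paste0(p, ".graph.json"))
    write_gfa(graph, paste0(p, ".gfa"),
              walks = list(master = art$master))
    if (length(df$rrps)) {
      write.table(rrp_table(df$rrps), paste0(p, ".rrps.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    if (!is.null(art$stoichiometry)) {
      for (ds in names(art$stoichiometry))
        write_stoich_report(art$stoichiometry[[ds]],
                            paste0(p, ".stoich.", ds, ".tsv"))
    }
    if (!is.null(graph$contigs[[art$master$steps$contig_id[1]]]$sequence)) {
      write_fasta(setNames(emit_sequence(graph, art$master), "master"),
                  paste0(p, ".master.fasta"))
    }
    walk_tab <- do.call(rbind, lapply(seq_along(art$enumeration),
                                      function(i) {
      w <- art$enumeration[[i]]
      data.frame(walk = i, kind = w$kind, length = w$length,
                 path = paste0(w$steps$contig_id, w$steps$orientation,
                               collapse = ","),
                 stringsAsFactors = FALSE)
    }))
    write.table(walk_tab, paste0(p, ".walks.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(art$summary, paste0(p, ".summary.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  art
}
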