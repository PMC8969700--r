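## Readers and writers: graph JSON, GFA v1, 12-column tabular alignment
## hits, placement TSV, curation scripts and the stoichiometry report.
## Every format round-trips loss-free; malformed lines are reported with
## line numbers.

#' Write an assembly graph to JSON
#'
#' Schema: `{"format": "mitograph-graph", "version": 1, "contigs": [...],
#' "edges": [...]}`; termini are implicit (head/tail per contig).
#'
#' @param graph an assembly graph.
#' @param path output path.
#' @export
write_graph_json <- function(graph, path) {
  contigs <- lapply(graph$contigs, function(ct) {
    out <- list(id = ct$id, length = ct$length,
                mean_coverage = ct$mean_coverage, origin = ct$origin,
                is_hcc = ct$is_hcc, role = ct$role)
    if (!is.null(ct$sequence)) out$sequence <- ct$sequence
    if (!is.null(ct$members)) out$members <- ct$members
    out
  })
  oe <- overlap_edges_of(graph)
  obj <- list(format = "mitograph-graph", version = 1L,
              contigs = unname(contigs),
              edges = oe[, c("c1", "s1", "c2", "s2", "overlap_length")])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read an assembly graph from JSON
#'
#' @param path a file written by [write_graph_json()].
#' @return an `assembly_graph`.
#' @export
read_graph_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "mitograph-graph"))
    stop("read_graph_json: ", path, " is not a mitograph graph file")
  contigs <- list()
  for (c0 in obj$contigs) {
    members <- NULL
    if (!is.null(c0$members)) {
      members <- data.frame(
        contig_id = vapply(c0$members, `[[`, character(1), "contig_id"),
        orientation = vapply(c0$members, `[[`, character(1), "orientation"),
        stringsAsFactors = FALSE)
    }
    contigs[[c0$id]] <- mito_contig(
      id = c0$id, length = c0$length, sequence = c0$sequence,
      mean_coverage = if (is.null(c0$mean_coverage)) NA_real_ else
        c0$mean_coverage,
      origin = c0$origin, is_hcc = isTRUE(c0$is_hcc), role = c0$role,
      members = members)
  }
  edges <- NULL
  if (length(obj$edges)) {
    edges <- data.frame(
      c1 = vapply(obj$edges, `[[`, character(1), "c1"),
      s1 = vapply(obj$edges, `[[`, character(1), "s1"),
      c2 = vapply(obj$edges, `[[`, character(1), "c2"),
      s2 = vapply(obj$edges, `[[`, character(1), "s2"),
      overlap_length = vapply(obj$edges, function(e)
        as.integer(e$overlap_length), integer(1)),
      stringsAsFactors = FALSE)
  }
  assembly_graph(contigs, overlap_edges = edges)
}

#' Export an assembly graph (and walks) as GFA v1
#'
#' One S-line per contig, one L-line per overlap edge (CIGAR `<ov>M`), and
#' optionally one P-line per walk.
#'
#' @param graph an assembly graph.
#' @param path output path.
#' @param walks optional named list of `mito_walk` objects.
#' @export
write_gfa <- function(graph, path, walks = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("H\tVN:Z:1.0", con)
  for (ct in graph$contigs) {
    writeLines(paste("S", ct$id, ct$sequence %||% "*",
                     paste0("LN:i:", ct$length), sep = "\t"), con)
  }
  oe <- overlap_edges_of(graph)
  for (i in seq_len(nrow(oe))) {
    d1 <- if (oe$s1[i] == "tail") "+" else "-"
    d2 <- if (oe$s2[i] == "head") "+" else "-"
    writeLines(paste("L", oe$c1[i], d1, oe$c2[i], d2,
                     paste0(oe$overlap_length[i], "M"), sep = "\t"), con)
  }
  for (nm in names(walks)) {
    w <- walks[[nm]]
    writeLines(paste("P", nm,
                     paste0(w$steps$contig_id, w$steps$orientation,
                            collapse = ","),
                     paste0(w$junction_overlaps, "M", collapse = ","),
                     sep = "\t"), con)
  }
  invisible(path)
}

BLAST12_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                  "gapopen", "qstart", "qend", "sstart", "send", "evalue",
                  "bitscore")

#' Read 12-column tabular alignment hits
#'
#' The standard tabular dialect (qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore); `sstart > send`
#' encodes a minus-strand hit.  A different column order can be supplied.
#'
#' @param path TSV file.
#' @param columns column names in file order (default the 12-column
#'   dialect; must include the 8 fields used).
#' @return data.frame of overlap hits as used by [filter_end_to_end()].
#' @export
read_blast_tab <- function(path, columns = BLAST12_COLS) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(overlap_hit_df())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != length(columns))
  if (length(bad))
    stop("read_blast_tab: ", path, ": lines ",
         paste(head(bad, 5), collapse = ", "),
         " do not have ", length(columns), " tab-separated fields ",
         "(column mapping tried: ", paste(columns, collapse = " "), ")")
  m <- do.call(rbind, parts)
  colnames(m) <- columns
  need <- c("qseqid", "sseqid", "pident", "length", "qstart", "qend",
            "sstart", "send", "evalue")
  missing <- setdiff(need, columns)
  if (length(missing))
    stop("read_blast_tab: column mapping lacks: ",
         paste(missing, collapse = ", "))
  data.frame(query_id = m[, "qseqid"], subject_id = m[, "sseqid"],
             identity = as.numeric(m[, "pident"]),
             aln_length = as.integer(m[, "length"]),
             q_start = as.integer(m[, "qstart"]),
             q_end = as.integer(m[, "qend"]),
             s_start = as.integer(m[, "sstart"]),
             s_end = as.integer(m[, "send"]),
             evalue = as.numeric(m[, "evalue"]),
             stringsAsFactors = FALSE)
}

#' Write / read read-placement tables
#'
#' Columns: read_id, mate (1/2, or 0 for unpaired long reads), contig_id,
#' start, end, strand, identity.  This is the documented SAM-to-TSV
#' contract: primary alignments only, one row per mate.
#'
#' @param placements data.frame.
#' @param path TSV path.
#' @export
write_placements <- function(placements, path) {
  write.table(placements, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_placements
#' @export
read_placements <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  for (col in intersect(c("read_id", "contig_id", "strand"), names(df)))
    df[[col]] <- as.character(df[[col]])
  need <- c("read_id", "mate", "contig_id", "start", "end", "strand",
            "identity")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("read_placements: ", path, " lacks columns: ",
         paste(missing, collapse = ", "))
  df
}

#' Write / read curation scripts
#'
#' One action per row: kind, target, reason, evidence (tab-separated).
#'
#' @param actions list of [curation_action()].
#' @param path TSV path.
#' @export
write_curation_script <- function(actions, path) {
  df <- do.call(rbind, lapply(actions, function(a) data.frame(
    kind = a$kind, target = a$target, reason = a$reason %||% "",
    evidence = a$evidence %||% "", stringsAsFactors = FALSE)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curation_script
#' @export
read_curation_script <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   colClasses = "character", fill = FALSE)
  lapply(seq_len(nrow(df)), function(i)
    curation_action(df$kind[i], df$target[i], df$reason[i] %||% "",
                    df$evidence[i] %||% ""))
}

#' Write the stoichiometry report
#'
#' A TSV with one row per repeat pair: per-variant counts and integer
#' shares, the read sum, the usage factor and the dominance group.
#'
#' @param summary result of [summarize_stoichiometry()].
#' @param path TSV path.
#' @export
write_stoich_report <- function(summary, path) {
  rows <- list()
  for (rid in summary$rows$rrp_id) {
    cc <- summary$crc[summary$crc$rrp_id == rid, ]
    r <- summary$rows[summary$rows$rrp_id == rid, ]
    rows[[rid]] <- data.frame(
      rrp_id = rid,
      t(setNames(cc$count, paste0("count_", seq_len(nrow(cc))))),
      t(setNames(cc$share, paste0("share_", seq_len(nrow(cc))))),
      read_sum = r$read_sum, usage_factor = r$usage_factor,
      group = r$group, crc_keys = paste(cc$crc_key, collapse = ";"),
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
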