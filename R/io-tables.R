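# Tabular readers/writers: expression matrices, miRNA target maps,
# methylation call sets, DMR intervals, window statistics, and network
# export. All TSVs are tab-delimited with a header row; "NA" marks missing.

#' Construct an expression matrix
#'
#' Features x samples abundance matrix (FPKM or TPM; the unit is recorded as
#' metadata, not interpreted) with a group (ecotype) label per sample.
#'
#' @param values numeric matrix, rownames = feature ids, colnames = sample
#'   ids, all entries non-negative.
#' @param groups named character vector mapping every sample id to a group.
#' @param unit free-text unit tag (e.g. "FPKM", "TPM").
#' @return Matrix of class `expr_matrix` with `groups` and `unit`
#'   attributes.
#' @export
expression_matrix <- function(values, groups, unit = NA_character_) {
  .assert(is.matrix(values) && is.numeric(values), "values must be a numeric matrix")
  .assert(!is.null(rownames(values)) && !anyDuplicated(rownames(values)),
          "feature ids must be unique rownames")
  .assert(!is.null(colnames(values)) && !anyDuplicated(colnames(values)),
          "sample ids must be unique colnames")
  .assert(all(is.finite(values)) && all(values >= 0),
          "expression values must be non-negative and finite")
  missing <- setdiff(colnames(values), names(groups))
  .assert(length(missing) == 0L, "sample(s) without group label: %s",
          paste(missing, collapse = ", "))
  structure(values, groups = groups[colnames(values)], unit = unit,
            class = c("expr_matrix", class(values)))
}

expr_groups <- function(expr) attr(expr, "groups")

#' Read an expression TSV
#'
#' First column feature id, remaining columns one per sample. Duplicate
#' feature ids and negative values are errors.
#'
#' @param path TSV file.
#' @param group_map named character vector, sample id -> group name.
#' @param unit unit tag stored on the result.
#' @return An [expression_matrix].
#' @export
read_expression_tsv <- function(path, group_map, unit = NA_character_) {
  df <- read_tsv_plain(path)
  .assert(ncol(df) >= 2L, "expression table needs a feature column and samples")
  ids <- as.character(df[[1]])
  .assert(!anyDuplicated(ids), "duplicate feature id(s): %s",
          paste(utils::head(unique(ids[duplicated(ids)])), collapse = ", "))
  vals <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  .assert(!anyNA(vals), "non-numeric or missing expression value")
  .assert(all(vals >= 0), "negative expression value")
  rownames(vals) <- ids
  expression_matrix(vals, groups = group_map, unit = unit)
}

#' Write an expression matrix as TSV
#' @param expr an [expression_matrix] (or plain matrix).
#' @param path output file.
#' @param id_col name of the feature-id column.
#' @export
write_expression_tsv <- function(expr, path, id_col = "feature_id") {
  df <- data.frame(rownames(expr), as.data.frame(unclass(expr)[, , drop = FALSE]),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write_tsv_commented(df, path)
}

TARGET_CLASSES <- c("mRNA", "lncRNA", "circRNA")

#' Read a miRNA target table
#'
#' TSV with columns `miRNA_id`, `target_id`, `target_class`. Duplicate rows
#' collapse to set semantics; an unknown target class is an error.
#'
#' @param path TSV file.
#' @return A `target_map` data.frame (one row per unique miRNA-target pair).
#' @export
read_target_table <- function(path) {
  df <- read_tsv_plain(path)
  req <- c("miRNA_id", "target_id", "target_class")
  .assert(all(req %in% names(df)), "target table needs columns %s",
          paste(req, collapse = ", "))
  target_map(df[req])
}

#' Construct a target map
#'
#' @param df data.frame with `miRNA_id`, `target_id`, `target_class`.
#' @return De-duplicated `target_map` data.frame.
#' @export
target_map <- function(df) {
  bad <- setdiff(unique(df$target_class), TARGET_CLASSES)
  .assert(length(bad) == 0L, "unknown target_class: %s",
          paste(bad, collapse = ", "))
  df <- unique(df[c("miRNA_id", "target_id", "target_class")])
  df$miRNA_id <- as.character(df$miRNA_id)
  df$target_id <- as.character(df$target_id)
  rownames(df) <- NULL
  structure(df, class = c("target_map", "data.frame"))
}

#' Read per-cytosine methylation calls
#'
#' CX-report-like TSV: `chrom`, `pos` (1-based), `strand`, `meth_count`,
#' `unmeth_count`, `context`. Total coverage is `meth + unmeth`; records
#' violating `0 <= meth <= total`, `total > 0` or the CG/CHG/CHH context
#' vocabulary are rejected.
#'
#' @param path TSV file.
#' @return data.frame with `chrom`, `pos`, `strand`, `context`,
#'   `meth_count`, `total_count`.
#' @export
read_methylation_tsv <- function(path) {
  df <- read_tsv_plain(path)
  req <- c("chrom", "pos", "strand", "meth_count", "unmeth_count", "context")
  .assert(all(req %in% names(df)), "methylation table needs columns %s",
          paste(req, collapse = ", "))
  .assert(all(df$context %in% c("CG", "CHG", "CHH")),
          "unknown methylation context: %s",
          paste(setdiff(unique(df$context), c("CG", "CHG", "CHH")),
                collapse = ", "))
  .assert(all(df$meth_count >= 0) && all(df$unmeth_count >= 0),
          "negative methylation count")
  total <- df$meth_count + df$unmeth_count
  .assert(all(total > 0), "cytosine record with zero total coverage")
  data.frame(chrom = as.character(df$chrom), pos = as.integer(df$pos),
             strand = as.character(df$strand),
             context = as.character(df$context),
             meth_count = as.integer(df$meth_count),
             total_count = as.integer(total), stringsAsFactors = FALSE)
}

#' Write methylation calls as a CX-report-like TSV
#' @param calls data.frame as returned by [read_methylation_tsv].
#' @param path output file.
#' @export
write_methylation_tsv <- function(calls, path) {
  out <- data.frame(chrom = calls$chrom, pos = calls$pos,
                    strand = calls$strand, meth_count = calls$meth_count,
                    unmeth_count = calls$total_count - calls$meth_count,
                    context = calls$context)
  write_tsv_commented(out, path)
}

#' Read context-tagged DMR intervals from BED
#'
#' BED is already 0-based half-open, matching the internal convention. The
#' 4th column carries the methylation context (CG/CHG/CHH).
#'
#' @param path BED file (no header).
#' @return data.frame with `chrom`, `start`, `end`, `context`.
#' @export
read_dmr_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  .assert(ncol(df) >= 4L, "DMR BED needs 4 columns (chrom, start, end, context)")
  names(df)[1:4] <- c("chrom", "start", "end", "context")
  .assert(all(df$start < df$end), "DMR with start >= end")
  .assert(all(df$context %in% c("CG", "CHG", "CHH")),
          "unknown DMR context: %s",
          paste(setdiff(unique(df$context), c("CG", "CHG", "CHH")),
                collapse = ", "))
  df[1:4]
}

#' Write DMR intervals as BED
#' @param dmrs data.frame with `chrom`, `start`, `end`, `context`.
#' @param path output file.
#' @export
write_dmr_bed <- function(dmrs, path) {
  utils::write.table(dmrs[c("chrom", "start", "end", "context")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read per-window FST / nucleotide-diversity statistics
#'
#' TSV with columns `chrom`, `start`, `end`, `fst`, `pi_a`, `pi_b`.
#' FST may be negative (as common estimators emit); diversities must be
#' non-negative.
#'
#' @param path TSV file.
#' @return data.frame of window statistics.
#' @export
read_window_stats <- function(path) {
  df <- read_tsv_plain(path)
  req <- c("chrom", "start", "end", "fst", "pi_a", "pi_b")
  .assert(all(req %in% names(df)), "window table needs columns %s",
          paste(req, collapse = ", "))
  .assert(all(df$start < df$end), "window with start >= end")
  .assert(all(df$pi_a >= 0) && all(df$pi_b >= 0),
          "negative nucleotide diversity")
  df[req]
}

#' Export a network
#'
#' Writes the node and edge tables of a network (e.g. a `cerna_network`) in
#' one of three formats: `"tsv"` (edge table plus a `.nodes.tsv` node
#' attribute table; round-trips exactly through [read_network_edges]),
#' `"sif"` (Cytoscape simple interaction format), or `"graphml"` (via the
#' igraph package).
#'
#' @param network list with `nodes` and `edges` data.frames (`edges` has at
#'   least `from`, `to`, `edge_type`).
#' @param path output file.
#' @param format one of `"tsv"`, `"sif"`, `"graphml"`.
#' @export
write_network <- function(network, path, format = c("tsv", "sif", "graphml")) {
  format <- match.arg(format)
  nodes <- network$nodes
  edges <- network$edges
  if (format == "tsv") {
    write_tsv_commented(edges, path)
    write_tsv_commented(nodes, sub("(\\.[^.]+)?$", ".nodes.tsv", path))
  } else if (format == "sif") {
    lines <- if (nrow(edges)) {
      sprintf("%s\t%s\t%s", edges$from, edges$edge_type, edges$to)
    } else character()
    writeLines(lines, path)
  } else {
    .assert(requireNamespace("igraph", quietly = TRUE),
            "the igraph package is required for GraphML export")
    g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                       vertices = nodes)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read back an edge-TSV network
#' @param path edge table written by [write_network] with `format = "tsv"`.
#' @return list with `edges` and `nodes` data.frames.
#' @export
read_network_edges <- function(path) {
  edges <- read_tsv_plain(path)
  npath <- sub("(\\.[^.]+)?$", ".nodes.tsv", path)
  nodes <- if (file.exists(npath)) read_tsv_plain(npath) else NULL
  list(edges = edges, nodes = nodes)
}
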