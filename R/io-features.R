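# Shared data model for genomic features plus GFF3 in/out.
#
# Internal coordinates are 0-based half-open throughout the package; the
# GFF3 (1-based inclusive) and BED (0-based half-open) dialects are
# converted at the file boundary and nowhere else.

FEATURE_CLASSES <- c("gene", "mRNA", "lncRNA", "circRNA", "miRNA",
                     "DMR", "window")

#' Construct a feature set
#'
#' A validated data.frame of strand-aware genomic intervals with an optional
#' exon table attached as an attribute. Coordinates are 0-based half-open.
#'
#' @param features data.frame with columns `chrom`, `start`, `end`,
#'   `strand`, `feature_id`, `feature_class` and optionally `exon_count`.
#' @param exons optional data.frame of exon children with columns
#'   `parent_id`, `chrom`, `start`, `end`, `strand`. Exons must lie within
#'   their parent interval.
#' @return A `feature_set` (data.frame subclass) with an `exons` attribute.
#' @export
feature_set <- function(features, exons = NULL) {
  req <- c("chrom", "start", "end", "strand", "feature_id", "feature_class")
  .assert(all(req %in% names(features)), "missing feature columns: %s",
          paste(setdiff(req, names(features)), collapse = ", "))
  features$chrom <- as.character(features$chrom)
  features$feature_id <- as.character(features$feature_id)
  features$strand <- as.character(features$strand)
  .assert(all(features$start >= 0), "negative start coordinate")
  .assert(all(features$start < features$end),
          "start >= end for feature(s): %s",
          paste(utils::head(features$feature_id[features$start >= features$end]),
                collapse = ", "))
  .assert(!anyDuplicated(features$feature_id),
          "duplicate feature_id: %s",
          paste(utils::head(unique(features$feature_id[
            duplicated(features$feature_id)])), collapse = ", "))
  bad_cls <- setdiff(unique(features$feature_class), FEATURE_CLASSES)
  .assert(length(bad_cls) == 0L, "unknown feature_class: %s",
          paste(bad_cls, collapse = ", "))
  .assert(all(features$strand %in% c("+", "-", ".")),
          "invalid strand value")
  if (is.null(features$exon_count)) features$exon_count <- NA_integer_
  if (!is.null(exons) && nrow(exons) > 0L) {
    idx <- match(exons$parent_id, features$feature_id)
    .assert(!anyNA(idx), "exon with unknown parent: %s",
            paste(utils::head(exons$parent_id[is.na(idx)]), collapse = ", "))
    inside <- exons$start >= features$start[idx] &
      exons$end <= features$end[idx] &
      exons$chrom == features$chrom[idx]
    .assert(all(inside), "exon outside its parent interval (parent %s)",
            paste(utils::head(exons$parent_id[!inside]), collapse = ", "))
  }
  rownames(features) <- NULL
  structure(features, exons = exons, class = c("feature_set", "data.frame"))
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %d features (%s)\n", nrow(x),
              paste(sprintf("%s: %d", names(table(x$feature_class)),
                            table(x$feature_class)), collapse = ", ")))
  NextMethod()
}

feature_exons <- function(fs) attr(fs, "exons")

.parse_gff_attr <- function(attr_str, key) {
  m <- regmatches(attr_str,
                  regexec(paste0("(?:^|;)\\s*", key, "=([^;]+)"), attr_str))
  vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_, "")
}

#' Read a GFF3 annotation
#'
#' Parses a GFF3 file into a [feature_set], converting 1-based inclusive
#' coordinates to the internal 0-based half-open convention. Exon children
#' (type `exon`, linked by `Parent=`) populate `exon_count` and the exon
#' table. Feature types outside the recognised vocabulary are skipped and
#' counted in a message; malformed lines and records with `end < start` are
#' errors, never silently dropped.
#'
#' @param path GFF3 file.
#' @param type_map named character vector mapping GFF3 `type` values to
#'   internal feature classes.
#' @return A [feature_set].
#' @export
read_gff <- function(path,
                     type_map = c(gene = "gene", mRNA = "mRNA",
                                  lnc_RNA = "lncRNA", lncRNA = "lncRNA",
                                  circRNA = "circRNA", miRNA = "miRNA",
                                  pre_miRNA = "miRNA")) {
  lines <- readLines(path)
  keep <- !(grepl("^#", lines) | lines == "")
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(feature_set(data.frame(chrom = character(), start = integer(),
                                  end = integer(), strand = character(),
                                  feature_id = character(),
                                  feature_class = character())))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  .assert(all(nf == 9L), "malformed GFF3 line %d: expected 9 fields, got %d",
          lineno[which(nf != 9L)[1]], nf[which(nf != 9L)[1]])
  mat <- do.call(rbind, fields)
  start <- suppressWarnings(as.integer(mat[, 4]))
  end <- suppressWarnings(as.integer(mat[, 5]))
  bad <- which(is.na(start) | is.na(end))
  .assert(length(bad) == 0L, "malformed GFF3 line %d: non-numeric coordinates",
          lineno[bad[1]])
  bad <- which(end < start)
  .assert(length(bad) == 0L, "GFF3 line %d: end < start", lineno[bad[1]])
  type <- mat[, 3]
  strand <- mat[, 7]
  strand[!strand %in% c("+", "-")] <- "."

  is_exon <- type == "exon"
  known <- type %in% names(type_map) & !is_exon
  n_skip <- sum(!known & !is_exon)
  if (n_skip > 0L) {
    message(sprintf("read_gff: skipped %d record(s) of unrecognised type (%s)",
                    n_skip,
                    paste(unique(type[!known & !is_exon]), collapse = ", ")))
  }

  ids <- .parse_gff_attr(mat[known, 9], "ID")
  .assert(!anyNA(ids), "GFF3 line %d: feature record without ID attribute",
          lineno[known][which(is.na(ids))[1]])
  feats <- data.frame(
    chrom = mat[known, 1], start = start[known] - 1L, end = end[known],
    strand = strand[known], feature_id = ids,
    feature_class = unname(type_map[type[known]]),
    stringsAsFactors = FALSE
  )
  exons <- NULL
  if (any(is_exon)) {
    parent <- .parse_gff_attr(mat[is_exon, 9], "Parent")
    .assert(!anyNA(parent), "GFF3 line %d: exon without Parent attribute",
            lineno[is_exon][which(is.na(parent))[1]])
    exons <- data.frame(
      parent_id = parent, chrom = mat[is_exon, 1],
      start = start[is_exon] - 1L, end = end[is_exon],
      strand = strand[is_exon], stringsAsFactors = FALSE
    )
    exons <- exons[exons$parent_id %in% feats$feature_id, , drop = FALSE]
  }
  cnt <- if (!is.null(exons)) table(exons$parent_id) else table(character())
  feats$exon_count <- as.integer(cnt[feats$feature_id])
  feats$exon_count[is.na(feats$exon_count)] <- 0L
  feature_set(feats, exons = exons)
}

#' Write a feature set as GFF3
#'
#' Inverse of [read_gff]: internal 0-based half-open coordinates become
#' 1-based inclusive, exon children are emitted with `Parent=` links, and a
#' read-back reproduces coordinates and strands bit-exactly.
#'
#' @param fs a [feature_set].
#' @param path output file.
#' @export
write_gff <- function(fs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  lines <- sprintf("%s\tecoRNA\t%s\t%d\t%d\t.\t%s\t.\tID=%s",
                   fs$chrom, fs$feature_class, fs$start + 1L, fs$end,
                   fs$strand, fs$feature_id)
  writeLines(lines, con)
  ex <- feature_exons(fs)
  if (!is.null(ex) && nrow(ex) > 0L) {
    writeLines(sprintf("%s\tecoRNA\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                       ex$chrom, ex$start + 1L, ex$end, ex$strand,
                       ex$parent_id), con)
  }
  invisible(path)
}
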