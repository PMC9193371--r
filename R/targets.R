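# lncRNA cis/trans target inference and DE-target set intersections.

#' Cis targets of lncRNAs
#'
#' A gene is a cis target of a lncRNA iff its interval overlaps the window
#' `[lnc_start - window_bp, lnc_end + window_bp)` on the same chromosome.
#' The window is symmetric and strand-agnostic ("upstream and downstream"
#' of the lncRNA span). `distance_bp` is 0 for genes overlapping the lncRNA
#' itself, otherwise the gap length between the two intervals.
#'
#' @param lncrnas,genes feature_set/data.frames of intervals.
#' @param window_bp window half-width in bp (default 100 kb).
#' @return data.frame of pairs: `regulator_id`, `target_id`, `mode = "cis"`,
#'   `distance_bp`.
#' @export
cis_targets <- function(lncrnas, genes, window_bp = 100000) {
  if (nrow(lncrnas) == 0L || nrow(genes) == 0L) {
    return(data.frame(regulator_id = character(), target_id = character(),
                      mode = character(), distance_bp = integer()))
  }
  win <- data.frame(chrom = lncrnas$chrom,
                    start = pmax(0L, lncrnas$start - as.integer(window_bp)),
                    end = lncrnas$end + as.integer(window_bp),
                    strand = "+")
  hits <- GenomicRanges::findOverlaps(fs_granges(win, use_strand = FALSE),
                                      fs_granges(genes, use_strand = FALSE),
                                      ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  gap <- pmax(0L,
              pmax(genes$start[si] - lncrnas$end[qi],
                   lncrnas$start[qi] - genes$end[si]))
  out <- data.frame(regulator_id = lncrnas$feature_id[qi],
                    target_id = genes$feature_id[si],
                    mode = "cis", distance_bp = as.integer(gap),
                    stringsAsFactors = FALSE)
  out[order(out$regulator_id, out$target_id), , drop = FALSE]
}

#' Trans targets by expression correlation
#'
#' A regulator-gene pair is a trans pair iff the absolute Pearson
#' correlation of their expression across shared samples exceeds
#' `r_threshold` AND the two-sided p-value is below `p_threshold` (both
#' strict; both conditions are enforced even where they interact awkwardly
#' at small sample sizes). Constant-expression features carry no
#' correlation signal and are skipped with a message.
#'
#' @param ncrna_expr,gene_expr expression matrices over identical samples.
#' @param r_threshold absolute correlation cutoff (default 0.9).
#' @param p_threshold p-value cutoff (default 0.01).
#' @return data.frame of pairs: `regulator_id`, `target_id`,
#'   `mode = "trans"`, `r`, `pvalue`.
#' @export
trans_targets <- function(ncrna_expr, gene_expr, r_threshold = 0.9,
                          p_threshold = 0.01) {
  .assert(identical(colnames(ncrna_expr), colnames(gene_expr)),
          "sample ids differ between the two expression matrices")
  n <- ncol(ncrna_expr)
  .assert(n >= 3L, "need at least 3 shared samples")
  nc <- unclass(ncrna_expr); ge <- unclass(gene_expr)
  const_nc <- apply(nc, 1L, stats::sd) == 0
  const_ge <- apply(ge, 1L, stats::sd) == 0
  if (any(const_nc) || any(const_ge)) {
    message(sprintf("trans_targets: skipped %d regulator(s) and %d gene(s) with constant expression",
                    sum(const_nc), sum(const_ge)))
  }
  nc <- nc[!const_nc, , drop = FALSE]
  ge <- ge[!const_ge, , drop = FALSE]
  if (nrow(nc) == 0L || nrow(ge) == 0L) {
    return(data.frame(regulator_id = character(), target_id = character(),
                      mode = character(), r = numeric(), pvalue = numeric()))
  }
  r <- stats::cor(t(nc), t(ge))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(r) == 1] <- 0
  keep <- which(abs(r) > r_threshold & p < p_threshold, arr.ind = TRUE)
  if (nrow(keep) == 0L) {
    return(data.frame(regulator_id = character(), target_id = character(),
                      mode = character(), r = numeric(), pvalue = numeric()))
  }
  out <- data.frame(regulator_id = rownames(nc)[keep[, 1]],
                    target_id = rownames(ge)[keep[, 2]],
                    mode = "trans",
                    r = r[keep], pvalue = p[keep],
                    stringsAsFactors = FALSE)
  out[order(out$regulator_id, out$target_id), , drop = FALSE]
}

#' Intersect DE-regulator targets with DE features
#'
#' Pure set algebra: for the differentially expressed regulators only,
#' pools their targets, intersects the pool with the DE target set, and
#' reports per-regulator counts.
#'
#' @param target_map a [target_map] data.frame.
#' @param de_regulators character vector of DE regulator (miRNA) ids.
#' @param de_targets character vector of DE feature ids.
#' @return list with `pooled_targets`, `de_intersection`, and a
#'   `per_regulator` data.frame (`miRNA_id`, `n_targets`, `n_de_targets`).
#' @export
intersect_de_targets <- function(target_map, de_regulators, de_targets) {
  sub <- target_map[target_map$miRNA_id %in% de_regulators, , drop = FALSE]
  pooled <- sort(unique(sub$target_id))
  inter <- intersect(pooled, de_targets)
  per <- if (nrow(sub)) {
    agg <- split(sub$target_id, sub$miRNA_id)
    data.frame(miRNA_id = names(agg),
               n_targets = vapply(agg, function(t) length(unique(t)), 0L),
               n_de_targets = vapply(agg, function(t)
                 length(intersect(unique(t), de_targets)), 0L),
               row.names = NULL, stringsAsFactors = FALSE)
  } else {
    data.frame(miRNA_id = character(), n_targets = integer(),
               n_de_targets = integer())
  }
  list(pooled_targets = pooled, de_intersection = sort(inter),
       per_regulator = per)
}
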