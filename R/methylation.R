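# Per-context weighted methylation over feature bodies and flanks,
# metagene binning, group comparisons, and DMR-DE association.
#
# "Weighted" methylation level = sum(methylated reads) / sum(total reads)
# over a region's cytosines of one context, not the mean of per-site
# fractions; the weighted form is robust to coverage heterogeneity.

.region_intervals <- function(features, region, flank_bp) {
  strand <- norm_strand(features$strand,
                        if (region %in% c("upstream", "downstream"))
                          paste(region, "regions") else NULL)
  plus <- strand == "+"
  switch(region,
    body = data.frame(chrom = features$chrom, start = features$start,
                      end = features$end,
                      feature_id = features$feature_id),
    upstream = data.frame(
      chrom = features$chrom,
      start = ifelse(plus, pmax(0, features$start - flank_bp), features$end),
      end = ifelse(plus, features$start, features$end + flank_bp),
      feature_id = features$feature_id),
    downstream = data.frame(
      chrom = features$chrom,
      start = ifelse(plus, features$end, pmax(0, features$start - flank_bp)),
      end = ifelse(plus, features$end + flank_bp, features$start),
      feature_id = features$feature_id),
    flank = rbind(
      data.frame(chrom = features$chrom,
                 start = pmax(0, features$start - flank_bp),
                 end = features$start, feature_id = features$feature_id),
      data.frame(chrom = features$chrom, start = features$end,
                 end = features$end + flank_bp,
                 feature_id = features$feature_id)),
    stop("unknown region: ", region))
}

#' Weighted methylation level of one region
#'
#' Sum of methylated counts over sum of total counts across the in-region
#' cytosines of the stated context with coverage at least `min_total`.
#' Coordinates are 0-based half-open; a region with no qualifying site has
#' an undefined level (`NA`).
#'
#' @param calls methylation call data.frame (see [read_methylation_tsv]).
#' @param chrom,start,end region interval (0-based half-open).
#' @param context one of CG, CHG, CHH.
#' @param min_total minimum per-site coverage (default 1: every covered
#'   site counts).
#' @return list with `meth`, `total`, `level`.
#' @export
region_methylation_level <- function(calls, chrom, start, end, context,
                                     min_total = 1L) {
  .assert(context %in% c("CG", "CHG", "CHH"), "unknown context: %s", context)
  sel <- calls$chrom == chrom & calls$context == context &
    calls$pos - 1L >= start & calls$pos - 1L < end &
    calls$total_count >= min_total
  meth <- sum(calls$meth_count[sel])
  total <- sum(calls$total_count[sel])
  list(meth = meth, total = total,
       level = if (total > 0) meth / total else NA_real_)
}

#' Per-feature weighted methylation levels
#'
#' Vectorised form of [region_methylation_level] over a feature set, for
#' the feature body, a strand-aware 2 kb upstream/downstream flank, or both
#' flanks pooled.
#'
#' @param calls methylation call data.frame.
#' @param features feature_set/data.frame.
#' @param context one of CG, CHG, CHH.
#' @param region one of `body`, `upstream`, `downstream`, `flank`.
#' @param flank_bp flank width (default 2000).
#' @param min_total minimum per-site coverage.
#' @return Named numeric vector of levels (NA where no covered site).
#' @export
feature_methylation_levels <- function(calls, features, context,
                                       region = "body", flank_bp = 2000L,
                                       min_total = 1L) {
  .assert(nrow(features) > 0L, "empty feature set")
  regions <- .region_intervals(features, region, flank_bp)
  regions <- regions[regions$start < regions$end, , drop = FALSE]
  calls <- calls[calls$context == context &
                   calls$total_count >= min_total, , drop = FALSE]
  meth <- total <- stats::setNames(numeric(nrow(features)),
                                   features$feature_id)
  if (nrow(calls) > 0L && nrow(regions) > 0L) {
    hits <- GenomicRanges::findOverlaps(
      pos_granges(calls$chrom, calls$pos),
      fs_granges(transform(regions, strand = "+"), use_strand = FALSE),
      ignore.strand = TRUE)
    ci <- S4Vectors::queryHits(hits)
    fid <- regions$feature_id[S4Vectors::subjectHits(hits)]
    if (length(ci)) {
      ms <- rowsum(calls$meth_count[ci], fid)
      ts <- rowsum(calls$total_count[ci], fid)
      meth[rownames(ms)] <- ms[, 1]
      total[rownames(ts)] <- ts[, 1]
    }
  }
  ifelse(total > 0, meth / total, NA_real_)
}

#' Metagene methylation profile
#'
#' Bins each feature into `flank_bins` fixed-width upstream bins,
#' `body_bins` proportional body bins and `flank_bins` downstream bins
#' (defaults 20/20/20 with 100 bp flank bins over +/-2 kb), computes the
#' weighted methylation level per feature and bin, and averages across the
#' features covered in that bin. Bin 0 is always the 5'-most bin:
#' minus-strand features have their genomic bin vector reversed, so
#' reversing a feature's strand reverses its contribution exactly. Bins
#' without any covered cytosine are missing (`NA`), never zero.
#'
#' @param calls methylation call data.frame.
#' @param features strand-annotated feature_set/data.frame.
#' @param context one of CG, CHG, CHH.
#' @param flank_bp flank width (default 2000).
#' @param body_bins,flank_bins bin counts (defaults 20 each).
#' @param min_total minimum per-site coverage.
#' @return data.frame of class `metagene_profile`: `context`, `bin`,
#'   `region`, `mean_level`, `n_features`.
#' @export
metagene_profile <- function(calls, features, context, flank_bp = 2000L,
                             body_bins = 20L, flank_bins = 20L,
                             min_total = 1L) {
  .assert(!is.null(features) && nrow(features) > 0L, "empty feature set")
  .assert(context %in% c("CG", "CHG", "CHH"), "unknown context: %s", context)
  strand <- norm_strand(features$strand, "metagene profiling")
  nbins <- 2L * flank_bins + body_bins
  calls <- calls[calls$context == context &
                   calls$total_count >= min_total, , drop = FALSE]

  ext <- data.frame(chrom = features$chrom,
                    start = pmax(0L, features$start - flank_bp),
                    end = features$end + flank_bp, strand = "+")
  meth <- total <- matrix(0, nrow(features), nbins)
  if (nrow(calls) > 0L) {
    hits <- GenomicRanges::findOverlaps(
      pos_granges(calls$chrom, calls$pos),
      fs_granges(ext, use_strand = FALSE), ignore.strand = TRUE)
    ci <- S4Vectors::queryHits(hits)
    fi <- S4Vectors::subjectHits(hits)
    if (length(ci)) {
      pos0 <- calls$pos[ci] - 1L
      fstart <- features$start[fi]
      fend <- features$end[fi]
      flen <- fend - fstart
      binw <- flank_bp / flank_bins
      # genomic-layout bin: 0..flank_bins-1 upstream-left, body, right flank
      bin <- integer(length(ci))
      left <- pos0 < fstart
      right <- pos0 >= fend
      body <- !left & !right
      bin[left] <- pmin(flank_bins - 1L,
                        floor((pos0[left] - (fstart[left] - flank_bp)) / binw))
      bin[body] <- flank_bins +
        pmin(body_bins - 1L,
             floor((pos0[body] - fstart[body]) / flen[body] * body_bins))
      bin[right] <- flank_bins + body_bins +
        pmin(flank_bins - 1L, floor((pos0[right] - fend[right]) / binw))
      # orientation flip: bin 0 must be 5'-most
      minus <- strand[fi] == "-"
      bin[minus] <- nbins - 1L - bin[minus]
      lin <- fi + bin * nrow(features)  # column-major linear index
      ms <- rowsum(calls$meth_count[ci], lin)
      ts <- rowsum(calls$total_count[ci], lin)
      meth[as.integer(rownames(ms))] <- ms[, 1]
      total[as.integer(rownames(ts))] <- ts[, 1]
    }
  }
  lev <- ifelse(total > 0, meth / total, NA)
  region <- rep(c("upstream", "body", "downstream"),
                c(flank_bins, body_bins, flank_bins))
  out <- data.frame(
    context = context,
    bin = 0:(nbins - 1L),
    region = region,
    mean_level = colMeans(lev, na.rm = TRUE),
    n_features = colSums(!is.na(lev)),
    stringsAsFactors = FALSE)
  out$mean_level[out$n_features == 0L] <- NA_real_
  attr(out, "feature_levels") <- lev
  class(out) <- c("metagene_profile", "data.frame")
  out
}

#' @export
plot.metagene_profile <- function(x, ...) {
  graphics::plot(x$bin, x$mean_level, type = "l", xlab = "bin (5' to 3')",
                 ylab = "weighted methylation level",
                 main = paste0(x$context[1], " metagene profile"),
                 ylim = c(0, 1), ...)
  brk <- cumsum(c(sum(x$region == "upstream"), sum(x$region == "body")))
  graphics::abline(v = brk - 0.5, lty = 3, col = "grey50")
  invisible(x)
}

#' Compare group methylation levels
#'
#' Two-sided Mann-Whitney U test on per-feature levels of two sample
#' groups; undefined (NA) levels are excluded with a message.
#'
#' @param levels_a,levels_b per-feature level vectors (see
#'   [feature_methylation_levels]).
#' @return A [test_result].
#' @export
compare_group_methylation <- function(levels_a, levels_b) {
  na_a <- sum(is.na(levels_a)); na_b <- sum(is.na(levels_b))
  if (na_a + na_b > 0L) {
    message(sprintf("compare_group_methylation: excluded %d + %d undefined levels",
                    na_a, na_b))
  }
  a <- levels_a[!is.na(levels_a)]; b <- levels_b[!is.na(levels_b)]
  .assert(length(a) > 0L && length(b) > 0L,
          "a group is empty after excluding undefined levels")
  mann_whitney_u(a, b)
}

#' DMR - differential-expression association
#'
#' For each methylation context present in the DMR set, flags every feature
#' whose stated region (body, or either 2 kb flank) overlaps a DMR of that
#' context by at least one base, then tests the 2x2 table
#' (DE vs non-DE) x (DMR vs no DMR) with the chi-squared test (no
#' correction). A degenerate table (zero marginal) is an error carrying the
#' offending table in the message.
#'
#' @param features feature_set/data.frame.
#' @param dmrs data.frame with `chrom`, `start`, `end`, `context`.
#' @param de_flags data.frame from [flag_differential] covering the
#'   features.
#' @param region `"body"` or `"flank"` (both flanks pooled).
#' @param flank_bp flank width (default 2000).
#' @return Named list per context: `table` (2x2 counts), `test`
#'   ([test_result]), `flagged` (feature ids overlapping a DMR).
#' @export
dmr_de_association <- function(features, dmrs, de_flags,
                               region = c("body", "flank"),
                               flank_bp = 2000L) {
  region <- match.arg(region)
  .assert(nrow(dmrs) > 0L,
          "empty DMR set: every feature would be un-flagged (zero marginal)")
  dirs <- de_flags$direction[match(features$feature_id, de_flags$feature_id)]
  .assert(!anyNA(dirs), "feature(s) missing from de_flags")
  is_de <- dirs != "ns"
  out <- list()
  for (ctx in sort(unique(dmrs$context))) {
    d <- dmrs[dmrs$context == ctx, , drop = FALSE]
    regions <- .region_intervals(features, region, flank_bp)
    regions <- regions[regions$start < regions$end, , drop = FALSE]
    flagged <- rep(FALSE, nrow(features))
    if (nrow(d) > 0L && nrow(regions) > 0L) {
      hits <- GenomicRanges::findOverlaps(
        fs_granges(transform(regions, strand = "+"), use_strand = FALSE),
        fs_granges(transform(d, strand = "+"), use_strand = FALSE),
        ignore.strand = TRUE)
      hit_ids <- unique(regions$feature_id[S4Vectors::queryHits(hits)])
      flagged <- features$feature_id %in% hit_ids
    }
    tab <- matrix(c(sum(is_de & flagged), sum(is_de & !flagged),
                    sum(!is_de & flagged), sum(!is_de & !flagged)),
                  nrow = 2, byrow = TRUE,
                  dimnames = list(c("DE", "non_DE"), c("DMR", "no_DMR")))
    test <- tryCatch(chi_square_2x2(tab), error = function(e) {
      stop(sprintf("context %s: %s", ctx, conditionMessage(e)),
           call. = FALSE)
    })
    out[[ctx]] <- list(context = ctx, table = tab, test = test,
                       flagged = features$feature_id[flagged])
  }
  out
}
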