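# Selection-scan classification of sliding windows from FST and
# nucleotide-diversity ratios, and feature overlap with selected regions.

#' Classify windows as ecotype-selected
#'
#' A window is selected in population A iff its FST reaches the upper
#' `1 - fst_quantile` tail AND its diversity ratio `pi_a / pi_b` falls in
#' the lower `ratio_quantile` tail; symmetrically for population B with the
#' reciprocal ratio. Empirical quantiles use linear interpolation between
#' order statistics (R type 7) and the threshold comparisons are inclusive
#' (`>=` for the FST tail, `<=` for the ratio tail). Ratio quantiles are
#' computed over finite ratios only: windows with `pi_a = pi_b = 0` have no
#' defined ratio, and an infinite ratio (`pi_b = 0 < pi_a`) sorts above
#' every finite one and can never enter a lower tail. If every FST value is
#' identical the FST gate degenerates (all windows pass) with a warning.
#' In the rare event that a window qualifies for both tails, the smaller of
#' the two ratios decides; an exact tie stays unselected, so swapping
#' population labels swaps the calls exactly.
#'
#' @param windows data.frame with `chrom`, `start`, `end`, `fst`, `pi_a`,
#'   `pi_b` (at least 20 windows with finite FST).
#' @param fst_quantile FST tail quantile (default 0.95, the upper 5%).
#' @param ratio_quantile ratio tail quantile (default 0.05, the lower 5%).
#' @return The windows with `ratio_ab`, `ratio_ba`, `selected_in` in
#'   \{`pop_a`, `pop_b`, `none`\}; thresholds in the `thresholds`
#'   attribute.
#' @export
classify_selected <- function(windows, fst_quantile = 0.95,
                              ratio_quantile = 0.05) {
  req <- c("chrom", "start", "end", "fst", "pi_a", "pi_b")
  .assert(all(req %in% names(windows)), "window table needs columns %s",
          paste(req, collapse = ", "))
  fst <- windows$fst
  .assert(sum(is.finite(fst)) >= 20L,
          "need at least 20 windows with finite FST")
  if (length(unique(fst[is.finite(fst)])) == 1L) {
    warning("all FST values identical: degenerate threshold, every window passes the FST gate",
            call. = FALSE)
  }
  thr_fst <- stats::quantile(fst[is.finite(fst)], fst_quantile, names = FALSE)

  ratio_ab <- ifelse(windows$pi_a == 0 & windows$pi_b == 0, NA_real_,
                     windows$pi_a / windows$pi_b)
  ratio_ba <- ifelse(windows$pi_a == 0 & windows$pi_b == 0, NA_real_,
                     windows$pi_b / windows$pi_a)
  fin_a <- is.finite(ratio_ab)
  fin_b <- is.finite(ratio_ba)
  thr_a <- stats::quantile(ratio_ab[fin_a], ratio_quantile, names = FALSE)
  thr_b <- stats::quantile(ratio_ba[fin_b], ratio_quantile, names = FALSE)

  pass_fst <- is.finite(fst) & fst >= thr_fst
  in_a <- pass_fst & fin_a & ratio_ab <= thr_a
  in_b <- pass_fst & fin_b & ratio_ba <= thr_b
  both <- in_a & in_b
  # resolve double qualification by the smaller ratio; exact tie -> none
  in_a[both] <- ratio_ab[both] < ratio_ba[both]
  in_b[both] <- ratio_ba[both] < ratio_ab[both]

  out <- windows
  out$ratio_ab <- ratio_ab
  out$ratio_ba <- ratio_ba
  out$selected_in <- ifelse(in_a, "pop_a", ifelse(in_b, "pop_b", "none"))
  attr(out, "thresholds") <- c(fst = thr_fst, ratio_a = thr_a, ratio_b = thr_b)
  out
}

#' Features overlapping selected windows
#'
#' A feature is under selection iff it shares at least one base (half-open
#' arithmetic; mere adjacency does not count) with any selected window.
#' Selection population is carried over; a feature overlapping windows
#' selected in both populations is reported as `both`.
#'
#' @param features feature_set/data.frame of intervals with
#'   `feature_class`.
#' @param calls output of [classify_selected].
#' @return list with `table` (per-feature `feature_id`, `feature_class`,
#'   `selected_in`) and `per_class` (selected feature ids split by class).
#' @export
overlap_selected_features <- function(features, calls) {
  sel <- calls[calls$selected_in != "none", , drop = FALSE]
  selected_in <- rep("none", nrow(features))
  if (nrow(sel) > 0L && nrow(features) > 0L) {
    hits <- GenomicRanges::findOverlaps(
      fs_granges(features, use_strand = FALSE),
      fs_granges(transform(sel, strand = "+"), use_strand = FALSE),
      ignore.strand = TRUE)
    qi <- S4Vectors::queryHits(hits)
    pop <- sel$selected_in[S4Vectors::subjectHits(hits)]
    for (i in unique(qi)) {
      pops <- unique(pop[qi == i])
      selected_in[i] <- if (length(pops) > 1L) "both" else pops
    }
  }
  tab <- data.frame(feature_id = features$feature_id,
                    feature_class = features$feature_class,
                    selected_in = selected_in, stringsAsFactors = FALSE)
  sel_tab <- tab[tab$selected_in != "none", , drop = FALSE]
  list(table = tab,
       per_class = split(sel_tab$feature_id, sel_tab$feature_class))
}

#' Compare selected proportions between two feature classes
#'
#' Pearson chi-squared test (1 df, no continuity correction by default) on
#' the 2x2 table (selected, not selected) x (class A, class B).
#'
#' @param selected_a,total_a selected and total counts for class A.
#' @param selected_b,total_b same for class B.
#' @param yates apply the Yates correction?
#' @return A [test_result].
#' @export
compare_selected_proportions <- function(selected_a, total_a,
                                         selected_b, total_b,
                                         yates = FALSE) {
  .assert(selected_a <= total_a && selected_b <= total_b,
          "selected count exceeds total")
  .assert(total_a > 0 && total_b > 0, "zero total count")
  tab <- matrix(c(selected_a, total_a - selected_a,
                  selected_b, total_b - selected_b),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("class_a", "class_b"),
                                c("selected", "not_selected")))
  chi_square_2x2(tab, yates = yates)
}
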