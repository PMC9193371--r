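# Expression specificity (Tau), threshold-based differential-expression
# flagging, and ecotype-specific feature calling.

#' Tau expression-specificity index
#'
#' `tau = sum(1 - x_i / x_max) / (n - 1)` over `n >= 2` conditions:
#' 0 for perfectly uniform expression, 1 for expression confined to a single
#' condition. Computed on linear abundances by default; `log_transform`
#' applies `log2(x + 1)` first. A feature silent in every condition
#' (`x_max = 0`) has no defined specificity and returns `NA`.
#'
#' @param x non-negative expression vector (one value per condition), or a
#'   features x conditions matrix for row-wise computation.
#' @param log_transform apply `log2(x + 1)` before the index (default off).
#' @return Scalar tau for a vector input; named vector for a matrix.
#' @examples
#' specificity_index(c(8, 4, 2, 1, 0))  # 0.78125
#' @export
specificity_index <- function(x, log_transform = FALSE) {
  if (is.matrix(x)) {
    return(apply(x, 1L, specificity_index, log_transform = log_transform))
  }
  .assert(length(x) >= 2L, "tau needs at least 2 conditions")
  .assert(all(is.finite(x)) && all(x >= 0), "negative or non-finite expression")
  if (log_transform) x <- log2(x + 1)
  xmax <- max(x)
  if (xmax == 0) return(NA_real_)
  sum(1 - x / xmax) / (length(x) - 1)
}

#' Per-feature specificity table
#'
#' @param expr an [expression_matrix] (conditions are its columns).
#' @param log_transform see [specificity_index].
#' @return data.frame with `feature_id`, `tau`, `n_conditions`.
#' @export
specificity_table <- function(expr, log_transform = FALSE) {
  tau <- specificity_index(unclass(expr), log_transform = log_transform)
  data.frame(feature_id = rownames(expr), tau = unname(tau),
             n_conditions = ncol(expr), stringsAsFactors = FALSE)
}

#' Flag differential expression from precomputed statistics
#'
#' Threshold rule on externally estimated DE statistics (log2 fold change
#' and FDR are inputs; no model is fitted here): `up` iff
#' `log2FC > lfc_threshold` and `fdr < fdr_threshold`; `down` iff
#' `log2FC < -lfc_threshold` and `fdr < fdr_threshold`; otherwise `ns`.
#' All inequalities are strict, so a feature at exactly `log2FC = 1` is not
#' differential at the default threshold.
#'
#' @param stats data.frame with `feature_id`, `log2FC`, `fdr`.
#' @param lfc_threshold absolute log2 fold-change cutoff (default 1).
#' @param fdr_threshold FDR cutoff (default 0.05; the stricter 0.01 used for
#'   some contrasts is one parameter away).
#' @return data.frame with `feature_id` and `direction` in
#'   \{`up`, `down`, `ns`\}.
#' @export
flag_differential <- function(stats, lfc_threshold = 1.0,
                              fdr_threshold = 0.05) {
  req <- c("feature_id", "log2FC", "fdr")
  .assert(all(req %in% names(stats)), "DE table needs columns %s",
          paste(req, collapse = ", "))
  .assert(all(stats$fdr >= 0, na.rm = TRUE), "negative FDR")
  sig <- stats$fdr < fdr_threshold
  dir <- ifelse(sig & stats$log2FC > lfc_threshold, "up",
         ifelse(sig & stats$log2FC < -lfc_threshold, "down", "ns"))
  data.frame(feature_id = as.character(stats$feature_id), direction = dir,
             stringsAsFactors = FALSE)
}

#' Ecotype-specific features
#'
#' A feature is specific to group A iff its abundance is strictly positive
#' in every group-A sample and exactly zero in every group-B sample
#' (symmetrically for B). Zero means exact zero: undetected back-splice
#' junctions are emitted as true zeros, so no epsilon is applied.
#'
#' @param expr an [expression_matrix].
#' @param group_a,group_b group labels (must match the matrix's `groups`
#'   attribute, or `groups`).
#' @param groups optional named sample -> group vector overriding the
#'   attribute.
#' @return list with `a_specific` and `b_specific` feature-id vectors
#'   (disjoint by construction).
#' @export
ecotype_specific_features <- function(expr, group_a, group_b,
                                      groups = expr_groups(expr)) {
  .assert(!is.null(groups), "no group labels available")
  a_cols <- names(groups)[groups == group_a]
  b_cols <- names(groups)[groups == group_b]
  .assert(length(a_cols) > 0L, "group '%s' has no samples", group_a)
  .assert(length(b_cols) > 0L, "group '%s' has no samples", group_b)
  m <- unclass(expr)
  a_spec <- rowSums(m[, a_cols, drop = FALSE] > 0) == length(a_cols) &
    rowSums(m[, b_cols, drop = FALSE] == 0) == length(b_cols)
  b_spec <- rowSums(m[, b_cols, drop = FALSE] > 0) == length(b_cols) &
    rowSums(m[, a_cols, drop = FALSE] == 0) == length(a_cols)
  list(a_specific = rownames(m)[a_spec], b_specific = rownames(m)[b_spec])
}

#' Compare specificity between two feature groups
#'
#' Two-sided Mann-Whitney U test on two collections of tau values;
#' undefined (NA) values are excluded with a message.
#'
#' @param tau_a,tau_b numeric tau vectors (NA = undefined).
#' @return A [test_result].
#' @export
compare_specificity <- function(tau_a, tau_b) {
  na_a <- sum(is.na(tau_a)); na_b <- sum(is.na(tau_b))
  if (na_a + na_b > 0L) {
    message(sprintf("compare_specificity: excluded %d + %d undefined tau",
                    na_a, na_b))
  }
  a <- tau_a[!is.na(tau_a)]; b <- tau_b[!is.na(tau_b)]
  .assert(length(a) > 0L && length(b) > 0L,
          "a group is empty after excluding undefined tau")
  mann_whitney_u(a, b)
}
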