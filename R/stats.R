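# Exact and closed-form statistical primitives shared by all stages.

#' Construct a test result
#'
#' Light container for the outcome of a hypothesis test: the statistic, the
#' p-value, the method name, and method-specific extras (degrees of freedom,
#' the U statistic, the contingency table, ...).
#'
#' @param statistic numeric test statistic.
#' @param pvalue p-value in \[0, 1\].
#' @param method human-readable method name.
#' @param extras named list of method-specific quantities.
#' @return An object of class `test_result`.
#' @export
test_result <- function(statistic, pvalue, method, extras = list()) {
  .assert(is.na(pvalue) || (pvalue >= 0 && pvalue <= 1),
          "p-value outside [0, 1]: %g", pvalue)
  structure(list(statistic = unname(statistic), pvalue = unname(pvalue),
                 method = method, extras = extras),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  statistic = %g, p-value = %g\n", x$statistic, x$pvalue))
  invisible(x)
}

#' Upper-tail hypergeometric probability
#'
#' Computes `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability
#' of drawing at least `k` marked items when `n` items are drawn without
#' replacement from a population of `N` containing `K` marked items. This is
#' the shared-miRNA enrichment test behind ceRNA pair scoring: `k` shared
#' miRNAs between two RNAs targeted by `K` and `n` miRNAs respectively, out
#' of `N` miRNAs in the target map.
#'
#' The sum is evaluated in log space via `lchoose()` (log-gamma), so no
#' factorial overflow occurs for any practical population size.
#'
#' @param k observed overlap (integer within the hypergeometric support).
#' @param K marked items in the population.
#' @param n draws.
#' @param N population size.
#' @return Upper-tail probability in \[0, 1\].
#' @examples
#' hypergeom_sf(5, 5, 5, 10)  # 1/252
#' @export
hypergeom_sf <- function(k, K, n, N) {
  for (v in list(k = k, K = K, n = n, N = N)) {
    .assert(length(v) == 1L && is.finite(v) && v == round(v),
            "hypergeometric parameters must be single integers")
  }
  .assert(K >= 0 && K <= N, "K outside [0, N]")
  .assert(n >= 0 && n <= N, "n outside [0, N]")
  kmin <- max(0, n + K - N)
  kmax <- min(n, K)
  .assert(k >= kmin && k <= kmax,
          "k = %d outside support [%d, %d]", k, kmin, kmax)
  j <- k:kmax
  lt <- lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)
  m <- max(lt)
  min(1, exp(m) * sum(exp(lt - m)))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, order-preserving with the input.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values, same length and order as the input.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  .assert(all(is.finite(pvalues)) && all(pvalues >= 0) && all(pvalues <= 1),
          "p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Pearson correlation with a two-sided p-value
#'
#' `r` with a two-sided p from the t transform `t = r * sqrt((n-2)/(1-r^2))`
#' on `n - 2` degrees of freedom. A constant vector has no defined
#' correlation; `r` and the p-value come back `NA` with a warning, and
#' callers must treat the pair as non-significant.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return List with `r`, `pvalue`, `n`.
#' @export
pearson_r_p <- function(x, y) {
  n <- length(x)
  .assert(n == length(y), "x and y differ in length")
  .assert(n >= 3L, "need at least 3 paired observations")
  .assert(all(is.finite(x)) && all(is.finite(y)), "non-finite input")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector: correlation undefined", call. = FALSE)
    return(list(r = NA_real_, pvalue = NA_real_, n = n))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  r <- unname(ct$estimate)
  p <- if (abs(r) == 1) 0 else unname(ct$p.value)
  list(r = r, pvalue = p, n = n)
}

#' Mann-Whitney U test (two-sided)
#'
#' Exact enumeration when the smaller sample has at most `exact_max`
#' observations and there are no ties; otherwise the normal approximation
#' with tie correction (no continuity correction). The U statistic for the
#' first sample is reported in `extras`.
#'
#' @param a,b non-empty numeric vectors.
#' @param exact_max largest min-group size for which the exact distribution
#'   is used (default 8).
#' @return A [test_result].
#' @export
mann_whitney_u <- function(a, b, exact_max = 8L) {
  .assert(length(a) > 0L && length(b) > 0L, "empty sample")
  .assert(all(is.finite(a)) && all(is.finite(b)), "non-finite input")
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- !ties && min(length(a), length(b)) <= exact_max
  wt <- stats::wilcox.test(a, b, exact = exact, correct = FALSE)
  test_result(statistic = wt$statistic,
              pvalue = min(1, wt$p.value),
              method = "Mann-Whitney U test (two-sided)",
              extras = list(U = unname(wt$statistic), exact = exact))
}

#' Pearson chi-squared test on a 2x2 table
#'
#' One degree of freedom; Yates continuity correction only when asked for
#' (default off, the textbook closed form
#' `n (ad - bc)^2 / (r1 r2 c1 c2)`).
#'
#' @param table 2x2 matrix of non-negative counts with no zero marginal.
#' @param yates apply the continuity correction?
#' @return A [test_result] with the expected table in `extras`.
#' @export
chi_square_2x2 <- function(table, yates = FALSE) {
  tab <- as.matrix(table)
  .assert(all(dim(tab) == c(2L, 2L)), "table must be 2x2")
  .assert(all(tab >= 0) && all(is.finite(tab)), "counts must be non-negative")
  .assert(all(rowSums(tab) > 0) && all(colSums(tab) > 0),
          "zero marginal in 2x2 table [%s]", paste(tab, collapse = ", "))
  ct <- suppressWarnings(stats::chisq.test(tab, correct = yates))
  test_result(statistic = ct$statistic, pvalue = ct$p.value,
              method = if (yates) "chi-squared (Yates-corrected)"
                       else "chi-squared",
              extras = list(df = 1L, expected = ct$expected, observed = tab))
}
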