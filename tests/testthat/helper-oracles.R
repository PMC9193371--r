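# Independent brute-force oracles used to pin expected values.
# These deliberately share no code with the package implementation.

# exact hypergeometric upper tail by direct enumeration of binomials
# (choose() is exact in double precision at the sizes used here)
hyper_enum <- function(k, K, n, N) {
  j <- k:min(n, K)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# literal BH step-up definition: q_(i) = min_{j >= i} m * p_(j) / j
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- vapply(seq_len(m), function(i) min(1, min(m * ps[i:m] / (i:m))), 0)
  out <- numeric(m)
  out[o] <- q
  out
}

# exact two-sided Mann-Whitney p by enumerating all group assignments
mw_enum <- function(a, b) {
  m <- length(a); n <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combos <- utils::combn(m + n, m)
  us <- apply(combos, 2, function(ix) sum(r[ix]) - m * (m + 1) / 2)
  p_lo <- mean(us <= u_obs)
  p_hi <- mean(us >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# quadratic all-pairs cis-target scan
cis_brute <- function(lnc, genes, window_bp) {
  out <- list()
  for (i in seq_len(nrow(lnc))) {
    for (j in seq_len(nrow(genes))) {
      if (lnc$chrom[i] != genes$chrom[j]) next
      gap <- max(0, max(genes$start[j] - lnc$end[i],
                        lnc$start[i] - genes$end[j]))
      # gene must overlap [lnc_start - w, lnc_end + w) half-open
      if (genes$start[j] < lnc$end[i] + window_bp &&
          genes$end[j] > lnc$start[i] - window_bp) {
        out[[length(out) + 1L]] <- data.frame(
          regulator_id = lnc$feature_id[i], target_id = genes$feature_id[j],
          distance_bp = gap)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(regulator_id = character(), target_id = character(),
               distance_bp = integer())
}

# quadratic feature-vs-window overlap scan (half-open, >= 1 shared base)
overlap_brute <- function(features, wins) {
  vapply(seq_len(nrow(features)), function(i) {
    any(wins$chrom == features$chrom[i] &
          wins$start < features$end[i] &
          wins$end > features$start[i])
  }, TRUE)
}

# naive per-site weighted methylation level
region_level_brute <- function(calls, chrom, start, end, context) {
  meth <- 0; total <- 0
  for (i in seq_len(nrow(calls))) {
    p0 <- calls$pos[i] - 1
    if (calls$chrom[i] == chrom && calls$context[i] == context &&
        p0 >= start && p0 < end) {
      meth <- meth + calls$meth_count[i]
      total <- total + calls$total_count[i]
    }
  }
  if (total > 0) meth / total else NA_real_
}
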