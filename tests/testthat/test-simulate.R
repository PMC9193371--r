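# The synthetic-data generators: determinism, planted-truth coherence,
# and feasibility guards.

small_ann <- function(seed = 101) {
  make_annotation(seed, n_chrom = 1, chrom_len = 4e5, n_genes = 50,
                  n_lncrna = 24, n_circrna = 12, n_mirna = 20)
}

test_that("annotation generation is deterministic and class-coherent", {
  a1 <- small_ann(); a2 <- small_ann()
  expect_identical(as.data.frame(a1$features), as.data.frame(a2$features))
  expect_identical(a1$truth$lncrna_classes, a2$truth$lncrna_classes)
  expect_equal(table(a1$features$feature_class)[["gene"]], 50L)

  # the classifier recovers the planted positional classes exactly
  fs <- a1$features
  lnc <- fs[fs$feature_class == "lncRNA", ]
  cls <- classify_lncrna(lnc, fs, gene_exons = feature_exons(fs))
  planted <- a1$truth$lncrna_classes[cls$feature_id]
  expect_identical(unname(planted), cls$class)

  expect_error(make_annotation(1, n_chrom = 1, chrom_len = 1e4,
                               n_genes = 100), "infeasible")
})

test_that("expression simulation plants DE, specificity and pair correlation", {
  ann <- small_ann()
  tm <- simulate_target_map(ann, n_true_pairs = 5, n_decoy_pairs = 10,
                            seed = 7)
  ex <- simulate_expression(ann, cerna_pairs = tm$truth$true_pairs,
                            noise_sd = 0, seed = 7)
  expect_identical(
    unclass(ex$expr),
    unclass(simulate_expression(ann, cerna_pairs = tm$truth$true_pairs,
                                noise_sd = 0, seed = 7)$expr))

  # noise_sd = 0 -> pair correlation exactly 1
  m <- unclass(ex$expr)
  for (i in seq_len(5)) {
    r <- cor(m[tm$truth$true_pairs$id_a[i], ],
             m[tm$truth$true_pairs$id_b[i], ])
    expect_equal(r, 1, tolerance = 1e-12)
  }

  # planted specific circRNAs are recovered by the all-positive/all-zero rule
  res <- ecotype_specific_features(ex$expr, "temperate", "tropical")
  expect_true(all(ex$truth$planted_specific$a %in% res$a_specific))
  expect_true(all(ex$truth$planted_specific$b %in% res$b_specific))

  # planted DE features are recovered from the analytic statistics
  flags <- flag_differential(ex$de_stats)
  de_called <- flags$feature_id[flags$direction != "ns"]
  planted <- names(ex$truth$planted_de)
  expect_gte(mean(planted %in% de_called), 0.9)

  expect_error(simulate_expression(ann, de_fraction = 1.5), "de_fraction")
})

test_that("a null expression simulation stays type-I controlled", {
  ann <- small_ann()
  hits <- vapply(1:20, function(s) {
    ex <- simulate_expression(ann, de_fraction = 0, n_specific = 0,
                              seed = s)
    flags <- flag_differential(ex$de_stats)
    sum(flags$direction != "ns")
  }, 0L)
  # planted-null runs should flag essentially nothing after BH
  expect_lte(mean(hits), 0.5)
})

test_that("target map plants the promised shared sets and honours k_min", {
  ann <- small_ann()
  tm <- simulate_target_map(ann, n_true_pairs = 6, n_decoy_pairs = 12,
                            k_min = 6, seed = 3)
  expect_true(all(tm$truth$true_pairs$k >= 6))
  pairs <- enumerate_candidate_pairs(tm$map)
  key <- paste(pairs$id_a, pairs$id_b)
  for (i in 1:6) {
    tp <- sort(c(tm$truth$true_pairs$id_a[i], tm$truth$true_pairs$id_b[i]))
    expect_true(paste(tp[1], tp[2]) %in% key)
  }
  # true-pair memberships are disjoint
  members <- c(tm$truth$true_pairs$id_a, tm$truth$true_pairs$id_b)
  expect_false(anyDuplicated(members) > 0)
  expect_error(simulate_target_map(ann, k_min = 100), "k_min")
})

test_that("background-only target maps yield no candidate pairs at default degree", {
  ann <- small_ann()
  tm <- simulate_target_map(ann, n_true_pairs = 0, n_decoy_pairs = 0,
                            mean_degree = 5, seed = 13)
  pairs <- enumerate_candidate_pairs(tm$map)
  # chance k > 5 overlap is hypergeometrically negligible at this density
  expect_equal(nrow(pairs), 0L)
})

test_that("methylation simulation respects base levels, DMRs and determinism", {
  ann <- small_ann()
  sim <- simulate_methylation(ann, coverage_mean = 10, seed = 5)
  sim2 <- simulate_methylation(ann, coverage_mean = 10, seed = 5)
  expect_identical(sim$calls, sim2$calls)

  # extreme base level 1 with no site noise -> every level exactly 1
  one <- simulate_methylation(ann, base_levels = list(CG = c(1, 1)),
                              site_density = c(CG = 1),
                              site_noise_sd = 0, dmr_n = 0,
                              coverage_mean = 10, seed = 5)
  calls <- one$calls[[1]]
  expect_true(all(calls$meth_count == calls$total_count))

  # pooled level concentrates around the base level
  lv <- simulate_methylation(ann, base_levels = list(CG = c(0.3, 0.3)),
                             site_density = c(CG = 5), site_noise_sd = 0,
                             dmr_n = 0, coverage_mean = 20, seed = 5)
  pooled <- do.call(rbind, lv$calls)
  expect_equal(sum(pooled$meth_count) / sum(pooled$total_count), 0.3,
               tolerance = 0.01)

  # a planted DMR shifts the first group inside the feature body
  dmr <- simulate_methylation(ann, base_levels = list(CG = c(0.4, 0.4)),
                              site_density = c(CG = 5), site_noise_sd = 0,
                              dmr_n = 3, dmr_delta = 0.4,
                              coverage_mean = 30, seed = 5)
  fs <- ann$features
  f <- dmr$dmrs[1, ]
  grp <- dmr$groups
  g1 <- do.call(rbind, dmr$calls[grp == "temperate"])
  g2 <- do.call(rbind, dmr$calls[grp == "tropical"])
  l1 <- region_methylation_level(g1, f$chrom, f$start, f$end, "CG")$level
  l2 <- region_methylation_level(g2, f$chrom, f$start, f$end, "CG")$level
  expect_gt(abs(l1 - l2), 0.2)

  expect_error(simulate_methylation(ann, base_levels = list(CG = c(1.2, 0.5))),
               "base level")
})

test_that("window simulation plants recoverable sweeps deterministically", {
  w1 <- simulate_window_stats(n_windows = 2000, sweep_count = 20, seed = 9)
  w2 <- simulate_window_stats(n_windows = 2000, sweep_count = 20, seed = 9)
  expect_identical(w1$windows, w2$windows)
  calls <- classify_selected(w1$windows)
  sel_a <- which(calls$selected_in == "pop_a")
  sel_b <- which(calls$selected_in == "pop_b")
  expect_gte(mean(w1$truth$pop_a_idx %in% sel_a), 0.9)
  expect_gte(mean(w1$truth$pop_b_idx %in% sel_b), 0.9)

  # no sweeps planted -> nothing to recover, tails still bounded
  w0 <- simulate_window_stats(n_windows = 1000, sweep_count = 0, seed = 9)
  calls0 <- classify_selected(w0$windows)
  expect_lte(sum(calls0$selected_in != "none"), 0.05 * 1000 + 2)
  expect_error(simulate_window_stats(n_windows = 10, sweep_count = 11),
               "sweep_count")
})
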