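# Weighted methylation levels, metagene binning, group comparison,
# and DMR-DE association.

test_that("region level is the weighted ratio of summed counts", {
  calls <- mk_calls("chr1", c(10L, 20L, 30L), c(3L, 7L, 5L),
                    c(10L, 10L, 10L),
                    context = c("CG", "CG", "CHH"))
  res <- region_methylation_level(calls, "chr1", 0L, 100L, "CG")
  expect_equal(res$level, 0.5)
  expect_equal(res$total, 20L)
  # context filter: CHH query over a CG-only region is undefined
  res <- region_methylation_level(calls, "chr1", 0L, 25L, "CHH")
  expect_true(is.na(res$level))
  # empty region undefined, never zero
  expect_true(is.na(region_methylation_level(calls, "chr1", 500L, 600L,
                                             "CG")$level))
})

test_that("region level equals the naive per-site loop on random fixtures", {
  set.seed(61)
  for (i in 1:10) {
    n <- 60
    calls <- mk_calls(sample(c("chr1", "chr2"), n, replace = TRUE),
                      sample(1:1000, n), rbinom(n, 20, 0.4), 20L,
                      context = sample(c("CG", "CHG", "CHH"), n,
                                       replace = TRUE))
    start <- sample(0:500, 1); end <- start + sample(100:500, 1)
    ctx <- sample(c("CG", "CHG", "CHH"), 1)
    expect_equal(region_methylation_level(calls, "chr1", start, end,
                                          ctx)$level,
                 region_level_brute(calls, "chr1", start, end, ctx))
  }
})

test_that("min_total excludes low-coverage sites", {
  calls <- mk_calls("chr1", c(10L, 20L), c(1L, 5L), c(2L, 10L))
  all_sites <- region_methylation_level(calls, "chr1", 0L, 100L, "CG")
  expect_equal(all_sites$level, 0.5)
  deep <- region_methylation_level(calls, "chr1", 0L, 100L, "CG",
                                   min_total = 5L)
  expect_equal(deep$level, 0.5)
  deeper <- region_methylation_level(calls, "chr1", 0L, 100L, "CG",
                                     min_total = 11L)
  expect_true(is.na(deeper$level))
})

test_that("fully methylated and unmethylated fixtures give exact 1 and 0 profiles", {
  feats <- fs_df("chr1", c(5000L, 9000L), c(7000L, 9800L), c("+", "-"),
                 c("fA", "fB"), "lncRNA")
  set.seed(67)
  pos <- sort(sample(2500:12500, 400))
  full <- mk_calls("chr1", pos, 15L, 15L)
  prof <- metagene_profile(full, feats, "CG")
  expect_true(all(prof$mean_level[prof$n_features > 0] == 1))
  none <- mk_calls("chr1", pos, 0L, 15L)
  prof0 <- metagene_profile(none, feats, "CG")
  expect_true(all(prof0$mean_level[prof0$n_features > 0] == 0))
  expect_error(metagene_profile(full, feats[0, ], "CG"), "empty")
})

test_that("reversing a feature's strand reverses its bin vector exactly", {
  set.seed(71)
  pos <- sort(sample(2500:9500, 300))
  calls <- mk_calls("chr1", pos, rbinom(300, 12, runif(300)), 12L)
  plus <- fs_df("chr1", 5000L, 7000L, "+", "f1", "lncRNA")
  minus <- fs_df("chr1", 5000L, 7000L, "-", "f1", "lncRNA")
  pp <- metagene_profile(calls, plus, "CG")
  pm <- metagene_profile(calls, minus, "CG")
  expect_identical(pm$mean_level, rev(pp$mean_level))
  expect_identical(pm$n_features, rev(pp$n_features))
})

test_that("minus-strand upstream signal comes from the genomic right flank", {
  # methylation only in [7000, 9000), i.e. genomically right of the body
  calls <- mk_calls("chr1", seq(7010L, 8990L, by = 50L), 10L, 10L)
  minus <- fs_df("chr1", 5000L, 7000L, "-", "f1", "lncRNA")
  prof <- metagene_profile(calls, minus, "CG")
  up <- prof[prof$region == "upstream", ]
  dn <- prof[prof$region == "downstream", ]
  expect_true(any(up$n_features > 0))
  expect_true(all(dn$n_features == 0))
  expect_true(all(up$mean_level[up$n_features > 0] == 1))
})

test_that("group comparison is a two-sided exact U test with NA exclusion", {
  res <- compare_group_methylation(rep(0.9, 10), rep(0.1, 10))
  expect_lt(res$pvalue, 0.01)
  same <- compare_group_methylation(c(0.3, 0.5, 0.7), c(0.3, 0.5, 0.7))
  expect_equal(same$pvalue, 1, tolerance = 1e-9)
  expect_message(compare_group_methylation(c(0.2, NA), c(0.4, 0.5)),
                 "excluded")
  expect_error(compare_group_methylation(c(NA_real_), c(0.4)), "empty")
})

test_that("DMR association builds the right 2x2 table per context and region", {
  feats <- fs_df("chr1", seq(0L, 39000L, by = 1000L),
                 seq(500L, 39500L, by = 1000L), "+",
                 sprintf("f%02d", 1:40), "lncRNA")
  de <- data.frame(feature_id = feats$feature_id,
                   direction = rep(c("up", "ns"), each = 20))
  # CHG DMRs over the bodies of 10 DE features and 2 non-DE features
  dmr_feats <- c(1:10, 21:22)
  dmrs <- data.frame(chrom = "chr1", start = feats$start[dmr_feats],
                     end = feats$end[dmr_feats], context = "CHG")
  res <- dmr_de_association(feats, dmrs, de, region = "body")
  expect_named(res, "CHG")
  expect_equal(as.vector(res$CHG$table),
               c(10, 2, 10, 18))  # DE&DMR, nonDE&DMR, DE&noDMR, nonDE&noDMR
  expect_equal(res$CHG$test$statistic,
               chi_square_2x2(matrix(c(10, 10, 2, 18), 2,
                                     byrow = TRUE))$statistic)

  # a DMR in the gap next to a feature flags it only under region = "flank"
  gap_dmr <- data.frame(chrom = "chr1", start = 600L, end = 900L,
                        context = "CG")
  body_res <- tryCatch(dmr_de_association(feats, gap_dmr, de, "body"),
                       error = function(e) e)
  expect_s3_class(body_res, "error")  # no body overlap -> zero marginal
  flank_res <- dmr_de_association(feats, gap_dmr, de, "flank")
  expect_true("f01" %in% flank_res$CG$flagged)

  # empty DMR set -> zero marginal -> error naming the context
  expect_error(dmr_de_association(feats, dmrs[0, ], de, "body"))
})
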