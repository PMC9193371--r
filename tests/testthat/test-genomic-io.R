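# Format boundaries: GFF3 coordinate conventions, validation, round-trips,
# and the tabular readers.

write_lines_tmp <- function(lines) {
  f <- withr::local_tempfile(fileext = ".txt", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("GFF3 coordinates convert to 0-based half-open and exons are counted", {
  f <- write_lines_tmp(c(
    "##gff-version 3",
    "chr1\t.\tgene\t101\t200\t.\t+\t.\tID=g1",
    "chr1\t.\texon\t101\t150\t.\t+\t.\tParent=g1",
    "chr1\t.\texon\t151\t180\t.\t+\t.\tParent=g1",
    "chr1\t.\texon\t181\t200\t.\t+\t.\tParent=g1",
    "chr1\t.\tlnc_RNA\t501\t900\t.\t-\t.\tID=l1"))
  fs <- read_gff(f)
  g1 <- fs[fs$feature_id == "g1", ]
  expect_equal(g1$start, 100L)
  expect_equal(g1$end, 200L)
  expect_equal(g1$strand, "+")
  expect_equal(g1$exon_count, 3L)
  expect_equal(fs$feature_class[fs$feature_id == "l1"], "lncRNA")
})

test_that("GFF3 reader rejects malformed records and skips unknown types", {
  bad <- write_lines_tmp(c("chr1\t.\tgene\t101\t200\t.\t+\t.")) # 8 fields
  expect_error(read_gff(bad), "line 1")
  rev <- write_lines_tmp(c("chr1\t.\tgene\t300\t200\t.\t+\t.\tID=g1"))
  expect_error(read_gff(rev), "end < start")
  skip <- write_lines_tmp(c(
    "chr1\t.\tgene\t101\t200\t.\t+\t.\tID=g1",
    "chr1\t.\trepeat_region\t1\t50\t.\t+\t.\tID=r1"))
  expect_message(fs <- read_gff(skip), "skipped 1")
  expect_equal(nrow(fs), 1L)
})

test_that("GFF3 write/read round-trip preserves coordinates and strands", {
  ann <- make_annotation(5, n_chrom = 1, chrom_len = 2e5, n_genes = 20,
                         n_lncrna = 12, n_circrna = 6, n_mirna = 5)
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff(ann$features, f)
  back <- read_gff(f)
  orig <- as.data.frame(ann$features)
  back <- as.data.frame(back)
  back <- back[match(orig$feature_id, back$feature_id), ]
  expect_identical(back$start, as.integer(orig$start))
  expect_identical(back$end, as.integer(orig$end))
  expect_identical(back$strand, orig$strand)
  expect_identical(back$feature_class, orig$feature_class)
})

test_that("feature_set enforces its invariants", {
  expect_error(feature_set(fs_df("chr1", 100, 100, "+", "a")), "start >= end")
  expect_error(feature_set(rbind(fs_df("chr1", 0, 10, "+", "a"),
                                 fs_df("chr1", 5, 20, "+", "a"))),
               "duplicate")
  expect_error(feature_set(fs_df("chr1", 0, 10, "+", "a", class = "tRNA")),
               "unknown feature_class")
  exons <- data.frame(parent_id = "a", chrom = "chr1", start = 5L,
                      end = 30L, strand = "+")
  expect_error(feature_set(fs_df("chr1", 0, 10, "+", "a"), exons),
               "outside its parent")
})

test_that("expression reader validates values, samples and duplicates", {
  gm <- c(s1 = "temperate", s2 = "tropical")
  ok <- write_lines_tmp(c("feature_id\ts1\ts2", "f1\t1.5\t0", "f2\t2\t3"))
  em <- read_expression_tsv(ok, gm)
  expect_equal(dim(em), c(2L, 2L))
  expect_equal(unname(expr_groups(em)), c("temperate", "tropical"))

  dup <- write_lines_tmp(c("feature_id\ts1\ts2", "f1\t1\t2", "f1\t3\t4"))
  expect_error(read_expression_tsv(dup, gm), "duplicate")
  neg <- write_lines_tmp(c("feature_id\ts1\ts2", "f1\t-1.0\t2"))
  expect_error(read_expression_tsv(neg, gm), "negative")
  expect_error(read_expression_tsv(ok, gm["s1"]), "without group label")
})

test_that("target table collapses duplicates and rejects unknown classes", {
  f <- write_lines_tmp(c("miRNA_id\ttarget_id\ttarget_class",
                         "m1\tg1\tmRNA", "m1\tg1\tmRNA", "m1\tl1\tlncRNA"))
  tm <- read_target_table(f)
  expect_equal(nrow(tm), 2L)
  expect_setequal(tm$target_id[tm$miRNA_id == "m1"], c("g1", "l1"))

  bad <- write_lines_tmp(c("miRNA_id\ttarget_id\ttarget_class",
                           "m1\tt1\ttRNA"))
  expect_error(read_target_table(bad), "unknown target_class")
})

test_that("methylation reader enforces counts and context vocabulary", {
  f <- write_lines_tmp(c("chrom\tpos\tstrand\tmeth_count\tunmeth_count\tcontext",
                         "chr1\t10\t+\t3\t7\tCG", "chr1\t20\t-\t0\t5\tCHH"))
  calls <- read_methylation_tsv(f)
  expect_equal(calls$total_count, c(10L, 5L))
  zero <- write_lines_tmp(c("chrom\tpos\tstrand\tmeth_count\tunmeth_count\tcontext",
                            "chr1\t10\t+\t0\t0\tCG"))
  expect_error(read_methylation_tsv(zero), "zero total")
  bad <- write_lines_tmp(c("chrom\tpos\tstrand\tmeth_count\tunmeth_count\tcontext",
                           "chr1\t10\t+\t1\t1\tCHGG"))
  expect_error(read_methylation_tsv(bad), "context")
})

test_that("network edge-TSV round-trips node and edge sets exactly", {
  net <- list(
    nodes = data.frame(id = c("l1", "g1", "m1"),
                       class = c("lncRNA", "mRNA", "miRNA"),
                       de_direction = c("up", "ns", "ns")),
    edges = data.frame(from = c("l1", "m1"), to = c("g1", "g1"),
                       edge_type = c("ceRNA", "miRNA_target")))
  f <- file.path(withr::local_tempdir(), "net.tsv")
  write_network(net, f, "tsv")
  back <- read_network_edges(f)
  expect_equal(back$edges[order(back$edges$from), ],
               net$edges[order(net$edges$from), ], ignore_attr = TRUE)
  expect_equal(back$nodes[order(back$nodes$id), ],
               net$nodes[order(net$nodes$id), ], ignore_attr = TRUE)

  # empty network still yields a valid header-only file
  empty <- list(nodes = net$nodes[0, ], edges = net$edges[0, ])
  f2 <- file.path(withr::local_tempdir(), "empty.tsv")
  write_network(empty, f2, "tsv")
  expect_equal(nrow(read_network_edges(f2)$edges), 0L)

  sif <- file.path(withr::local_tempdir(), "net.sif")
  write_network(net, sif, "sif")
  expect_equal(length(readLines(sif)), 2L)
  expect_error(write_network(net, f, "xml"), "arg")
})

test_that("window and DMR readers validate geometry", {
  f <- write_lines_tmp(c("chrom\tstart\tend\tfst\tpi_a\tpi_b",
                         "chr1\t0\t20000\t0.1\t0.004\t0.005"))
  w <- read_window_stats(f)
  expect_equal(w$fst, 0.1)
  bad <- write_lines_tmp(c("chrom\tstart\tend\tfst\tpi_a\tpi_b",
                           "chr1\t100\t50\t0.1\t0.004\t0.005"))
  expect_error(read_window_stats(bad), "start >= end")

  b <- write_lines_tmp(c("chr1\t100\t500\tCHG"))
  d <- read_dmr_bed(b)
  expect_equal(d$context, "CHG")
  expect_equal(d$start, 100L)
})
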