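# ceRNA candidate enumeration, scoring, and network assembly.

# target map where L and G share m1..m6 out of 10 mapped miRNAs
shared6_map <- function() {
  target_map(data.frame(
    miRNA_id = c(rep(paste0("m", 1:6), 2), paste0("m", 7:10)),
    target_id = c(rep("L", 6), rep("G", 6), rep("other", 4)),
    target_class = c(rep("lncRNA", 6), rep("mRNA", 6), rep("mRNA", 4))))
}

test_that("candidate enumeration inverts the map and applies the strict k gate", {
  pairs <- enumerate_candidate_pairs(shared6_map())
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$k, 6L)
  expect_equal(pairs$K, 6L)
  expect_equal(pairs$n, 6L)
  expect_equal(pairs$N, 10L)
  expect_setequal(strsplit(pairs$shared_mirnas, ",")[[1]], paste0("m", 1:6))

  # k = 5 is not emitted ("greater than 5" is strict)
  tm5 <- target_map(data.frame(
    miRNA_id = rep(paste0("m", 1:5), 2),
    target_id = c(rep("L", 5), rep("G", 5)),
    target_class = c(rep("lncRNA", 5), rep("mRNA", 5))))
  expect_equal(nrow(enumerate_candidate_pairs(tm5)), 0L)

  # class gate: mRNA-mRNA pairs excluded by default, admitted on request
  tmm <- target_map(data.frame(
    miRNA_id = rep(paste0("m", 1:6), 2),
    target_id = c(rep("G1", 6), rep("G2", 6)),
    target_class = "mRNA"))
  expect_equal(nrow(enumerate_candidate_pairs(tmm)), 0L)
  expect_equal(nrow(enumerate_candidate_pairs(
    tmm, pair_classes = list(c("mRNA", "mRNA")))), 1L)
})

test_that("pair scoring combines hypergeometric, FDR and correlation gates", {
  tm <- target_map(data.frame(
    miRNA_id = c(rep(paste0("m", 1:6), 2), paste0("m", 7:10)),
    target_id = c(rep("L", 6), rep("G", 6), rep("X", 4)),
    target_class = c(rep("lncRNA", 6), rep("mRNA", 6), rep("mRNA", 4))))
  pairs <- enumerate_candidate_pairs(tm)
  x <- c(1, 5, 2, 8, 4, 9, 3, 7, 6, 10)
  grp <- stats::setNames(rep("g", 10), paste0("s", 1:10))
  mk_expr <- function(...) {
    m <- rbind(...)
    colnames(m) <- paste0("s", 1:10)
    expression_matrix(m, grp)
  }
  expr <- mk_expr(L = x, G = 2 * x, X = rev(x))
  scored <- score_cerna_pairs(pairs, expr)
  expect_equal(scored$p_hyper, 1 / 210, tolerance = 1e-12)
  expect_equal(scored$r, 1)
  expect_true(scored$passes)

  # correlation gate: same map but imperfect expression
  noisy <- mk_expr(L = x, G = x + c(2, -2, 1, -1, 2, -2, 1, -1, 2, -2),
                   X = rev(x))
  scored2 <- score_cerna_pairs(pairs, noisy)
  expect_lt(abs(scored2$r), 0.99)
  expect_false(scored2$passes)
  expect_equal(scored2$fail_reason, "threshold")

  # missing expression marks the pair failed, not dropped
  part <- mk_expr(L = x)
  scored3 <- score_cerna_pairs(pairs, part)
  expect_equal(nrow(scored3), 1L)
  expect_false(scored3$passes)
  expect_match(scored3$fail_reason, "missing")
})

test_that("q-values dominate p-values and respect family shrinkage", {
  ann <- make_annotation(3, n_chrom = 1, chrom_len = 5e5, n_genes = 60,
                         n_lncrna = 20, n_circrna = 10, n_mirna = 25)
  tm <- simulate_target_map(ann, n_true_pairs = 8, n_decoy_pairs = 20,
                            seed = 9)
  pairs <- enumerate_candidate_pairs(tm$map)
  ex <- simulate_expression(ann, cerna_pairs = tm$truth$true_pairs[1:2],
                            seed = 9)
  scored <- score_cerna_pairs(pairs, ex$expr)
  expect_true(all(scored$q_hyper >= scored$p_hyper - 1e-15))
  # removing a miRNA never increases k
  tm_small <- tm$map[tm$map$miRNA_id != tm$map$miRNA_id[1], , drop = FALSE]
  pairs_small <- enumerate_candidate_pairs(target_map(tm_small))
  key <- paste(pairs$id_a, pairs$id_b)
  key_s <- paste(pairs_small$id_a, pairs_small$id_b)
  common <- intersect(key, key_s)
  expect_true(all(pairs_small$k[match(common, key_s)] <=
                    pairs$k[match(common, key)]))
})

test_that("network assembly matches the hand-counted example", {
  tm <- shared6_map()
  pairs <- enumerate_candidate_pairs(tm)
  m <- rbind(L = as.numeric(1:10), G = as.numeric(2 * (1:10)))
  colnames(m) <- paste0("s", 1:10)
  expr <- expression_matrix(m, stats::setNames(rep("g", 10), colnames(m)))
  scored <- score_cerna_pairs(pairs, expr)
  de <- data.frame(feature_id = c("G", "L"), direction = c("up", "ns"))
  net <- build_cerna_network(scored, tm, de_flags = de)
  # 2 RNA nodes + 6 shared miRNA nodes; 1 ceRNA edge + 12 miRNA-target edges
  expect_equal(nrow(net$nodes), 8L)
  expect_equal(sum(net$edges$edge_type == "ceRNA"), 1L)
  expect_equal(sum(net$edges$edge_type == "miRNA_target"), 12L)
  expect_equal(net$nodes$de_direction[net$nodes$id == "G"], "up")

  # empty scored set -> valid empty network
  none <- scored; none$passes <- FALSE
  net0 <- build_cerna_network(none, tm)
  expect_equal(nrow(net0$nodes), 0L)
  expect_equal(nrow(net0$edges), 0L)
})

test_that("network assembly is deterministic and de-duplicates shared nodes", {
  ann <- make_annotation(5, n_chrom = 1, chrom_len = 5e5, n_genes = 60,
                         n_lncrna = 20, n_circrna = 10, n_mirna = 25)
  tm <- simulate_target_map(ann, n_true_pairs = 6, n_decoy_pairs = 10,
                            seed = 5)
  ex <- simulate_expression(ann, design = c(a = 5L, b = 5L),
                            cerna_pairs = tm$truth$true_pairs, seed = 5)
  n1 <- cerna(tm$map, ex$expr)
  n2 <- cerna(tm$map, ex$expr)
  expect_identical(n1$nodes, n2$nodes)
  expect_identical(n1$edges, n2$edges)
  expect_false(anyDuplicated(n1$nodes$id) > 0)
  expect_false(anyDuplicated(paste(n1$edges$from, n1$edges$to,
                                   n1$edges$edge_type)) > 0)
  expect_gte(sum(n1$pairs$passes, na.rm = TRUE), 5)
})

test_that("DE subnetwork keeps only edges with a DE mRNA endpoint", {
  tm <- shared6_map()
  pairs <- enumerate_candidate_pairs(tm)
  m <- rbind(L = as.numeric(1:10), G = as.numeric(2 * (1:10)))
  colnames(m) <- paste0("s", 1:10)
  expr <- expression_matrix(m, stats::setNames(rep("g", 10), colnames(m)))
  scored <- score_cerna_pairs(pairs, expr)
  net <- build_cerna_network(scored, tm)

  de_yes <- data.frame(feature_id = "G", log2FC = 2.5, fdr = 0.001)
  sub <- extract_de_subnetwork(net, de_yes)
  expect_equal(sum(sub$edges$edge_type == "ceRNA"), 1L)
  expect_equal(nrow(sub$nodes), 8L)

  # boundary: log2FC exactly 1.0 is not DE (strict)
  de_no <- data.frame(feature_id = "G", log2FC = 1.0, fdr = 0.001)
  sub0 <- extract_de_subnetwork(net, de_no)
  expect_equal(nrow(sub0$edges), 0L)
  expect_equal(nrow(sub0$nodes), 0L)
})
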