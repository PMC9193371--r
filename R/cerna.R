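# ceRNA network construction: shared-MRE hypergeometric test, expression
# correlation gating, FDR over the candidate family, and network assembly.
#
# Two RNAs compete for the same miRNAs when they carry common miRNA
# response elements; here the MRE relation is the miRNA -> target map, and
# a candidate pair is scored by (1) the number of shared miRNAs k, (2) the
# upper-tail hypergeometric probability of sharing that many out of N
# mapped miRNAs, with BH correction across all candidates, and (3) the
# Pearson correlation of the two expression profiles.

DEFAULT_PAIR_CLASSES <- list(c("lncRNA", "mRNA"), c("circRNA", "mRNA"))

.pair_class_keys <- function(pair_classes) {
  vapply(pair_classes,
         function(p) paste(sort(p), collapse = "|"), "")
}

#' Enumerate candidate ceRNA pairs
#'
#' Inverts the target map to a target -> miRNA-set relation and emits every
#' unordered pair of targets whose class combination is admitted by
#' `pair_classes` and whose shared-miRNA count `k` is strictly greater than
#' `min_shared`. For each pair, `K` and `n` are the miRNA counts of the two
#' members and `N` is the number of distinct miRNAs in the map (the map is
#' the universe of observable MREs).
#'
#' @param target_map a [target_map] data.frame.
#' @param pair_classes list of admissible unordered class pairs (default
#'   lncRNA-mRNA and circRNA-mRNA).
#' @param min_shared strict lower bound on k (default 5, i.e. k > 5).
#' @return data.frame of pair skeletons: ids, classes, `k`, `K`, `n`, `N`,
#'   and a comma-separated `shared_mirnas` column.
#' @export
enumerate_candidate_pairs <- function(target_map,
                                      pair_classes = DEFAULT_PAIR_CLASSES,
                                      min_shared = 5L) {
  .assert(nrow(target_map) > 0L, "empty target map")
  mirnas <- sort(unique(target_map$miRNA_id))
  targets <- unique(target_map[c("target_id", "target_class")])
  targets <- targets[order(targets$target_id), , drop = FALSE]
  N <- length(mirnas)
  empty <- data.frame(id_a = character(), class_a = character(),
                      id_b = character(), class_b = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), shared_mirnas = character())
  if (nrow(targets) < 2L) return(empty)

  inc <- matrix(FALSE, nrow(targets), N,
                dimnames = list(targets$target_id, mirnas))
  inc[cbind(match(target_map$target_id, targets$target_id),
            match(target_map$miRNA_id, mirnas))] <- TRUE
  shared <- tcrossprod(inc * 1L)
  deg <- rowSums(inc)

  keys <- .pair_class_keys(pair_classes)
  idx <- which(upper.tri(shared) & shared > min_shared, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(empty)
  cls_a <- targets$target_class[idx[, 1]]
  cls_b <- targets$target_class[idx[, 2]]
  admit <- vapply(seq_len(nrow(idx)), function(i)
    paste(sort(c(cls_a[i], cls_b[i])), collapse = "|") %in% keys, TRUE)
  idx <- idx[admit, , drop = FALSE]
  if (nrow(idx) == 0L) return(empty)

  shared_ids <- vapply(seq_len(nrow(idx)), function(i) {
    paste(mirnas[inc[idx[i, 1], ] & inc[idx[i, 2], ]], collapse = ",")
  }, "")
  out <- data.frame(
    id_a = targets$target_id[idx[, 1]],
    class_a = targets$target_class[idx[, 1]],
    id_b = targets$target_id[idx[, 2]],
    class_b = targets$target_class[idx[, 2]],
    k = as.integer(shared[idx]),
    K = as.integer(deg[idx[, 1]]),
    n = as.integer(deg[idx[, 2]]),
    N = N,
    shared_mirnas = shared_ids,
    stringsAsFactors = FALSE)
  out <- out[order(out$id_a, out$id_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Score candidate ceRNA pairs
#'
#' Adds to each enumerated pair the hypergeometric upper-tail probability
#' `p_hyper = P(X >= k)`, the BH-adjusted `q_hyper` computed over the whole
#' enumerated family, the Pearson correlation `r` of the two expression
#' profiles with its two-sided p-value `p_r`, and a `passes` flag:
#' `p_hyper < p_threshold`, `q_hyper < q_threshold`, `|r| > r_threshold`,
#' `p_r < pr_threshold` (the k gate is part of enumeration). A pair with a
#' missing or constant expression profile is marked failed with a reason,
#' never silently dropped.
#'
#' @param pairs output of [enumerate_candidate_pairs].
#' @param expr an [expression_matrix] holding every pair member (one
#'   harmonised matrix; its unit is whatever the caller normalised to).
#' @param p_threshold,q_threshold hypergeometric p/FDR cutoffs (default
#'   0.01).
#' @param r_threshold absolute-correlation cutoff (default 0.99).
#' @param pr_threshold correlation p-value cutoff (default 0.01).
#' @return The pairs with `p_hyper`, `q_hyper`, `r`, `p_r`, `passes`,
#'   `fail_reason` columns.
#' @export
score_cerna_pairs <- function(pairs, expr, p_threshold = 0.01,
                              q_threshold = 0.01, r_threshold = 0.99,
                              pr_threshold = 0.01) {
  if (nrow(pairs) == 0L) {
    pairs$p_hyper <- pairs$q_hyper <- pairs$r <- pairs$p_r <- numeric(0)
    pairs$passes <- logical(0); pairs$fail_reason <- character(0)
    return(pairs)
  }
  pairs$p_hyper <- vapply(seq_len(nrow(pairs)), function(i)
    hypergeom_sf(pairs$k[i], pairs$K[i], pairs$n[i], pairs$N[i]), 0)
  pairs$q_hyper <- bh_fdr(pairs$p_hyper)

  m <- unclass(expr)
  r <- p_r <- rep(NA_real_, nrow(pairs))
  reason <- rep("", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$id_a[i]; b <- pairs$id_b[i]
    if (!(a %in% rownames(m)) || !(b %in% rownames(m))) {
      reason[i] <- "missing expression profile"
      next
    }
    if (stats::sd(m[a, ]) == 0 || stats::sd(m[b, ]) == 0) {
      reason[i] <- "constant expression profile"
      next
    }
    pr <- pearson_r_p(m[a, ], m[b, ])
    r[i] <- pr$r; p_r[i] <- pr$pvalue
  }
  pairs$r <- r
  pairs$p_r <- p_r
  pairs$passes <- !is.na(r) &
    pairs$p_hyper < p_threshold & pairs$q_hyper < q_threshold &
    abs(r) > r_threshold & p_r < pr_threshold
  reason[reason == "" & !pairs$passes] <- "threshold"
  reason[pairs$passes] <- ""
  pairs$fail_reason <- reason
  pairs
}

#' Assemble the ceRNA network
#'
#' Nodes are the RNAs of all passing pairs plus their shared miRNAs; edges
#' are the undirected ceRNA edges plus the directed miRNA -> target edges
#' of the map restricted to included nodes. DE direction (when supplied) is
#' annotated on nodes. Node and edge ordering is deterministic.
#'
#' @param scored output of [score_cerna_pairs].
#' @param target_map a [target_map].
#' @param de_flags optional data.frame from [flag_differential].
#' @return An object of class `cerna_network` with `nodes`, `edges`,
#'   `pairs`.
#' @export
build_cerna_network <- function(scored, target_map, de_flags = NULL) {
  pass <- scored[isTRUE_v(scored$passes), , drop = FALSE]
  classes <- unique(rbind(
    data.frame(id = scored$id_a, class = scored$class_a),
    data.frame(id = scored$id_b, class = scored$class_b)))
  shared <- if (nrow(pass)) {
    sort(unique(unlist(strsplit(pass$shared_mirnas, ",", fixed = TRUE))))
  } else character()
  rna_ids <- sort(unique(c(pass$id_a, pass$id_b)))
  nodes <- rbind(
    data.frame(id = rna_ids,
               class = if (length(rna_ids))
                 classes$class[match(rna_ids, classes$id)] else character(),
               stringsAsFactors = FALSE),
    data.frame(id = shared,
               class = rep("miRNA", length(shared)),
               stringsAsFactors = FALSE))
  nodes$de_direction <- rep("ns", nrow(nodes))
  if (!is.null(de_flags) && nrow(nodes)) {
    hit <- match(nodes$id, de_flags$feature_id)
    nodes$de_direction[!is.na(hit)] <- de_flags$direction[hit[!is.na(hit)]]
  }
  ce_edges <- if (nrow(pass)) {
    swap <- pass$id_a > pass$id_b
    data.frame(from = ifelse(swap, pass$id_b, pass$id_a),
               to = ifelse(swap, pass$id_a, pass$id_b),
               edge_type = "ceRNA", k = pass$k, r = pass$r,
               q_hyper = pass$q_hyper, stringsAsFactors = FALSE)
  } else {
    data.frame(from = character(), to = character(), edge_type = character(),
               k = integer(), r = numeric(), q_hyper = numeric())
  }
  mt <- target_map[target_map$miRNA_id %in% shared &
                     target_map$target_id %in% rna_ids, , drop = FALSE]
  nmt <- nrow(mt)
  mt_edges <- data.frame(from = mt$miRNA_id, to = mt$target_id,
                         edge_type = rep("miRNA_target", nmt),
                         k = rep(NA_integer_, nmt), r = rep(NA_real_, nmt),
                         q_hyper = rep(NA_real_, nmt),
                         stringsAsFactors = FALSE)
  edges <- rbind(ce_edges, mt_edges)
  edges <- edges[order(edges$edge_type, edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, pairs = scored),
            class = "cerna_network")
}

isTRUE_v <- function(x) !is.na(x) & x

#' Construct a ceRNA network from a target map and expression
#'
#' One-call front end to the ceRNA stage: enumerates candidate pairs,
#' scores them, and assembles the network.
#'
#' @inheritParams enumerate_candidate_pairs
#' @inheritParams score_cerna_pairs
#' @param de_flags optional DE flags annotated on nodes.
#' @return A `cerna_network` (with the full scored pair table in `$pairs`).
#' @export
cerna <- function(target_map, expr, de_flags = NULL, min_shared = 5L,
                  p_threshold = 0.01, q_threshold = 0.01,
                  r_threshold = 0.99, pr_threshold = 0.01,
                  pair_classes = DEFAULT_PAIR_CLASSES) {
  pairs <- enumerate_candidate_pairs(target_map, pair_classes = pair_classes,
                                     min_shared = min_shared)
  scored <- score_cerna_pairs(pairs, expr, p_threshold = p_threshold,
                              q_threshold = q_threshold,
                              r_threshold = r_threshold,
                              pr_threshold = pr_threshold)
  net <- build_cerna_network(scored, target_map, de_flags = de_flags)
  net$params <- list(min_shared = min_shared, p_threshold = p_threshold,
                     q_threshold = q_threshold, r_threshold = r_threshold,
                     pr_threshold = pr_threshold)
  net
}

#' @export
print.cerna_network <- function(x, ...) {
  cat("<cerna_network>\n")
  cat(sprintf("  candidate pairs: %d (passing: %d)\n",
              nrow(x$pairs), sum(isTRUE_v(x$pairs$passes))))
  cat(sprintf("  nodes: %d (%s)\n", nrow(x$nodes),
              paste(sprintf("%s %d", names(table(x$nodes$class)),
                            table(x$nodes$class)), collapse = ", ")))
  cat(sprintf("  edges: %d ceRNA, %d miRNA-target\n",
              sum(x$edges$edge_type == "ceRNA"),
              sum(x$edges$edge_type == "miRNA_target")))
  invisible(x)
}

#' @export
summary.cerna_network <- function(object, ...) {
  p <- object$pairs
  out <- list(n_candidates = nrow(p),
              n_passing = sum(isTRUE_v(p$passes)),
              n_nodes = nrow(object$nodes),
              n_edges = nrow(object$edges),
              nodes_by_class = table(object$nodes$class))
  class(out) <- "summary.cerna_network"
  out
}

#' @export
print.summary.cerna_network <- function(x, ...) {
  cat(sprintf("ceRNA network: %d/%d candidate pairs pass; %d nodes, %d edges\n",
              x$n_passing, x$n_candidates, x$n_nodes, x$n_edges))
  print(x$nodes_by_class)
  invisible(x)
}

#' Plot a ceRNA network
#'
#' Simple force-directed drawing via igraph (if installed): RNA classes are
#' colour-coded, ceRNA edges solid, miRNA-target edges dashed.
#'
#' @param x a `cerna_network`.
#' @param ... passed to `igraph::plot.igraph`.
#' @export
plot.cerna_network <- function(x, ...) {
  .assert(requireNamespace("igraph", quietly = TRUE),
          "the igraph package is required for plotting")
  if (nrow(x$nodes) == 0L) {
    graphics::plot.new()
    graphics::title("empty ceRNA network")
    return(invisible(x))
  }
  g <- igraph::graph_from_data_frame(x$edges[c("from", "to", "edge_type")],
                                     directed = FALSE, vertices = x$nodes)
  pal <- c(mRNA = "grey70", lncRNA = "steelblue", circRNA = "darkorange",
           miRNA = "forestgreen")
  igraph::plot.igraph(
    g, vertex.color = pal[igraph::V(g)$class], vertex.size = 6,
    vertex.label.cex = 0.6,
    edge.lty = ifelse(igraph::E(g)$edge_type == "ceRNA", 1, 2), ...)
  invisible(x)
}

#' Extract the DE-mRNA ceRNA subnetwork
#'
#' Keeps the ceRNA edges with at least one differentially expressed mRNA
#' endpoint at the stated (strict) thresholds, plus the incident miRNA
#' nodes and miRNA-target edges.
#'
#' @param network a `cerna_network`.
#' @param de_stats data.frame with `feature_id`, `log2FC`, `fdr`.
#' @param lfc_threshold,fdr_threshold strict cutoffs (defaults 1.0, 0.01).
#' @return A `cerna_network` restricted to the DE subnetwork.
#' @export
extract_de_subnetwork <- function(network, de_stats, lfc_threshold = 1.0,
                                  fdr_threshold = 0.01) {
  flags <- flag_differential(de_stats, lfc_threshold, fdr_threshold)
  de_ids <- flags$feature_id[flags$direction != "ns"]
  mrna_ids <- network$nodes$id[network$nodes$class == "mRNA"]
  de_mrna <- intersect(de_ids, mrna_ids)
  ce <- network$edges[network$edges$edge_type == "ceRNA", , drop = FALSE]
  keep_ce <- ce$from %in% de_mrna | ce$to %in% de_mrna
  ce <- ce[keep_ce, , drop = FALSE]
  pairs <- network$pairs
  key_all <- paste(pmin(pairs$id_a, pairs$id_b),
                   pmax(pairs$id_a, pairs$id_b))
  pairs_kept <- pairs[key_all %in% paste(ce$from, ce$to) &
                        isTRUE_v(pairs$passes), , drop = FALSE]
  rna_ids <- unique(c(ce$from, ce$to))
  mirnas <- if (nrow(pairs_kept)) {
    sort(unique(unlist(strsplit(pairs_kept$shared_mirnas, ",", fixed = TRUE))))
  } else character()
  nodes <- network$nodes[network$nodes$id %in% c(rna_ids, mirnas), ,
                         drop = FALSE]
  mt <- network$edges[network$edges$edge_type == "miRNA_target" &
                        network$edges$from %in% mirnas &
                        network$edges$to %in% rna_ids, , drop = FALSE]
  edges <- rbind(ce, mt)
  rownames(edges) <- rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges, pairs = pairs_kept),
            class = "cerna_network")
}
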