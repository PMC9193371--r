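# End-to-end orchestration: fixture writing and the full analysis run.

DEFAULT_CONFIG <- list(
  # lncRNA filter
  min_len = 200, min_fpkm = 0.1, min_exons = 2,
  # DE thresholds
  lfc_threshold = 1.0, fdr_threshold = 0.05,
  # cis / trans targets
  cis_window_bp = 100000, trans_r_threshold = 0.9, trans_p_threshold = 0.01,
  # ceRNA
  min_shared = 5, p_threshold = 0.01, q_threshold = 0.01,
  r_threshold = 0.99, pr_threshold = 0.01,
  # selection scan
  fst_quantile = 0.95, ratio_quantile = 0.05,
  # methylation
  flank_bp = 2000, body_bins = 20, flank_bins = 20, min_total = 1
)

#' Validate a pipeline configuration
#'
#' Unknown keys are rejected and every threshold must lie in its documented
#' range; the merged (defaults + overrides) configuration is returned.
#'
#' @param config named list of overrides to [`DEFAULT_CONFIG`]'s keys.
#' @return Full validated configuration list.
#' @export
validate_run_config <- function(config = list()) {
  unknown <- setdiff(names(config), names(DEFAULT_CONFIG))
  .assert(length(unknown) == 0L, "validation error: unknown config key(s): %s",
          paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(DEFAULT_CONFIG, config)
  chk01 <- c("fdr_threshold", "trans_p_threshold", "p_threshold",
             "q_threshold", "pr_threshold", "fst_quantile", "ratio_quantile")
  for (k in chk01) {
    .assert(cfg[[k]] > 0 && cfg[[k]] <= 1,
            "validation error: %s must be in (0, 1]", k)
  }
  .assert(cfg$r_threshold >= 0 && cfg$r_threshold <= 1,
          "validation error: r_threshold must be in [0, 1]")
  .assert(cfg$trans_r_threshold >= 0 && cfg$trans_r_threshold <= 1,
          "validation error: trans_r_threshold must be in [0, 1]")
  for (k in c("min_shared", "min_exons", "min_total", "cis_window_bp",
              "flank_bp", "body_bins", "flank_bins", "min_len")) {
    .assert(cfg[[k]] >= 0, "validation error: %s must be non-negative", k)
  }
  cfg
}

#' Write a self-contained synthetic fixture directory
#'
#' Generates a fully coherent multi-omic fixture — annotation, expression,
#' analytic DE statistics, lncRNA candidate table, miRNA target map with
#' planted ceRNA pairs, per-sample methylation calls with planted DMRs, and
#' sliding-window FST/pi tables with planted sweeps — and writes it with a
#' ground-truth file (`truth.json`) and a manifest recording every seed and
#' parameter.
#'
#' @param dir output directory (created if absent).
#' @param seed master seed; sub-generators use fixed offsets from it.
#' @param n_genes,n_lncrna,n_circrna,n_mirna annotation sizes.
#' @param design named two-group sample design (default 3 temperate vs 2
#'   tropical).
#' @param n_true_pairs,n_decoy_pairs planted ceRNA pairs and decoys.
#' @param de_fraction planted DE fraction.
#' @param n_windows_per_chrom,sweeps_per_chrom selection-scan geometry.
#' @param dmr_n DMRs per methylation context.
#' @return The ground-truth list, invisibly.
#' @export
write_fixture <- function(dir, seed = 1L,
                          n_genes = 500L, n_lncrna = 150L,
                          n_circrna = 80L, n_mirna = 60L,
                          design = c(temperate = 3L, tropical = 2L),
                          n_true_pairs = 20L, n_decoy_pairs = 100L,
                          de_fraction = 0.1,
                          n_windows_per_chrom = 400L,
                          sweeps_per_chrom = 8L, dmr_n = 5L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ann <- make_annotation(seed, n_genes = n_genes, n_lncrna = n_lncrna,
                         n_circrna = n_circrna, n_mirna = n_mirna)
  tm <- simulate_target_map(ann, n_true_pairs = n_true_pairs,
                            n_decoy_pairs = n_decoy_pairs, seed = seed + 1L)
  ex <- simulate_expression(ann, design = design, de_fraction = de_fraction,
                            cerna_pairs = tm$truth$true_pairs[c("id_a", "id_b")],
                            seed = seed + 2L)
  fs <- ann$features

  # DMRs preferentially over DE lncRNA bodies so the DMR-DE association
  # stage has signal to find
  lnc_ids <- fs$feature_id[fs$feature_class == "lncRNA"]
  de_lnc <- intersect(names(ex$truth$planted_de), lnc_ids)
  n_dmr_feats <- dmr_n * 3L
  dmr_feats <- withr::with_seed(seed + 10L, {
    pick_de <- utils::head(sample(de_lnc), ceiling(n_dmr_feats / 2))
    rest <- sample(setdiff(lnc_ids, pick_de))
    utils::head(c(pick_de, rest), n_dmr_feats)
  })
  meth <- simulate_methylation(ann, design = design, dmr_n = dmr_n,
                               dmr_feature_ids = dmr_feats,
                               seed = seed + 3L)

  chroms <- unique(fs$chrom)
  wins <- list(); wtruth <- list()
  for (i in seq_along(chroms)) {
    w <- simulate_window_stats(n_windows = n_windows_per_chrom,
                               sweep_count = sweeps_per_chrom,
                               chrom = chroms[i], seed = seed + 4L + i)
    wins[[i]] <- w$windows
    wtruth[[chroms[i]]] <- w$truth
  }
  windows <- do.call(rbind, wins)

  # lncRNA candidate table: every annotated lncRNA (all-pass) plus decoy
  # candidates failing exactly one criterion each
  lnc <- fs[fs$feature_class == "lncRNA", , drop = FALSE]
  cand <- data.frame(feature_id = lnc$feature_id, chrom = lnc$chrom,
                     start = lnc$start, end = lnc$end, strand = lnc$strand,
                     length_nt = lnc$end - lnc$start,
                     mean_fpkm = rowMeans(unclass(ex$expr)[lnc$feature_id, ,
                                                           drop = FALSE]),
                     exon_count = lnc$exon_count,
                     cpc2 = TRUE, cnci = TRUE, pfam = TRUE, cpat = TRUE,
                     stringsAsFactors = FALSE)
  decoy <- withr::with_seed(seed + 11L, {
    n_d <- 40L
    fail <- rep(c("length", "fpkm", "exons", "coding"), length.out = n_d)
    data.frame(feature_id = sprintf("cand_fail_%02d", seq_len(n_d)),
               chrom = sample(chroms, n_d, replace = TRUE),
               start = st <- sample.int(9e5, n_d),
               end = st + ifelse(fail == "length", 150L, 800L),
               strand = sample(c("+", "-"), n_d, replace = TRUE),
               length_nt = ifelse(fail == "length", 150L, 800L),
               mean_fpkm = ifelse(fail == "fpkm", 0.01, 5),
               exon_count = ifelse(fail == "exons", 1L, 3L),
               cpc2 = TRUE, cnci = TRUE, pfam = TRUE,
               cpat = fail != "coding", stringsAsFactors = FALSE)
  })

  write_gff(fs, file.path(dir, "annotation.gff3"))
  write_expression_tsv(ex$expr, file.path(dir, "expression.tsv"))
  write_tsv_commented(ex$de_stats, file.path(dir, "de_stats.tsv"))
  write_tsv_commented(as.data.frame(tm$map), file.path(dir, "targets.tsv"))
  write_tsv_commented(rbind(cand, decoy),
                      file.path(dir, "lncrna_candidates.tsv"))
  for (s in names(meth$calls)) {
    write_methylation_tsv(meth$calls[[s]],
                          file.path(dir, sprintf("meth_%s.tsv", s)))
  }
  write_dmr_bed(meth$dmrs, file.path(dir, "dmrs.bed"))
  write_tsv_commented(windows, file.path(dir, "windows.tsv"))

  truth <- list(
    lncrna_classes = as.list(ann$truth$lncrna_classes),
    planted_de = as.list(ex$truth$planted_de),
    planted_specific = ex$truth$planted_specific,
    cerna_true_pairs = tm$truth$true_pairs,
    cerna_decoy_pairs = tm$truth$decoy_pairs,
    dmr_features = meth$truth$dmr_features,
    retained_candidates = cand$feature_id,
    sweep_windows = wtruth
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package_version = as.character(utils::packageVersion("ecoRNA")),
    seed = seed,
    sub_seeds = list(annotation = seed, target_map = seed + 1L,
                     expression = seed + 2L, methylation = seed + 3L,
                     windows = seed + 5L),
    design = as.list(design),
    samples = as.list(expr_groups(ex$expr)),
    params = list(n_genes = n_genes, n_lncrna = n_lncrna,
                  n_circrna = n_circrna, n_mirna = n_mirna,
                  n_true_pairs = n_true_pairs,
                  n_decoy_pairs = n_decoy_pairs,
                  de_fraction = de_fraction,
                  n_windows_per_chrom = n_windows_per_chrom,
                  sweeps_per_chrom = sweeps_per_chrom, dmr_n = dmr_n)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(truth)
}

#' Run the full analysis pipeline on a fixture directory
#'
#' Executes the stages in dependency order — lncRNA filtering and
#' classification, specificity and DE flagging, ecotype-specific circRNAs,
#' cis/trans targets of DE lncRNAs, ceRNA network construction and DE
#' subnetwork extraction, selection-window classification with feature
#' overlap, and methylation group comparison with DMR-DE association —
#' writing one result table per stage plus a machine-readable
#' `summary.json`. Every output carries a header comment with the package
#' version, a config fingerprint and the fixture seeds; outputs contain no
#' timestamps, so identical reruns are byte-identical. Any stage failure
#' aborts with the stage name.
#'
#' @param fixture_dir directory produced by [write_fixture] (or
#'   equivalently structured real data).
#' @param out_dir output directory.
#' @param config named list of threshold overrides (see
#'   [validate_run_config]).
#' @return The summary list, invisibly.
#' @export
run_pipeline <- function(fixture_dir, out_dir, config = list()) {
  cfg <- validate_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- jsonlite::read_json(file.path(fixture_dir, "manifest.json"))
  hdr <- c(sprintf("ecoRNA %s", manifest$package_version %||% "?"),
           sprintf("config_hash: %s",
                   fnv1a(jsonlite::toJSON(cfg, auto_unbox = TRUE))),
           sprintf("fixture_seed: %s", manifest$seed %||% "?"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  summary <- list(config = cfg)

  ann <- stage("read-annotation",
               read_gff(file.path(fixture_dir, "annotation.gff3")))
  group_map <- unlist(manifest$samples)
  expr <- stage("read-expression",
                read_expression_tsv(file.path(fixture_dir, "expression.tsv"),
                                    group_map))
  de_stats <- stage("read-de-stats",
                    read_tsv_plain(file.path(fixture_dir, "de_stats.tsv")))
  tmap <- stage("read-targets",
                read_target_table(file.path(fixture_dir, "targets.tsv")))
  windows <- stage("read-windows",
                   read_window_stats(file.path(fixture_dir, "windows.tsv")))
  dmrs <- stage("read-dmrs", read_dmr_bed(file.path(fixture_dir, "dmrs.bed")))
  cand <- stage("read-candidates",
                read_tsv_plain(file.path(fixture_dir,
                                         "lncrna_candidates.tsv")))
  meth_files <- list.files(fixture_dir, "^meth_.*\\.tsv$", full.names = TRUE)
  calls <- stage("read-methylation",
                 lapply(meth_files, read_methylation_tsv))
  names(calls) <- sub("^meth_(.*)\\.tsv$", "\\1", basename(meth_files))

  groups <- unique(unname(group_map))
  genes <- ann[ann$feature_class == "gene", , drop = FALSE]
  lnc <- ann[ann$feature_class == "lncRNA", , drop = FALSE]
  circ_ids <- ann$feature_id[ann$feature_class == "circRNA"]

  # -- lncRNA filter + positional classification -------------------------
  retained <- stage("lncrna-filter", suppressMessages(
    filter_lncrna_candidates(cand, min_len = cfg$min_len,
                             min_fpkm = cfg$min_fpkm,
                             min_exons = cfg$min_exons)))
  lnc_kept <- lnc[lnc$feature_id %in% retained$feature_id, , drop = FALSE]
  cls <- stage("lncrna-classify",
               classify_lncrna(lnc_kept, ann,
                               gene_exons = feature_exons(ann)))
  write_tsv_commented(cls, file.path(out_dir, "lncrna_classes.tsv"), hdr)
  summary$lncrna <- list(candidates = nrow(cand), retained = nrow(retained),
                         classes = as.list(table(cls$class)))

  # -- specificity + DE flags + ecotype-specific circRNAs ----------------
  spec <- stage("specificity", specificity_table(expr))
  write_tsv_commented(spec, file.path(out_dir, "specificity.tsv"), hdr)
  flags <- stage("de-flag", flag_differential(de_stats,
                                              cfg$lfc_threshold,
                                              cfg$fdr_threshold))
  write_tsv_commented(flags, file.path(out_dir, "de_flags.tsv"), hdr)
  especific <- stage("ecotype-specific",
                     ecotype_specific_features(expr[circ_ids, , drop = FALSE],
                                               groups[1], groups[2],
                                               groups = group_map))
  de_by_class <- function(class) {
    ids <- ann$feature_id[ann$feature_class == class]
    sum(flags$direction != "ns" & flags$feature_id %in% ids)
  }
  summary$expression <- list(
    de_gene = de_by_class("gene"), de_lncRNA = de_by_class("lncRNA"),
    de_circRNA = de_by_class("circRNA"), de_miRNA = de_by_class("miRNA"),
    specific_circ_a = length(especific$a_specific),
    specific_circ_b = length(especific$b_specific),
    mean_tau = mean(spec$tau, na.rm = TRUE))

  # -- cis/trans targets of DE lncRNAs -----------------------------------
  de_ids <- flags$feature_id[flags$direction != "ns"]
  de_lnc <- lnc[lnc$feature_id %in% de_ids, , drop = FALSE]
  cis <- stage("cis-targets",
               cis_targets(de_lnc, genes, window_bp = cfg$cis_window_bp))
  trans <- stage("trans-targets", suppressMessages(
    if (nrow(de_lnc)) {
      trans_targets(expr[de_lnc$feature_id, , drop = FALSE],
                    expr[genes$feature_id, , drop = FALSE],
                    r_threshold = cfg$trans_r_threshold,
                    p_threshold = cfg$trans_p_threshold)
    } else {
      data.frame(regulator_id = character(), target_id = character(),
                 mode = character(), r = numeric(), pvalue = numeric())
    }))
  write_tsv_commented(cis, file.path(out_dir, "cis_targets.tsv"), hdr)
  write_tsv_commented(trans, file.path(out_dir, "trans_targets.tsv"), hdr)
  summary$targets <- list(de_lncrna = nrow(de_lnc), cis_pairs = nrow(cis),
                          trans_pairs = nrow(trans))

  # -- ceRNA network ------------------------------------------------------
  net <- stage("cerna", suppressWarnings(
    cerna(tmap, expr, de_flags = flags, min_shared = cfg$min_shared,
          p_threshold = cfg$p_threshold, q_threshold = cfg$q_threshold,
          r_threshold = cfg$r_threshold, pr_threshold = cfg$pr_threshold)))
  sub <- stage("cerna-de-subnetwork",
               extract_de_subnetwork(net, de_stats,
                                     lfc_threshold = cfg$lfc_threshold,
                                     fdr_threshold = 0.01))
  write_tsv_commented(net$pairs[setdiff(names(net$pairs), "shared_mirnas")],
                      file.path(out_dir, "cerna_pairs.tsv"), hdr)
  write_network(net, file.path(out_dir, "cerna_network.tsv"), "tsv")
  write_network(sub, file.path(out_dir, "cerna_de_subnetwork.tsv"), "tsv")
  summary$cerna <- list(candidates = nrow(net$pairs),
                        passing = sum(isTRUE_v(net$pairs$passes)),
                        nodes = nrow(net$nodes), edges = nrow(net$edges),
                        de_sub_nodes = nrow(sub$nodes),
                        de_sub_edges = nrow(sub$edges))

  # -- selection scan -----------------------------------------------------
  calls_sel <- stage("selection",
                     classify_selected(windows, cfg$fst_quantile,
                                       cfg$ratio_quantile))
  ovl <- stage("selection-overlap", overlap_selected_features(ann, calls_sel))
  write_tsv_commented(calls_sel, file.path(out_dir, "selection_calls.tsv"),
                      c(hdr, sprintf("thresholds: %s",
                                     paste(sprintf("%s=%.6g",
                                                   names(attr(calls_sel, "thresholds")),
                                                   attr(calls_sel, "thresholds")),
                                           collapse = " "))))
  write_tsv_commented(ovl$table, file.path(out_dir, "selected_features.tsv"),
                      hdr)
  sel_counts <- lapply(ovl$per_class, length)
  prop_test <- stage("selection-proportions", {
    n_gene <- sum(ann$feature_class == "gene")
    n_lnc <- sum(ann$feature_class == "lncRNA")
    compare_selected_proportions(length(ovl$per_class$gene %||% character()),
                                 n_gene,
                                 length(ovl$per_class$lncRNA %||% character()),
                                 n_lnc)
  })
  summary$selection <- list(
    windows = nrow(windows),
    selected_pop_a = sum(calls_sel$selected_in == "pop_a"),
    selected_pop_b = sum(calls_sel$selected_in == "pop_b"),
    selected_features = sel_counts,
    gene_vs_lncrna_chisq = unname(prop_test$statistic),
    gene_vs_lncrna_p = prop_test$pvalue)

  # -- methylation --------------------------------------------------------
  grp_of <- group_map[names(calls)]
  pooled <- lapply(groups, function(g)
    do.call(rbind, calls[grp_of == g]))
  names(pooled) <- groups
  meth_tests <- list()
  for (ctx in c("CG", "CHG", "CHH")) {
    lev <- lapply(pooled, function(p) suppressMessages(
      feature_methylation_levels(p, lnc, ctx, region = "body",
                                 flank_bp = cfg$flank_bp,
                                 min_total = cfg$min_total)))
    tst <- stage(paste0("methylation-", ctx),
                 suppressMessages(compare_group_methylation(lev[[1]],
                                                            lev[[2]])))
    meth_tests[[ctx]] <- list(
      mean_a = mean(lev[[1]], na.rm = TRUE),
      mean_b = mean(lev[[2]], na.rm = TRUE),
      p = tst$pvalue)
  }
  assoc <- stage("dmr-de-association", {
    lnc_flags <- flags[flags$feature_id %in% lnc$feature_id, , drop = FALSE]
    dmr_de_association(lnc, dmrs, lnc_flags, region = "body",
                       flank_bp = cfg$flank_bp)
  })
  summary$methylation <- list(
    group_tests = meth_tests,
    dmr_association = lapply(assoc, function(a)
      list(chisq = unname(a$test$statistic), p = a$test$pvalue,
           table = as.list(as.vector(a$table)))))

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(summary)
}
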