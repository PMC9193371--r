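# lncRNA candidate filtering, positional classification and
# cross-accession merging.

#' Filter lncRNA candidates
#'
#' A candidate survives iff it is called non-coding by all four
#' coding-potential tools (CPC2, CNCI, Pfam-scan, CPAT; the verdicts are
#' inputs, the tools are not run here), its length is at least `min_len`
#' nt, its mean abundance is at least `min_fpkm`, and it has at least
#' `min_exons` exons. The multi-exon rule defaults to `min_exons = 2`
#' (at least two exons); a stricter reading (at least three) is one
#' parameter away.
#'
#' @param candidates data.frame with columns `feature_id`, `length_nt`,
#'   `mean_fpkm`, `exon_count` and logical columns `cpc2`, `cnci`, `pfam`,
#'   `cpat` (TRUE = non-coding verdict).
#' @param min_len minimum transcript length in nt (default 200).
#' @param min_fpkm minimum mean FPKM (default 0.1).
#' @param min_exons minimum exon count (default 2).
#' @param require_all_tools if TRUE (default) all four verdicts must be
#'   non-coding; if FALSE a single non-coding verdict suffices.
#' @return The surviving rows, with per-criterion removal counts attached as
#'   the `removed` attribute and reported in a message.
#' @export
filter_lncrna_candidates <- function(candidates, min_len = 200,
                                     min_fpkm = 0.1, min_exons = 2,
                                     require_all_tools = TRUE) {
  req <- c("feature_id", "length_nt", "mean_fpkm", "exon_count",
           "cpc2", "cnci", "pfam", "cpat")
  .assert(all(req %in% names(candidates)), "candidate table needs columns %s",
          paste(setdiff(req, names(candidates)), collapse = ", "))
  tools <- as.matrix(candidates[c("cpc2", "cnci", "pfam", "cpat")])
  noncoding <- if (require_all_tools) rowSums(!tools) == 0L
               else rowSums(tools) > 0L
  pass_len <- candidates$length_nt >= min_len
  pass_fpkm <- candidates$mean_fpkm >= min_fpkm
  pass_exons <- candidates$exon_count >= min_exons
  keep <- noncoding & pass_len & pass_fpkm & pass_exons
  removed <- c(coding_potential = sum(!noncoding), length = sum(!pass_len),
               fpkm = sum(!pass_fpkm), exons = sum(!pass_exons))
  message(sprintf(
    "filter_lncrna_candidates: retained %d/%d (failed: coding %d, length %d, fpkm %d, exons %d)",
    sum(keep), nrow(candidates), removed[1], removed[2], removed[3], removed[4]))
  out <- candidates[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- removed
  out
}

#' Classify lncRNAs by genomic position
#'
#' Assigns each lncRNA one of four positional classes relative to annotated
#' gene models: `lincRNA` (no gene overlap), `sense` (overlaps a same-strand
#' exon), `intronic` (overlaps a same-strand gene but no same-strand exon),
#' `antisense` (overlaps a gene only on the opposite strand). When several
#' genes overlap one lncRNA, same-strand exonic evidence wins, then
#' same-strand intronic, then antisense. Overlap means at least one shared
#' base under half-open arithmetic; strand "." is treated as "+" with a
#' warning. lncRNAs on chromosomes absent from the annotation come back
#' `lincRNA` with a warning.
#'
#' @param lncrnas feature_set (or data.frame) of lncRNA intervals.
#' @param genes feature_set of gene models carrying exon children (in the
#'   `exons` attribute or passed via `gene_exons`).
#' @param gene_exons optional exon data.frame overriding the attribute.
#' @return data.frame with `feature_id` and `class`.
#' @export
classify_lncrna <- function(lncrnas, genes, gene_exons = feature_exons(genes)) {
  .assert(nrow(lncrnas) > 0L, "no lncRNAs to classify")
  genes <- genes[genes$feature_class == "gene", , drop = FALSE]
  lnc_strand <- norm_strand(lncrnas$strand, "lncRNA classification")
  gene_strand <- norm_strand(genes$strand)
  lnc_gr <- fs_granges(lncrnas, use_strand = FALSE)
  gene_gr <- fs_granges(genes, use_strand = FALSE)

  missing_chrom <- !(lncrnas$chrom %in% unique(genes$chrom))
  if (any(missing_chrom)) {
    warning(sprintf(
      "%d lncRNA(s) on chromosome(s) absent from the annotation: classified lincRNA",
      sum(missing_chrom)), call. = FALSE)
  }

  # suppressWarnings: disjoint seqlevels (already surfaced above) make
  # findOverlaps chatty
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(lnc_gr, gene_gr, ignore.strand = TRUE))
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  same <- lnc_strand[qi] == gene_strand[si]
  has_same_gene <- tabulate(qi[same], nrow(lncrnas)) > 0L
  has_anti_gene <- tabulate(qi[!same], nrow(lncrnas)) > 0L

  has_sense <- rep(FALSE, nrow(lncrnas))
  if (!is.null(gene_exons) && nrow(gene_exons) > 0L) {
    ex <- gene_exons[gene_exons$parent_id %in% genes$feature_id, , drop = FALSE]
    if (nrow(ex) > 0L) {
      ex_strand <- norm_strand(ex$strand)
      ex_gr <- fs_granges(ex, use_strand = FALSE)
      ehits <- suppressWarnings(
        GenomicRanges::findOverlaps(lnc_gr, ex_gr, ignore.strand = TRUE))
      eq <- S4Vectors::queryHits(ehits)
      es <- S4Vectors::subjectHits(ehits)
      esame <- lnc_strand[eq] == ex_strand[es]
      has_sense <- tabulate(eq[esame], nrow(lncrnas)) > 0L
    }
  }

  cls <- ifelse(has_sense, "sense",
         ifelse(has_same_gene, "intronic",
         ifelse(has_anti_gene, "antisense", "lincRNA")))
  data.frame(feature_id = lncrnas$feature_id, class = cls,
             stringsAsFactors = FALSE)
}

#' Merge per-accession lncRNA sets by genomic overlap
#'
#' Single-linkage clustering of same-chromosome, same-strand intervals that
#' share at least one base (half-open; mere adjacency does not merge). Each
#' cluster emits the coordinate union and records its member ids per
#' accession; the total member count is conserved.
#'
#' @param sets named list of feature_set/data.frames, one per accession.
#' @return data.frame of non-redundant intervals with `cluster_id`,
#'   `chrom`, `start`, `end`, `strand`, `n_members`, `members`
#'   (comma-separated `accession:id`).
#' @export
merge_by_overlap <- function(sets) {
  .assert(is.list(sets) && length(sets) >= 1L, "need at least one accession set")
  if (is.null(names(sets))) names(sets) <- paste0("acc", seq_along(sets))
  all <- do.call(rbind, lapply(names(sets), function(nm) {
    df <- as.data.frame(sets[[nm]])[c("chrom", "start", "end", "strand",
                                      "feature_id")]
    df$accession <- nm
    df
  }))
  all$strand <- norm_strand(all$strand, "overlap merging")
  out <- list()
  for (key in unique(paste(all$chrom, all$strand))) {
    sub <- all[paste(all$chrom, all$strand) == key, , drop = FALSE]
    ir <- IRanges::IRanges(sub$start + 1L, sub$end)
    # min.gapwidth = 0 merges only truly overlapping ranges, not adjacent ones
    red <- IRanges::reduce(ir, min.gapwidth = 0L)
    mem <- IRanges::findOverlaps(ir, red)
    cl <- S4Vectors::subjectHits(mem)[order(S4Vectors::queryHits(mem))]
    for (i in seq_along(red)) {
      rows <- sub[cl == i, , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        chrom = rows$chrom[1],
        start = IRanges::start(red)[i] - 1L,
        end = IRanges::end(red)[i],
        strand = rows$strand[1],
        n_members = nrow(rows),
        members = paste(rows$accession, rows$feature_id, sep = ":",
                        collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start, res$strand), , drop = FALSE]
  res <- cbind(cluster_id = sprintf("merged_%04d", seq_len(nrow(res))), res)
  rownames(res) <- NULL
  res
}
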