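# Small in-code fixtures shared across test files.

fs_df <- function(chrom, start, end, strand, id, class = "gene",
                  exon_count = NA_integer_) {
  data.frame(chrom = chrom, start = start, end = end, strand = strand,
             feature_id = id, feature_class = class,
             exon_count = exon_count, stringsAsFactors = FALSE)
}

# a two-gene annotation with exons, used by classification tests:
#   geneA [0, 5000)+ exons [0,1000) and [4000,5000)  (intron [1000,4000))
#   geneB [6000, 8000)- exons [6000,6500) and [7500,8000)
tiny_genes <- function() {
  feats <- rbind(
    fs_df("chr1", 0L, 5000L, "+", "geneA", exon_count = 2L),
    fs_df("chr1", 6000L, 8000L, "-", "geneB", exon_count = 2L))
  exons <- data.frame(
    parent_id = c("geneA", "geneA", "geneB", "geneB"),
    chrom = "chr1",
    start = c(0L, 4000L, 6000L, 7500L),
    end = c(1000L, 5000L, 6500L, 8000L),
    strand = c("+", "+", "-", "-"), stringsAsFactors = FALSE)
  feature_set(feats, exons = exons)
}

# expression matrix for a 3-vs-2 two-group design
tiny_expr <- function(rows) {
  m <- do.call(rbind, rows)
  colnames(m) <- c("t1", "t2", "t3", "p1", "p2")
  groups <- c(t1 = "temperate", t2 = "temperate", t3 = "temperate",
              p1 = "tropical", p2 = "tropical")
  expression_matrix(m, groups)
}

# methylation call builder
mk_calls <- function(chrom, pos, meth, total, context = "CG",
                     strand = "+") {
  data.frame(chrom = chrom, pos = pos, strand = strand, context = context,
             meth_count = meth, total_count = total,
             stringsAsFactors = FALSE)
}
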