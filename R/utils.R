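# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert <- function(ok, msg, ...) {
  if (!isTRUE(ok)) stop(sprintf(msg, ...), call. = FALSE)
}

# Strand vocabulary is {+, -, .}; "." carries no orientation and is treated
# as "+" wherever orientation matters, with a warning so the coercion is
# never silent.
norm_strand <- function(strand, warn_context = NULL) {
  s <- as.character(strand)
  bad <- !s %in% c("+", "-", ".")
  .assert(!any(bad), "invalid strand value(s): %s",
          paste(unique(s[bad]), collapse = ", "))
  n_dot <- sum(s == ".")
  if (n_dot > 0L && !is.null(warn_context)) {
    warning(sprintf("%d feature(s) with strand '.' treated as '+' for %s",
                    n_dot, warn_context), call. = FALSE)
  }
  s[s == "."] <- "+"
  s
}

# Internal coordinates are 0-based half-open; GRanges is 1-based closed,
# so the shift happens here and only here.
fs_granges <- function(df, use_strand = TRUE, warn_context = NULL) {
  st <- if (use_strand) norm_strand(df$strand, warn_context) else "*"
  GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = st
  )
}

pos_granges <- function(chrom, pos) {
  # 1-based point positions (e.g. cytosine calls)
  GenomicRanges::GRanges(as.character(chrom), IRanges::IRanges(pos, pos))
}

# Deterministic non-cryptographic FNV-1a hash of a string, used to stamp
# output files with a config fingerprint.
fnv1a <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    # xor affects the low byte only (b < 256); h stays a double in [0, 2^32)
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b))
    # 32-bit modular multiply without losing double precision
    h1 <- h %/% 65536; h0 <- h %% 65536
    h <- (((h1 * p) %% 65536) * 65536 + h0 * p) %% 4294967296
  }
  sprintf("%08x", h)
}

write_tsv_commented <- function(df, path, comments = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

read_tsv_plain <- function(path) {
  utils::read.delim(path, comment.char = "#", check.names = FALSE,
                    stringsAsFactors = FALSE)
}
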