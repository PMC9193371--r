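# Synthetic multi-omic data generator with planted ground truth.
#
# The generator emulates the study design every downstream stage expects:
# a two-ecotype comparison with 3 vs 2 biological replicates across four
# RNA classes (mRNA/gene, lncRNA, circRNA, miRNA), a miRNA target map with
# planted shared-MRE ceRNA pairs plus uncorrelated decoy pairs, binomial
# bisulfite counts in CG/CHG/CHH with planted group differences and DMRs,
# and 20-kb sliding-window FST/pi tables with planted sweep windows. Every
# generator is a pure function of its seed and parameters.

#' Generate a synthetic genome annotation
#'
#' Places non-overlapping multi-exon gene models on `n_chrom` chromosomes,
#' then lncRNAs realising all four positional classes (intergenic,
#' antisense, intronic, sense), circRNA back-splice spans and miRNA loci.
#' Deterministic given the seed; an infeasible packing (chromosomes too
#' short for the requested counts) is an error.
#'
#' @param seed integer seed.
#' @param n_chrom,chrom_len chromosome count and length (bp).
#' @param n_genes,n_lncrna,n_circrna,n_mirna feature counts.
#' @return list with `features` (a [feature_set] incl. gene exons) and
#'   `truth` (planted lncRNA classes).
#' @export
make_annotation <- function(seed, n_chrom = 2L, chrom_len = 1e6,
                            n_genes = 500L, n_lncrna = 150L,
                            n_circrna = 80L, n_mirna = 60L) {
  slot <- floor(chrom_len * n_chrom / n_genes)
  .assert(slot >= 3000, "infeasible packing: %d genes do not fit in %d bp",
          n_genes, as.integer(chrom_len * n_chrom))
  withr::with_seed(seed, {
    chroms <- paste0("chr", seq_len(n_chrom))
    genes_per_chrom <- diff(round(seq(0, n_genes, length.out = n_chrom + 1)))
    slot <- floor(chrom_len / max(genes_per_chrom))

    genes <- list(); exons <- list(); gi <- 0L
    for (ci in seq_len(n_chrom)) {
      for (g in seq_len(genes_per_chrom[ci])) {
        gi <- gi + 1L
        slot_start <- (g - 1L) * slot
        len <- round(stats::runif(1, min(2000, slot * 0.4), slot * 0.6))
        start <- slot_start + round(stats::runif(1, 50, slot * 0.2))
        strand <- sample(c("+", "-"), 1)
        id <- sprintf("gene_%04d", gi)
        n_ex <- sample(2:5, 1)
        # alternate exon/intron segments over the gene span
        cuts <- sort(stats::runif(2L * n_ex - 2L, 0.05, 0.95))
        bnd <- round(c(0, cuts, 1) * len) + start
        ex_start <- bnd[seq(1, 2L * n_ex - 1L, by = 2)]
        ex_end <- bnd[seq(2, 2L * n_ex, by = 2)]
        ok <- ex_end > ex_start
        ex_start <- ex_start[ok]; ex_end <- ex_end[ok]
        genes[[gi]] <- data.frame(chrom = chroms[ci], start = start,
                                  end = start + len, strand = strand,
                                  feature_id = id, feature_class = "gene",
                                  exon_count = length(ex_start))
        exons[[gi]] <- data.frame(parent_id = id, chrom = chroms[ci],
                                  start = ex_start, end = ex_end,
                                  strand = strand)
      }
    }
    genes <- do.call(rbind, genes)
    exons <- do.call(rbind, exons)

    flip <- function(s) if (s == "+") "-" else "+"
    quota <- rep(n_lncrna %/% 4L, 4L)
    quota[1] <- quota[1] + n_lncrna %% 4L
    names(quota) <- c("lincRNA", "antisense", "intronic", "sense")

    lnc <- list(); li <- 0L
    truth_class <- character()
    multi_ex <- genes$feature_id[genes$exon_count >= 2L]
    for (cls in names(quota)) {
      for (j in seq_len(quota[[cls]])) {
        li <- li + 1L
        id <- sprintf("lnc_%04d", li)
        if (cls == "lincRNA") {
          # intergenic: between the end of one gene slot's gene and the next
          repeat {
            g <- sample(nrow(genes), 1)
            gap_start <- genes$end[g] + 10L
            nxt <- genes[genes$chrom == genes$chrom[g] &
                           genes$start > genes$end[g], , drop = FALSE]
            gap_end <- if (nrow(nxt)) min(nxt$start) - 10L
                       else genes$end[g] + 5000L
            if (gap_end - gap_start >= 400L) break
          }
          len <- round(stats::runif(1, 300, min(2000, gap_end - gap_start)))
          start <- gap_start + round(stats::runif(1, 0, gap_end - gap_start - len))
          row <- data.frame(chrom = genes$chrom[g], start = start,
                            end = start + len, strand = sample(c("+", "-"), 1))
        } else if (cls == "antisense") {
          g <- sample(nrow(genes), 1)
          len <- round(stats::runif(1, 300, 1500))
          start <- genes$start[g] +
            round(stats::runif(1, 0, max(1, genes$end[g] - genes$start[g] - len)))
          row <- data.frame(chrom = genes$chrom[g], start = start,
                            end = min(start + len, genes$end[g]),
                            strand = flip(genes$strand[g]))
        } else if (cls == "intronic") {
          repeat {
            gid <- sample(multi_ex, 1)
            ex <- exons[exons$parent_id == gid, , drop = FALSE]
            ex <- ex[order(ex$start), , drop = FALSE]
            int_start <- ex$end[1] + 5L
            int_end <- ex$start[2] - 5L
            if (int_end - int_start >= 250L) break
          }
          grow <- genes[genes$feature_id == gid, ]
          len <- round(stats::runif(1, 200, min(800, int_end - int_start)))
          start <- int_start +
            round(stats::runif(1, 0, int_end - int_start - len))
          row <- data.frame(chrom = grow$chrom, start = start,
                            end = start + len, strand = grow$strand)
        } else { # sense: inside an exon, same strand
          repeat {
            g <- sample(nrow(genes), 1)
            ex <- exons[exons$parent_id == genes$feature_id[g], , drop = FALSE]
            ex <- ex[ex$end - ex$start >= 250L, , drop = FALSE]
            if (nrow(ex)) break
          }
          e <- ex[sample(nrow(ex), 1), ]
          len <- round(stats::runif(1, 200, min(600, e$end - e$start)))
          start <- e$start + round(stats::runif(1, 0, e$end - e$start - len))
          row <- data.frame(chrom = e$chrom, start = start,
                            end = start + len, strand = genes$strand[g])
        }
        row$feature_id <- id
        row$feature_class <- "lncRNA"
        row$exon_count <- sample(2:4, 1)
        lnc[[li]] <- row
        truth_class[id] <- cls
      }
    }
    lnc <- do.call(rbind, lnc)

    circ <- lapply(seq_len(n_circrna), function(i) {
      g <- sample(nrow(genes), 1)
      len <- round(stats::runif(1, 200,
                                min(1500, genes$end[g] - genes$start[g])))
      start <- genes$start[g] +
        round(stats::runif(1, 0, genes$end[g] - genes$start[g] - len))
      data.frame(chrom = genes$chrom[g], start = start, end = start + len,
                 strand = genes$strand[g],
                 feature_id = sprintf("circ_%04d", i),
                 feature_class = "circRNA", exon_count = NA_integer_)
    })
    circ <- do.call(rbind, circ)

    mir <- lapply(seq_len(n_mirna), function(i) {
      g <- sample(nrow(genes), 1)
      start <- genes$end[g] + round(stats::runif(1, 200, 2000))
      len <- round(stats::runif(1, 90, 150))
      data.frame(chrom = genes$chrom[g],
                 start = min(start, n_chrom * chrom_len - len - 1),
                 end = min(start, n_chrom * chrom_len - len - 1) + len,
                 strand = sample(c("+", "-"), 1),
                 feature_id = sprintf("mir_%04d", i),
                 feature_class = "miRNA", exon_count = NA_integer_)
    })
    mir <- do.call(rbind, mir)

    feats <- rbind(genes, lnc, circ, mir)
    list(features = feature_set(feats, exons = exons),
         truth = list(lncrna_classes = truth_class, seed = seed))
  })
}

#' Simulate an expression matrix with planted structure
#'
#' Log-normal baseline abundances with per-sample biological noise; planted
#' DE features receive a group mean shift of `+/- lfc_mean` on the log2
#' scale; each planted ceRNA pair is driven by one shared latent factor
#' with small independent noise so the expected pair correlation exceeds
#' 0.995; planted ecotype-specific circRNAs are exact zeros in the off
#' group. DE statistics (log2FC, p, FDR) are emitted analytically from the
#' planted effects plus a stated normal error model (`se`), since count
#' model fitting is out of scope for this package.
#'
#' @param annotation output of [make_annotation].
#' @param design named integer vector of group sizes (default
#'   `c(temperate = 3, tropical = 2)`).
#' @param de_fraction fraction of eligible features planted DE (default
#'   0.1).
#' @param lfc_mean planted absolute log2 fold change (default 2).
#' @param cerna_pairs optional data.frame with `id_a`, `id_b`: pairs driven
#'   by a shared latent factor.
#' @param n_specific number of planted ecotype-specific circRNAs (default
#'   10% of circRNAs, at least 2).
#' @param de_pair_fraction fraction of planted ceRNA pairs whose members
#'   additionally receive a shared group shift of `+/- lfc_mean` (both
#'   members shift together, so the pair correlation is preserved while the
#'   members become differentially expressed; default 0.3).
#' @param noise_sd log2 noise of ceRNA pair members around the latent
#'   factor (default 0.05).
#' @param biol_sd log2 biological noise of unpaired features (default 0.5).
#' @param latent_sd log2 sd of the shared latent factor (default 2).
#' @param se standard error of the analytic log2FC estimates (default 0.3).
#' @param seed integer seed.
#' @return list with `expr` ([expression_matrix]), `de_stats`, `truth`.
#' @export
simulate_expression <- function(annotation,
                                design = c(temperate = 3L, tropical = 2L),
                                de_fraction = 0.1, lfc_mean = 2,
                                cerna_pairs = NULL, n_specific = NULL,
                                de_pair_fraction = 0.3,
                                noise_sd = 0.05, biol_sd = 0.5,
                                latent_sd = 2, se = 0.3, seed = 1L) {
  .assert(de_fraction >= 0 && de_fraction <= 1,
          "de_fraction outside [0, 1]")
  .assert(length(design) == 2L && all(design >= 1L),
          "design must give two positive group sizes")
  fs <- annotation$features
  ids <- fs$feature_id
  circ_ids <- fs$feature_id[fs$feature_class == "circRNA"]
  if (is.null(n_specific)) n_specific <- max(2L, round(0.1 * length(circ_ids)))
  withr::with_seed(seed, {
    groups <- rep(names(design), design)
    samples <- paste0(groups, "_", unlist(lapply(design, seq_len)))
    names(groups) <- samples
    n_s <- length(samples)
    is_a <- groups == names(design)[1]

    pair_members <- unique(c(cerna_pairs$id_a, cerna_pairs$id_b))
    spec_ids <- sample(setdiff(circ_ids, pair_members), n_specific)
    spec_a <- spec_ids[seq_len(ceiling(n_specific / 2))]
    spec_b <- setdiff(spec_ids, spec_a)

    eligible <- setdiff(ids, c(pair_members, spec_ids))
    n_de <- round(de_fraction * length(eligible))
    de_ids <- sample(eligible, n_de)
    de_dir <- sample(c(1, -1), n_de, replace = TRUE)
    names(de_dir) <- de_ids

    mu <- stats::runif(length(ids), 2, 8)
    names(mu) <- ids
    shift <- matrix(0, length(ids), n_s, dimnames = list(ids, samples))
    shift[de_ids, is_a] <- de_dir * lfc_mean
    log2x <- mu + shift + matrix(stats::rnorm(length(ids) * n_s, 0, biol_sd),
                                 length(ids), n_s)
    vals <- 2^log2x

    if (!is.null(cerna_pairs) && nrow(cerna_pairs)) {
      n_pair_de <- round(de_pair_fraction * nrow(cerna_pairs))
      pair_de <- sample(nrow(cerna_pairs), n_pair_de)
      for (i in seq_len(nrow(cerna_pairs))) {
        z <- stats::rnorm(n_s, 0, latent_sd)
        mu_p <- stats::runif(1, 3, 7)
        pshift <- numeric(n_s)
        if (i %in% pair_de) {
          dir <- sample(c(1, -1), 1)
          pshift[is_a] <- dir * lfc_mean
          members <- c(cerna_pairs$id_a[i], cerna_pairs$id_b[i])
          de_dir <- c(de_dir, stats::setNames(rep(dir, 2L), members))
        }
        for (m in c(cerna_pairs$id_a[i], cerna_pairs$id_b[i])) {
          vals[m, ] <- 2^(mu_p + z + pshift + stats::rnorm(n_s, 0, noise_sd))
        }
      }
    }
    for (s in spec_a) {
      vals[s, is_a] <- 2^(mu[s] + stats::rnorm(sum(is_a), 0, biol_sd))
      vals[s, !is_a] <- 0
    }
    for (s in spec_b) {
      vals[s, !is_a] <- 2^(mu[s] + stats::rnorm(sum(!is_a), 0, biol_sd))
      vals[s, is_a] <- 0
    }
    dimnames(vals) <- list(ids, samples)

    lfc_true <- stats::setNames(rep(0, length(ids)), ids)
    lfc_true[names(de_dir)] <- de_dir * lfc_mean
    lfc_true[spec_a] <- 6
    lfc_true[spec_b] <- -6
    lfc_hat <- lfc_true + stats::rnorm(length(ids), 0, se)
    pval <- 2 * stats::pnorm(-abs(lfc_hat) / se)
    de_stats <- data.frame(feature_id = ids, log2FC = lfc_hat,
                           pvalue = pval, fdr = bh_fdr(pval),
                           stringsAsFactors = FALSE)

    list(expr = expression_matrix(vals, groups, unit = "normalized"),
         de_stats = de_stats,
         truth = list(planted_de = de_dir,
                      planted_specific = list(a = spec_a, b = spec_b),
                      cerna_pairs = cerna_pairs,
                      design = design, seed = seed))
  })
}

#' Simulate a miRNA target map with planted ceRNA pairs
#'
#' Background targets are drawn independently per miRNA
#' (`Poisson(mean_degree)` targets each). Each planted "true" pair is an
#' (lncRNA or circRNA, mRNA) couple assigned at least `k_min` common
#' miRNAs; decoy pairs get shared miRNA sets of the same size but are meant
#' to receive no correlated expression (they exercise the correlation gate
#' as null candidates). True-pair memberships are disjoint so no latent
#' factor leaks across pairs.
#'
#' @param annotation output of [make_annotation].
#' @param mean_degree mean background targets per miRNA (default 5).
#' @param n_true_pairs planted correlated pairs (default 50).
#' @param n_decoy_pairs planted uncorrelated shared-MRE pairs (default
#'   500).
#' @param k_min minimum planted shared-miRNA count (default 6).
#' @param k_extra_mean Poisson mean of extra shared miRNAs beyond `k_min`.
#' @param seed integer seed.
#' @return list with `map` (a [target_map]) and `truth` (`true_pairs`,
#'   `decoy_pairs` data.frames with planted `k`).
#' @export
simulate_target_map <- function(annotation, mean_degree = 5,
                                n_true_pairs = 50L, n_decoy_pairs = 500L,
                                k_min = 6L, k_extra_mean = 1,
                                seed = 1L) {
  fs <- annotation$features
  mirnas <- fs$feature_id[fs$feature_class == "miRNA"]
  .assert(k_min <= length(mirnas), "k_min exceeds the number of miRNAs")
  tclass <- c(gene = "mRNA", lncRNA = "lncRNA", circRNA = "circRNA")
  targ <- fs[fs$feature_class %in% names(tclass), c("feature_id", "feature_class")]
  targ$target_class <- unname(tclass[targ$feature_class])
  nc_pool <- targ$feature_id[targ$target_class != "mRNA"]
  m_pool <- targ$feature_id[targ$target_class == "mRNA"]
  .assert(n_true_pairs <= length(nc_pool) && n_true_pairs <= length(m_pool),
          "not enough features for %d disjoint true pairs", n_true_pairs)
  withr::with_seed(seed, {
    rows <- list()
    plant_pair <- function(a, b) {
      k <- k_min + stats::rpois(1, k_extra_mean)
      shared <- sample(mirnas, k)
      list(df = data.frame(miRNA_id = rep(shared, 2L),
                           target_id = rep(c(a, b), each = k)),
           k = k, shared = shared)
    }
    nc_sh <- sample(nc_pool)
    m_sh <- sample(m_pool)
    true_pairs <- data.frame(id_a = nc_sh[seq_len(n_true_pairs)],
                             id_b = m_sh[seq_len(n_true_pairs)],
                             k = rep(NA_integer_, n_true_pairs),
                             stringsAsFactors = FALSE)
    for (i in seq_len(n_true_pairs)) {
      p <- plant_pair(true_pairs$id_a[i], true_pairs$id_b[i])
      true_pairs$k[i] <- p$k
      rows[[length(rows) + 1L]] <- p$df
    }
    nc_rest <- if (n_true_pairs > 0L) nc_sh[-seq_len(n_true_pairs)] else nc_sh
    m_rest <- if (n_true_pairs > 0L) m_sh[-seq_len(n_true_pairs)] else m_sh
    decoy_pairs <- NULL
    if (n_decoy_pairs > 0L) {
      .assert(length(nc_rest) > 0L && length(m_rest) > 0L,
              "no features left for decoy pairs")
      seen <- character()
      da <- db <- character(n_decoy_pairs); dk <- integer(n_decoy_pairs)
      i <- 0L
      while (i < n_decoy_pairs) {
        a <- sample(nc_rest, 1); b <- sample(m_rest, 1)
        key <- paste(a, b)
        if (key %in% seen) next
        seen <- c(seen, key)
        i <- i + 1L
        p <- plant_pair(a, b)
        da[i] <- a; db[i] <- b; dk[i] <- p$k
        rows[[length(rows) + 1L]] <- p$df
      }
      decoy_pairs <- data.frame(id_a = da, id_b = db, k = dk,
                                stringsAsFactors = FALSE)
    }
    deg <- stats::rpois(length(mirnas), mean_degree)
    for (j in seq_along(mirnas)) {
      if (deg[j] > 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          miRNA_id = mirnas[j],
          target_id = sample(targ$feature_id, min(deg[j], nrow(targ))))
      }
    }
    all <- do.call(rbind, rows)
    all$target_class <- targ$target_class[match(all$target_id,
                                                targ$feature_id)]
    list(map = target_map(all),
         truth = list(true_pairs = true_pairs, decoy_pairs = decoy_pairs,
                      n_mirnas = length(mirnas), seed = seed))
  })
}

#' Simulate bisulfite methylation call sets
#'
#' Places cytosines of each context along the chromosomes at the stated
#' densities, assigns each site a latent methylation probability (group
#' base level for its context, plus site-level noise, plus the planted DMR
#' shift where applicable), and draws per-sample counts as
#' `Binomial(coverage ~ Poisson(coverage_mean), level)`; sites with zero
#' drawn coverage are absent from that sample's call set. Default base
#' levels make the first group (temperate) moderately hypermethylated in
#' all three contexts.
#'
#' @param annotation output of [make_annotation] (provides the genome
#'   extent and the features DMRs are planted over).
#' @param design named group sizes (default `c(temperate = 3, tropical =
#'   2)`).
#' @param base_levels per-context two-element vectors (group order follows
#'   `design`).
#' @param site_density sites per kb per context.
#' @param site_noise_sd sd of site-level deviation from the base level.
#' @param dmr_n DMRs planted per context.
#' @param dmr_delta level shift of the first group inside a DMR.
#' @param dmr_feature_ids optional feature ids whose bodies host the DMRs
#'   (default: random lncRNAs).
#' @param coverage_mean Poisson mean read coverage (default 20).
#' @param seed integer seed.
#' @return list with `calls` (per-sample list of call data.frames),
#'   `dmrs` (intervals with context and direction), `groups`, `truth`.
#' @export
simulate_methylation <- function(annotation,
                                 design = c(temperate = 3L, tropical = 2L),
                                 base_levels = list(CG = c(0.65, 0.55),
                                                    CHG = c(0.45, 0.37),
                                                    CHH = c(0.12, 0.09)),
                                 site_density = c(CG = 2, CHG = 1.5,
                                                  CHH = 3),
                                 site_noise_sd = 0.03,
                                 dmr_n = 5L, dmr_delta = 0.3,
                                 dmr_feature_ids = NULL,
                                 coverage_mean = 20, seed = 1L) {
  for (bl in base_levels) {
    .assert(all(bl >= 0) && all(bl <= 1), "base level outside [0, 1]")
  }
  fs <- annotation$features
  chrom_len <- tapply(fs$end, fs$chrom, max) + 3000L
  withr::with_seed(seed, {
    groups <- rep(names(design), design)
    samples <- paste0(groups, "_", unlist(lapply(design, seq_len)))
    names(groups) <- samples

    sites <- list()
    for (chrom in names(chrom_len)) {
      for (ctx in names(base_levels)) {
        n <- round(site_density[[ctx]] * chrom_len[[chrom]] / 1000)
        pos <- sort(sample.int(chrom_len[[chrom]], n))
        sites[[length(sites) + 1L]] <- data.frame(
          chrom = chrom, pos = pos,
          strand = sample(c("+", "-"), n, replace = TRUE),
          context = ctx, stringsAsFactors = FALSE)
      }
    }
    sites <- do.call(rbind, sites)
    eff <- stats::rnorm(nrow(sites), 0, site_noise_sd)

    # planted DMRs over feature bodies
    if (is.null(dmr_feature_ids)) {
      lnc <- fs$feature_id[fs$feature_class == "lncRNA"]
      dmr_feature_ids <- sample(lnc, min(length(lnc),
                                         dmr_n * length(base_levels)))
    }
    dmr_rows <- list()
    di <- 0L
    dmr_shift <- numeric(nrow(sites))  # shift applied to the first group
    for (ctx in names(base_levels)) {
      lo <- di * dmr_n + 1L
      hi <- min((di + 1L) * dmr_n, length(dmr_feature_ids))
      take <- if (lo <= hi) dmr_feature_ids[lo:hi] else character()
      di <- di + 1L
      for (fid in take) {
        f <- fs[fs$feature_id == fid, ]
        dir <- sample(c(1, -1), 1)
        in_dmr <- sites$chrom == f$chrom & sites$context == ctx &
          sites$pos - 1L >= f$start & sites$pos - 1L < f$end
        dmr_shift[in_dmr] <- dmr_shift[in_dmr] + dir * dmr_delta
        dmr_rows[[length(dmr_rows) + 1L]] <- data.frame(
          chrom = f$chrom, start = f$start, end = f$end, context = ctx,
          direction = if (dir > 0) "hyper_in_1" else "hypo_in_1",
          feature_id = fid, stringsAsFactors = FALSE)
      }
    }
    dmrs <- if (length(dmr_rows)) do.call(rbind, dmr_rows) else
      data.frame(chrom = character(), start = integer(), end = integer(),
                 context = character(), direction = character(),
                 feature_id = character())

    base_g <- vapply(seq_len(2L), function(g)
      vapply(sites$context, function(ctx) base_levels[[ctx]][g], 0),
      numeric(nrow(sites)))
    lev <- matrix(pmin(1, pmax(0, base_g + eff + cbind(dmr_shift, 0))),
                  nrow(sites), 2L)

    calls <- stats::setNames(vector("list", length(samples)), samples)
    for (s in samples) {
      g <- match(groups[[s]], names(design))
      cov <- stats::rpois(nrow(sites), coverage_mean)
      keep <- cov > 0L
      meth <- stats::rbinom(sum(keep), cov[keep], lev[keep, g])
      calls[[s]] <- data.frame(
        chrom = sites$chrom[keep], pos = sites$pos[keep],
        strand = sites$strand[keep], context = sites$context[keep],
        meth_count = meth, total_count = cov[keep],
        stringsAsFactors = FALSE)
    }
    list(calls = calls, dmrs = dmrs, groups = groups,
         truth = list(dmr_features = unique(dmrs$feature_id),
                      base_levels = base_levels, seed = seed))
  })
}

#' Simulate sliding-window FST / diversity tables with planted sweeps
#'
#' Background FST is Beta-distributed on `[0, fst_max]` and diversities are
#' log-normal. Planted sweep windows receive FST above the background 99th
#' percentile and a diversity ratio below the background 1st percentile
#' (pi dropped in the selected population), split between the two
#' populations.
#'
#' @param n_windows total sliding windows.
#' @param sweep_count planted sweep windows (must not exceed `n_windows`).
#' @param chrom chromosome name for the window coordinates.
#' @param window_bp,step_bp sliding-window geometry (defaults 20 kb / 2
#'   kb).
#' @param fst_max upper bound of the background FST distribution.
#' @param pi_mean median background nucleotide diversity.
#' @param seed integer seed.
#' @return list with `windows` (chrom/start/end/fst/pi_a/pi_b) and `truth`
#'   (`pop_a_idx`, `pop_b_idx` planted row indices).
#' @export
simulate_window_stats <- function(n_windows = 10000L, sweep_count = 100L,
                                  chrom = "chrS1", window_bp = 20000L,
                                  step_bp = 2000L, fst_max = 0.3,
                                  pi_mean = 0.005, seed = 1L) {
  .assert(sweep_count <= n_windows, "sweep_count exceeds n_windows")
  withr::with_seed(seed, {
    fst <- fst_max * stats::rbeta(n_windows, 2, 8)
    pi_a <- stats::rlnorm(n_windows, log(pi_mean), 0.4)
    pi_b <- stats::rlnorm(n_windows, log(pi_mean), 0.4)
    sweep <- sample.int(n_windows, sweep_count)
    a_idx <- sweep[seq_len(floor(sweep_count / 2))]
    b_idx <- setdiff(sweep, a_idx)
    bg <- setdiff(seq_len(n_windows), sweep)
    if (length(bg) >= 20L && sweep_count > 0L) {
      q99 <- stats::quantile(fst[bg], 0.99, names = FALSE)
      q01 <- stats::quantile((pi_a / pi_b)[bg], 0.01, names = FALSE)
      fst[sweep] <- stats::runif(sweep_count, q99,
                                 min(0.95, q99 + 0.3))
      pi_a[a_idx] <- pi_b[a_idx] * stats::runif(length(a_idx), 0.2, 0.9) * q01
      pi_b[b_idx] <- pi_a[b_idx] * stats::runif(length(b_idx), 0.2, 0.9) * q01
    }
    start <- (seq_len(n_windows) - 1L) * step_bp
    windows <- data.frame(chrom = chrom, start = start,
                          end = start + window_bp, fst = fst,
                          pi_a = pi_a, pi_b = pi_b,
                          stringsAsFactors = FALSE)
    list(windows = windows,
         truth = list(pop_a_idx = sort(a_idx), pop_b_idx = sort(b_idx),
                      seed = seed))
  })
}
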