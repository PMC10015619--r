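# Genomic context of ASE genes: per-gene CSS Z-scores and divergence-peak
# (EcoPeak) membership, and tests for whether ASE genes occupy more divergent
# regions than background genes, controlling for SNP density (which drives
# power to detect ASE) by quantile binning and density-matched resampling.

#' SNP density of a gene
#'
#' Informative heterozygous sites per base pair of transcript.
#'
#' @param n_het_sites Number of informative het sites (vectorized).
#' @param transcript_length Transcript length in bp (> 0).
#' @return `n_het_sites / transcript_length`.
#' @export
snp_density <- function(n_het_sites, transcript_length) {
  if (any(transcript_length <= 0)) stop("snp_density: transcript_length must be > 0")
  if (any(n_het_sites < 0)) stop("snp_density: negative site count")
  n_het_sites / transcript_length
}

#' Annotate genes with CSS scores, EcoPeak membership and SNP density
#'
#' Per gene: `css_z` is the median score of CSS windows overlapping the gene
#' interval by at least 1 bp (`NA` when no window overlaps; such genes are
#' excluded from Z analyses), `in_ecopeak` is any-bp overlap with an EcoPeak,
#' and `snp_density` counts the gene's sites in `sites` per bp of transcript
#' (interval length).
#'
#' @param genes An `interval_set` of kind `gene`.
#' @param css_windows An `interval_set` of kind `css_window` (scores = Z).
#' @param ecopeaks An `interval_set` of kind `ecopeak`.
#' @param sites Optional `site_counts` data.frame used for SNP density
#'   (ideally after [filter_sites()]).
#' @return A data.frame (class `gene_genomic_summary`): `gene_id`, `chrom`,
#'   `start`, `end`, `length`, `n_sites`, `snp_density`, `css_z`,
#'   `in_ecopeak`.
#' @export
annotate_genes <- function(genes, css_windows, ecopeaks, sites = NULL) {
  gr_genes <- intervals_to_granges(genes)
  gr_css <- intervals_to_granges(css_windows)
  gr_peak <- intervals_to_granges(ecopeaks)
  hits <- GenomicRanges::findOverlaps(gr_genes, gr_css)
  css_z <- rep(NA_real_, length(gr_genes))
  if (length(hits)) {
    med <- tapply(css_windows$score[S4Vectors::subjectHits(hits)],
                  S4Vectors::queryHits(hits), stats::median)
    css_z[as.integer(names(med))] <- as.numeric(med)
  }
  in_peak <- GenomicRanges::countOverlaps(gr_genes, gr_peak) > 0L
  len <- genes$end - genes$start
  n_sites <- integer(length(len))
  if (!is.null(sites)) {
    cnt <- table(sites$gene_id)
    idx <- match(genes$name, names(cnt))
    n_sites[!is.na(idx)] <- as.integer(cnt[idx[!is.na(idx)]])
  }
  out <- data.frame(
    gene_id = genes$name, chrom = genes$chrom,
    start = genes$start, end = genes$end, length = len,
    n_sites = n_sites, snp_density = snp_density(n_sites, len),
    css_z = css_z, in_ecopeak = in_peak,
    stringsAsFactors = FALSE
  )
  class(out) <- c("gene_genomic_summary", "data.frame")
  out
}

#' Quantile-bin genes by SNP density
#'
#' Equal-frequency bins sized to `target_bin_occupancy` genes; bins with
#' fewer than `min_per_category` genes in either category (ASE, background)
#' are dropped from the binned Z comparison and logged. Binning is
#' deterministic: genes are ordered by density with gene-id tie-break.
#'
#' @param summaries A `gene_genomic_summary` data.frame.
#' @param ase Logical vector, `TRUE` for ASE genes (aligned to `summaries`).
#' @param target_bin_occupancy Average genes per bin (default 23).
#' @param min_per_category Per-category minimum for a bin to be kept
#'   (default 5).
#' @param verbose Log dropped bins.
#' @return `summaries` with `ase`, `density_bin` (integer) and `bin_kept`
#'   (logical) columns added; attribute `dropped_bins` lists dropped bin ids.
#' @export
bin_by_density <- function(summaries, ase, target_bin_occupancy = 23,
                           min_per_category = 5, verbose = FALSE) {
  n <- nrow(summaries)
  if (n < 2 * min_per_category) stop("bin_by_density: too few genes to bin")
  ord <- order(summaries$snp_density, summaries$gene_id)
  n_bins <- max(1L, round(n / target_bin_occupancy))
  bin_sorted <- if (n_bins == 1L) rep(1L, n) else {
    as.integer(cut(seq_len(n), breaks = n_bins, labels = FALSE))
  }
  bin <- integer(n)
  bin[ord] <- bin_sorted
  out <- summaries
  out$ase <- ase
  out$density_bin <- bin
  keep_tab <- vapply(seq_len(n_bins), function(b) {
    sel <- bin == b
    c(sum(sel & ase), sum(sel & !ase))
  }, numeric(2))
  kept <- keep_tab[1, ] >= min_per_category & keep_tab[2, ] >= min_per_category
  out$bin_kept <- kept[bin]
  dropped <- which(!kept)
  if (length(dropped)) {
    pipeline_log("bin_by_density",
                 sprintf("dropped %d/%d bins with < %d genes in a category",
                         length(dropped), n_bins, min_per_category),
                 verbose = verbose)
  }
  attr(out, "dropped_bins") <- dropped
  attr(out, "n_bins") <- n_bins
  out
}

#' Binned permutation test for CSS Z differences between ASE and background
#'
#' The observed statistic is the median over kept density bins of
#' (median Z of ASE genes - median Z of background genes). Within each bin
#' the ASE labels are shuffled (bin structure and per-bin category counts are
#' preserved) and the statistic recomputed; the two-sided permutation p is
#' `(b + 1)/(n_perm + 1)` on `|statistic| >= |observed|`. Genes without a CSS
#' Z are excluded.
#'
#' @param binned Output of [bin_by_density()].
#' @param n_perm Number of permutations (default 10000).
#' @param seed RNG seed.
#' @return A list: `per_bin` (per-bin medians and differences), `observed`
#'   (aggregate statistic), `perm_p`, `n_permutations`.
#' @export
binned_permutation_test <- function(binned, n_perm = 10000, seed = 1) {
  dat <- binned[binned$bin_kept & !is.na(binned$css_z), ]
  if (nrow(dat) == 0L) stop("binned_permutation_test: no genes in kept bins")
  bins <- split(seq_len(nrow(dat)), dat$density_bin)
  z <- dat$css_z
  is_ase <- dat$ase
  per_bin_stat <- function(lab) {
    vapply(bins, function(idx) {
      a <- lab[idx]
      stats::median(z[idx][a]) - stats::median(z[idx][!a])
    }, numeric(1))
  }
  obs_bins <- per_bin_stat(is_ase)
  observed <- stats::median(obs_bins)
  n_ase_bin <- vapply(bins, function(idx) sum(is_ase[idx]), 1L)
  b <- 0L
  with_seed(seed, {
    for (r in seq_len(n_perm)) {
      lab <- logical(length(z))
      for (j in seq_along(bins)) {
        idx <- bins[[j]]
        lab[idx[sample.int(length(idx), n_ase_bin[j])]] <- TRUE
      }
      if (abs(stats::median(per_bin_stat(lab))) >= abs(observed) - 1e-12) {
        b <- b + 1L
      }
    }
  })
  per_bin <- data.frame(
    density_bin = as.integer(names(bins)),
    n_ase = n_ase_bin,
    n_background = vapply(bins, length, 1L) - n_ase_bin,
    median_z_ase = vapply(bins, function(idx) stats::median(z[idx][is_ase[idx]]), 0),
    median_z_background = vapply(bins, function(idx) stats::median(z[idx][!is_ase[idx]]), 0),
    diff = obs_bins, row.names = NULL
  )
  list(per_bin = per_bin, observed = observed,
       perm_p = perm_pvalue(b, n_perm), n_permutations = n_perm)
}

# Draw one density-matched random gene set: per bin, sample as many genes as
# the ASE set has in that bin, uniformly from the pool. Returns row indices.
.sample_matched <- function(bin, ase, pool_idx_by_bin, n_ase_by_bin,
                            with_replacement_bins) {
  unlist(lapply(seq_along(pool_idx_by_bin), function(j) {
    k <- n_ase_by_bin[j]
    if (k == 0L) return(integer(0))
    pool <- pool_idx_by_bin[[j]]
    if (with_replacement_bins[j]) {
      pool[sample.int(length(pool), k, replace = TRUE)]
    } else {
      pool[sample.int(length(pool), k)]
    }
  }), use.names = FALSE)
}

.matched_resampler <- function(binned, background) {
  bin <- binned$density_bin
  ase <- binned$ase
  ubins <- sort(unique(bin))
  n_ase_by_bin <- vapply(ubins, function(b) sum(ase & bin == b), 1L)
  pool_idx_by_bin <- lapply(ubins, function(b) {
    if (background == "all") which(bin == b) else which(bin == b & !ase)
  })
  wr <- vapply(seq_along(ubins), function(j) {
    length(pool_idx_by_bin[[j]]) < n_ase_by_bin[j]
  }, TRUE)
  if (any(wr)) {
    pipeline_log("matched_resampling",
                 sprintf("%d bin(s) with insufficient pool; sampling with replacement",
                         sum(wr)))
  }
  empty <- n_ase_by_bin > 0L & vapply(pool_idx_by_bin, length, 1L) == 0L
  if (any(empty)) stop("matched resampling: a bin has ASE genes but an empty pool")
  function() .sample_matched(bin, ase, pool_idx_by_bin, n_ase_by_bin, wr)
}

#' EcoPeak enrichment of ASE genes with density-matched resampling
#'
#' Compares the number of ASE genes overlapping EcoPeaks to `n_resample`
#' random gene sets of the same size with SNP densities matched to the ASE
#' set (sampling within the quantile density bins). Fold enrichment is the
#' observed in-peak count over the mean resampled count; the p-value is
#' `(b + 1)/(n_resample + 1)` on resampled count >= observed (floor 1/1001 at
#' 1,000 resamples).
#'
#' @param summaries A `gene_genomic_summary` data.frame.
#' @param ase Logical ASE flags aligned to `summaries`.
#' @param n_resample Number of matched random sets (default 1000).
#' @param seed RNG seed.
#' @param target_bin_occupancy Density-bin occupancy (default 23; the same
#'   binning as the Z test).
#' @param background `"all"` (default: random sets drawn from all genes) or
#'   `"non_ase"` (drawn from background genes only; bins with too few
#'   background genes fall back to sampling with replacement, logged).
#' @return A list: `observed` (ASE genes in peaks), `prop_ase_in_peak`,
#'   `expected` (mean resampled count), `fold`, `p`, `n_resample`, and
#'   `resampled` (the in-peak counts of the matched random sets, for
#'   confidence intervals).
#' @export
ecopeak_enrichment <- function(summaries, ase, n_resample = 1000, seed = 1,
                               target_bin_occupancy = 23,
                               background = c("all", "non_ase")) {
  background <- match.arg(background)
  if (!any(summaries$in_ecopeak)) stop("ecopeak_enrichment: no EcoPeak overlaps any gene")
  binned <- bin_by_density(summaries, ase,
                           target_bin_occupancy = target_bin_occupancy,
                           min_per_category = 0)
  drawer <- .matched_resampler(binned, background)
  obs <- sum(ase & summaries$in_ecopeak)
  res <- with_seed(seed, {
    vapply(seq_len(n_resample), function(r) {
      sum(summaries$in_ecopeak[drawer()])
    }, numeric(1))
  })
  list(observed = obs,
       prop_ase_in_peak = obs / max(1L, sum(ase)),
       expected = mean(res),
       fold = obs / mean(res),
       p = perm_pvalue(sum(res >= obs), n_resample),
       n_resample = n_resample,
       resampled = res)
}

#' Per-chromosome enrichment of ASE genes with density-matched resampling
#'
#' Counts ASE genes per chromosome and compares each count to density-matched
#' random gene sets (same construction as [ecopeak_enrichment()]).
#'
#' @inheritParams ecopeak_enrichment
#' @return A data.frame per chromosome: `chrom`, `n_ase` (observed),
#'   `expected`, `fold`, `p` (`(b + 1)/(n_resample + 1)` on resampled count
#'   >= observed).
#' @export
chromosome_enrichment <- function(summaries, ase, n_resample = 1000, seed = 1,
                                  target_bin_occupancy = 23,
                                  background = c("all", "non_ase")) {
  background <- match.arg(background)
  chroms <- sort(unique(summaries$chrom))
  if (length(chroms) < 2L) stop("chromosome_enrichment: need >= 2 chromosomes")
  binned <- bin_by_density(summaries, ase,
                           target_bin_occupancy = target_bin_occupancy,
                           min_per_category = 0)
  drawer <- .matched_resampler(binned, background)
  obs <- vapply(chroms, function(ch) sum(ase & summaries$chrom == ch), 1L)
  counts <- matrix(0L, nrow = n_resample, ncol = length(chroms),
                   dimnames = list(NULL, chroms))
  with_seed(seed, {
    for (r in seq_len(n_resample)) {
      tab <- table(summaries$chrom[drawer()])
      counts[r, names(tab)] <- as.integer(tab)
    }
  })
  data.frame(
    chrom = chroms,
    n_ase = obs,
    expected = colMeans(counts),
    fold = obs / pmax(colMeans(counts), .Machine$double.eps),
    p = vapply(seq_along(chroms), function(j) {
      perm_pvalue(sum(counts[, j] >= obs[j]), n_resample)
    }, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Candidate genes: ASE within divergence peaks overlapping QTL
#'
#' Joins ASE calls, EcoPeak membership and QTL overlap: genes with ASE in at
#' least one unit that lie inside an EcoPeak and overlap at least one QTL
#' interval, listing their ASE tissues and the overlapping QTL names.
#'
#' @param ase An `ase_results` data.frame.
#' @param summaries A `gene_genomic_summary` data.frame.
#' @param genes An `interval_set` of kind `gene` (for coordinates).
#' @param qtl An `interval_set` of kind `qtl`.
#' @return A data.frame: `gene_id`, `chrom`, `ase_tissues`, `qtls`.
#' @export
candidate_table <- function(ase, summaries, genes, qtl) {
  ase_units <- ase[ase$is_ase, ]
  ase_genes <- unique(ase_units$gene_id)
  gr_genes <- intervals_to_granges(genes)
  gr_qtl <- intervals_to_granges(qtl)
  hits <- GenomicRanges::findOverlaps(gr_genes, gr_qtl)
  qtl_by_gene <- split(qtl$name[S4Vectors::subjectHits(hits)],
                       genes$name[S4Vectors::queryHits(hits)])
  in_peak <- summaries$gene_id[summaries$in_ecopeak]
  keep <- intersect(intersect(ase_genes, in_peak), names(qtl_by_gene))
  if (length(keep) == 0L) {
    return(data.frame(gene_id = character(0), chrom = character(0),
                      ase_tissues = character(0), qtls = character(0),
                      stringsAsFactors = FALSE))
  }
  keep <- sort(keep)
  data.frame(
    gene_id = keep,
    chrom = summaries$chrom[match(keep, summaries$gene_id)],
    ase_tissues = vapply(keep, function(g) {
      u <- ase_units[ase_units$gene_id == g, ]
      paste(sort(paste(u$tissue, u$timepoint, sep = "@")), collapse = ",")
    }, character(1)),
    qtls = vapply(keep, function(g) {
      paste(sort(unique(qtl_by_gene[[g]])), collapse = ",")
    }, character(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
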