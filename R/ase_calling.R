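# Site filtering and per-tissue gene-level ASE testing. The per-gene test is
# an exact binomial test of the pooled marine-allele fraction against 0.5
# (optionally a beta-binomial variant with per-tissue overdispersion
# estimated across replicates), with Benjamini-Hochberg correction within
# each tissue-timepoint.

#' Filter heterozygous sites for mapping-bias artifacts
#'
#' Removes sites whose pooled allelic counts show (1) extreme ratios
#' indicative of mapping bias (|log2(marine/freshwater)| > `max_abs_lfc`), or
#' (2) zero reads on one of the two parental alleles. Counts are expected to
#' be pooled across all libraries (the pooled treatment is logged so it can
#' be audited). Idempotent.
#'
#' @param sites A `site_counts` data.frame (see [read_site_counts()]).
#' @param max_abs_lfc Ratio threshold on |log2(marine/freshwater)|
#'   (default 10).
#' @param verbose Log the removal summary to stderr.
#' @return A list with `sites` (surviving rows) and `removed` (removed rows
#'   plus a `reason` column, `"zero-allele"` or `"ratio"`).
#' @export
filter_sites <- function(sites, max_abs_lfc = 10, verbose = FALSE) {
  m <- sites$marine_count
  f <- sites$freshwater_count
  zero <- m == 0L | f == 0L
  ratio <- !zero & abs(log2(m / f)) > max_abs_lfc
  reason <- rep(NA_character_, nrow(sites))
  reason[zero] <- "zero-allele"
  reason[ratio] <- "ratio"
  removed <- sites[!is.na(reason), , drop = FALSE]
  removed$reason <- reason[!is.na(reason)]
  kept <- sites[is.na(reason), , drop = FALSE]
  rownames(kept) <- rownames(removed) <- NULL
  pipeline_log("filter_sites",
               sprintf("counts pooled across libraries; removed %d/%d sites (%d zero-allele, %d ratio > %g)",
                       nrow(removed), nrow(sites), sum(zero), sum(ratio), max_abs_lfc),
               verbose = verbose)
  list(sites = kept, removed = removed)
}

# Method-of-moments estimate of beta-binomial overdispersion rho for one
# tissue, from per-replicate allelic fractions across genes. rho = 1/(a+b+1)
# of the latent Beta; 0 means pure binomial.
estimate_overdispersion <- function(marine, freshwater, gene, min_depth = 20) {
  n <- marine + freshwater
  keep <- n >= min_depth
  if (!any(keep)) return(0)
  frac <- marine[keep] / n[keep]
  nn <- n[keep]
  g <- gene[keep]
  # within-gene excess variance of replicate fractions relative to binomial
  sp <- split(seq_along(g), g)
  sp <- sp[vapply(sp, length, 1L) >= 2L]
  if (length(sp) < 10L) return(0)
  num <- 0; den <- 0
  for (idx in sp) {
    th <- mean(frac[idx])
    v <- stats::var(frac[idx])
    vb <- th * (1 - th) * mean(1 / nn[idx])
    w <- th * (1 - th) * (1 - mean(1 / nn[idx]))
    if (w > 0) { num <- num + (v - vb); den <- den + w }
  }
  if (den <= 0) return(0)
  max(0, min(0.5, num / den))
}

# Two-sided minimum-likelihood beta-binomial test against a symmetric
# Beta(a, a) allele-fraction null; full pmf enumeration.
betabinom_test_half <- function(x, n, rho) {
  if (rho <= 0) return(binom_test_half(x, n))
  a <- (1 / rho - 1) / 2
  vapply(seq_along(x), function(i) {
    if (n[i] == 0) return(NA_real_)
    k <- 0:n[i]
    lp <- lchoose(n[i], k) + lbeta(k + a, n[i] - k + a) - lbeta(a, a)
    pmf <- exp(lp - logsumexp(lp))   # renormalize for numerical safety
    min(1, sum(pmf[pmf <= pmf[x[i] + 1] * (1 + 1e-12)]))
  }, numeric(1))
}

#' Per-tissue gene-level ASE test
#'
#' Pools replicate counts per gene within each tissue-timepoint, tests the
#' marine-allele fraction against 0.5 with a two-sided exact binomial test
#' (or a beta-binomial variant whose overdispersion is estimated per tissue
#' across replicates by method of moments), and adjusts p-values with
#' Benjamini-Hochberg within each tissue-timepoint. The allelic log2 fold
#' change uses a 0.5 pseudocount per allele: `lfc = log2((m+0.5)/(f+0.5))`.
#'
#' @param counts An `allelic_counts` data.frame.
#' @param fdr FDR threshold for calling ASE (default 0.05).
#' @param test `"binomial"` (default) or `"betabinomial"`.
#' @return A data.frame (class `ase_results`) with one row per gene x
#'   tissue x timepoint: pooled counts, `lfc`, `p_value`, `fdr`, `is_ase`,
#'   `untestable`.
#' @export
call_ase <- function(counts, fdr = 0.05, test = c("binomial", "betabinomial")) {
  test <- match.arg(test)
  unit <- interaction(counts$tissue, counts$timepoint, drop = TRUE)
  pooled <- stats::aggregate(
    counts[, c("marine_count", "freshwater_count")],
    by = list(gene_id = counts$gene_id, tissue = counts$tissue,
              timepoint = counts$timepoint),
    FUN = sum
  )
  pooled <- pooled[order(pooled$tissue, pooled$timepoint, pooled$gene_id), ]
  rownames(pooled) <- NULL
  m <- pooled$marine_count; f <- pooled$freshwater_count
  n <- m + f
  pooled$lfc <- allelic_lfc(m, f)
  pooled$untestable <- n == 0L

  pooled$p_value <- NA_real_
  units <- unique(pooled[, c("tissue", "timepoint")])
  for (i in seq_len(nrow(units))) {
    sel <- pooled$tissue == units$tissue[i] &
      pooled$timepoint == units$timepoint[i]
    rho <- 0
    if (test == "betabinomial") {
      raw <- counts[counts$tissue == units$tissue[i] &
                      counts$timepoint == units$timepoint[i], ]
      rho <- estimate_overdispersion(raw$marine_count, raw$freshwater_count,
                                     raw$gene_id)
    }
    idx <- which(sel & !pooled$untestable)
    pooled$p_value[idx] <- if (test == "binomial") {
      binom_test_half(m[idx], n[idx])
    } else {
      betabinom_test_half(m[idx], n[idx], rho)
    }
  }

  # BH within each tissue-timepoint; untestable genes excluded
  pooled$fdr <- NA_real_
  for (i in seq_len(nrow(units))) {
    idx <- which(pooled$tissue == units$tissue[i] &
                   pooled$timepoint == units$timepoint[i] & !pooled$untestable)
    if (length(idx)) pooled$fdr[idx] <- bh_adjust(pooled$p_value[idx])
  }
  pooled$is_ase <- !is.na(pooled$fdr) & pooled$fdr < fdr
  attr(pooled, "fdr_threshold") <- fdr
  attr(pooled, "test") <- test
  class(pooled) <- c("ase_results", "data.frame")
  pooled
}

#' Summaries of ASE calls across tissues
#'
#' @param results An `ase_results` data.frame from [call_ase()].
#' @return A list with `per_tissue` (ASE counts and proportions per
#'   tissue-timepoint), `gene_profiles` (per-gene UpSet-style membership
#'   string over units, number of ASE units, and direction-change flag), and
#'   `n_direction_change` (genes whose lfc sign flips between ASE units).
#' @export
summarize_ase <- function(results) {
  results$unit <- paste(results$tissue, results$timepoint, sep = "@")
  units <- sort(unique(results$unit))
  per_tissue <- do.call(rbind, lapply(units, function(u) {
    r <- results[results$unit == u & !results$untestable, ]
    data.frame(unit = u, n_tested = nrow(r), n_ase = sum(r$is_ase),
               prop_ase = if (nrow(r)) sum(r$is_ase) / nrow(r) else NA_real_,
               stringsAsFactors = FALSE)
  }))

  genes <- sort(unique(results$gene_id))
  memb <- matrix(FALSE, nrow = length(genes), ncol = length(units),
                 dimnames = list(genes, units))
  sgn <- matrix(NA_real_, nrow = length(genes), ncol = length(units),
                dimnames = list(genes, units))
  ase_rows <- results[results$is_ase, ]
  memb[cbind(match(ase_rows$gene_id, genes), match(ase_rows$unit, units))] <- TRUE
  sgn[cbind(match(ase_rows$gene_id, genes), match(ase_rows$unit, units))] <-
    sign(ase_rows$lfc)
  profile <- apply(memb, 1L, function(z) paste(as.integer(z), collapse = ""))
  dir_change <- apply(sgn, 1L, function(z) {
    z <- z[!is.na(z) & z != 0]
    length(unique(z)) > 1L
  })
  gene_profiles <- data.frame(
    gene_id = genes, profile = profile,
    n_ase_units = rowSums(memb),
    direction_change = dir_change,
    stringsAsFactors = FALSE, row.names = NULL
  )
  list(per_tissue = per_tissue,
       gene_profiles = gene_profiles,
       n_direction_change = sum(dir_change))
}
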