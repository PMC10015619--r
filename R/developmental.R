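# Differential ASE between developmental timepoints in matched tissues:
# a two-sided Fisher's exact test on the 2x2 table of (marine, freshwater)
# counts at the early and late timepoint, pooled across replicates, applied
# to genes with ASE at >= 1 timepoint, BH-corrected within each tissue.

#' Fisher's exact test for differential ASE between two timepoints
#'
#' Two-sided exact test on the table \code{rbind(c(m1, f1), c(m2, f2))},
#' vectorized. Pairs with a zero-read timepoint are untestable (`NA`).
#'
#' @param m1,f1 Pooled marine/freshwater counts at the early timepoint.
#' @param m2,f2 Pooled counts at the late timepoint.
#' @return Two-sided p-values.
#' @export
diff_ase_test <- function(m1, f1, m2, f2) {
  p <- fisher_exact_2x2(m1, f1, m2, f2)
  p[(m1 + f1) == 0 | (m2 + f2) == 0] <- NA_real_
  p
}

#' Differential-ASE analysis across developmental timepoints
#'
#' For every tissue present at both timepoints, tests each gene with ASE at
#' at least one timepoint for a change in allelic ratio between timepoints
#' (Fisher's exact on replicate-pooled counts, BH within tissue), and labels
#' the temporal pattern:
#' \itemize{
#'   \item `bias`: `early_bias` if |lfc_early| > |lfc_late| (larger allelic
#'     imbalance early), `late_bias` otherwise; `no_change` when not
#'     significant. Exact |lfc| ties go to `late_bias` and are flagged.
#'   \item `mode`: `timepoint_specific` when ASE is called at exactly one
#'     timepoint, `magnitude_change` when called at both, `none` otherwise.
#' }
#'
#' @param counts An `allelic_counts` data.frame with both timepoints.
#' @param ase An `ase_results` data.frame from [call_ase()] on the same
#'   counts.
#' @param fdr FDR threshold for the differential test (default 0.05).
#' @return A data.frame (class `diff_ase_results`), one row per tested gene x
#'   tissue.
#' @export
dev_ase <- function(counts, ase, fdr = 0.05) {
  pooled <- stats::aggregate(
    counts[, c("marine_count", "freshwater_count")],
    by = list(gene_id = counts$gene_id, tissue = counts$tissue,
              timepoint = counts$timepoint), FUN = sum)
  both_tp <- intersect(unique(pooled$tissue[pooled$timepoint == 1L]),
                       unique(pooled$tissue[pooled$timepoint == 2L]))
  if (length(both_tp) == 0L) {
    stop("dev_ase: no tissue is present at both timepoints")
  }
  out <- list()
  for (tis in sort(both_tp)) {
    e <- pooled[pooled$tissue == tis & pooled$timepoint == 1L, ]
    l <- pooled[pooled$tissue == tis & pooled$timepoint == 2L, ]
    genes <- intersect(e$gene_id, l$gene_id)
    e <- e[match(genes, e$gene_id), ]
    l <- l[match(genes, l$gene_id), ]
    a <- ase[ase$tissue == tis, ]
    ase_early <- genes %in% a$gene_id[a$timepoint == 1L & a$is_ase]
    ase_late <- genes %in% a$gene_id[a$timepoint == 2L & a$is_ase]
    keep <- ase_early | ase_late
    if (!any(keep)) next
    e <- e[keep, ]; l <- l[keep, ]
    ase_early <- ase_early[keep]; ase_late <- ase_late[keep]
    p <- diff_ase_test(e$marine_count, e$freshwater_count,
                       l$marine_count, l$freshwater_count)
    res <- data.frame(
      gene_id = e$gene_id, tissue = tis,
      m_early = e$marine_count, f_early = e$freshwater_count,
      m_late = l$marine_count, f_late = l$freshwater_count,
      lfc_early = allelic_lfc(e$marine_count, e$freshwater_count),
      lfc_late = allelic_lfc(l$marine_count, l$freshwater_count),
      ase_early = ase_early, ase_late = ase_late,
      fisher_p = p, untestable = is.na(p),
      stringsAsFactors = FALSE
    )
    ok <- !res$untestable
    res$fdr <- NA_real_
    if (any(ok)) res$fdr[ok] <- bh_adjust(res$fisher_p[ok])
    out[[tis]] <- res
  }
  if (length(out) == 0L) {
    stop("dev_ase: no gene has ASE at either timepoint in a matched tissue")
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res <- classify_temporal(res, fdr = fdr)
  class(res) <- c("diff_ase_results", "data.frame")
  res
}

#' Label the temporal pattern of differential ASE
#'
#' @param res A data.frame with columns `fdr`, `lfc_early`, `lfc_late`,
#'   `ase_early`, `ase_late` (as built by [dev_ase()]).
#' @param fdr Significance threshold on the BH-adjusted Fisher p.
#' @return `res` with `bias`, `mode` and `lfc_tie` columns added.
#' @export
classify_temporal <- function(res, fdr = 0.05) {
  sig <- !is.na(res$fdr) & res$fdr < fdr
  res$lfc_tie <- sig & abs(res$lfc_early) == abs(res$lfc_late)
  res$bias <- ifelse(!sig, "no_change",
                     ifelse(abs(res$lfc_early) > abs(res$lfc_late),
                            "early_bias", "late_bias"))
  res$mode <- ifelse(!sig, "none",
                     ifelse(res$ase_early & res$ase_late, "magnitude_change",
                            ifelse(xor(res$ase_early, res$ase_late),
                                   "timepoint_specific", "none")))
  if (any(res$lfc_tie)) {
    pipeline_log("dev_ase", sprintf("%d |lfc| tie(s) assigned late_bias",
                                    sum(res$lfc_tie)))
  }
  res
}
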