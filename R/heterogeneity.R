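# Bayesian model comparison for multi-tissue ASE heterogeneity. Each included
# tissue is in one of three latent states (N/M/S); a gene's configuration is
# the vector of states across its included tissues. With a uniform prior over
# the 3^T configurations the posterior factorizes across tissues, so class
# posteriors are computed from per-tissue state posteriors in closed form;
# a user-supplied configuration prior falls back to exhaustive enumeration.
#
# Classes partition all configurations:
#   NOASE        all tissues N
#   UNIFORM_ASE  all M or all S
#   HET0         at least one ASE tissue (M or S) and at least one N
#   HET1         all tissues ASE (M or S) but states not all equal

HET_CLASSES <- c("NOASE", "UNIFORM_ASE", "HET0", "HET1")

# class label of one configuration (character vector over tissues)
configuration_class <- function(s) {
  if (all(s == "N")) return("NOASE")
  if (all(s == "M") || all(s == "S")) return("UNIFORM_ASE")
  if (any(s == "N")) return("HET0")
  "HET1"
}

#' Classify one gene's multi-tissue ASE pattern
#'
#' Computes the posterior distribution over per-tissue ASE-state
#' configurations from allelic counts summed across replicates. Tissues where
#' either allele has `min_reads` or fewer reads are excluded; genes with
#' fewer than two remaining tissues are unclassifiable.
#'
#' @param marine,freshwater Integer vectors of summed allelic counts, one
#'   entry per candidate tissue.
#' @param tissues Character vector of tissue labels (same length).
#' @param priors Prior specification, see [ase_priors()].
#' @param min_reads Per-allele depth cutoff for tissue inclusion (a tissue is
#'   kept only if both alleles exceed this; default 10).
#' @param config_prior `NULL` for a uniform prior over the 3^T configurations
#'   (default; posterior then factorizes across tissues), or a function
#'   `f(states)` returning an unnormalized prior weight for a configuration,
#'   in which case all 3^T configurations are enumerated (T <= 12).
#' @return A list (class `gene_classification`): `classifiable`, included
#'   `tissues`, `state_posterior` (tissues x states matrix), `class_pp`
#'   (posterior probability of each class), `pp_heterogeneity`,
#'   `tissue_specific_pp` and `tissue_specific_noase_pp` (per tissue), `map`
#'   (MAP configuration, ties broken N < M < S and flagged in `map_tied`).
#' @export
classify_gene <- function(marine, freshwater, tissues = NULL,
                          priors = ase_priors(), min_reads = 10,
                          config_prior = NULL) {
  stopifnot(length(marine) == length(freshwater))
  if (is.null(tissues)) tissues <- paste0("t", seq_along(marine))
  keep <- marine > min_reads & freshwater > min_reads
  res <- list(classifiable = FALSE, tissues = tissues[keep],
              excluded_tissues = tissues[!keep])
  class(res) <- "gene_classification"
  if (sum(keep) < 2L) return(res)

  x <- marine[keep]; n <- marine[keep] + freshwater[keep]
  tis <- tissues[keep]
  T <- length(x)
  L <- vapply(ASE_STATES, function(s) log_marginal(x, n, s, priors),
              numeric(T))
  L <- matrix(L, nrow = T, dimnames = list(tis, ASE_STATES))

  if (is.null(config_prior)) {
    # uniform configuration prior: posterior factorizes across tissues
    q <- t(apply(L, 1L, function(row) {
      w <- exp(row - logsumexp(row)); w / sum(w)
    }))
    dimnames(q) <- dimnames(L)
    qN <- q[, "N"]; qM <- q[, "M"]; qS <- q[, "S"]
    p_noase <- prod(qN)
    p_allase <- prod(1 - qN)
    p_allM <- prod(qM); p_allS <- prod(qS)
    class_pp <- c(
      NOASE = p_noase,
      UNIFORM_ASE = p_allM + p_allS,
      HET0 = 1 - p_noase - p_allase,
      HET1 = p_allase - p_allM - p_allS
    )
    class_pp <- pmax(class_pp, 0)
    ts_pp <- vapply(seq_len(T), function(t) {
      (qM[t] + qS[t]) * prod(qN[-t])
    }, numeric(1))
    ts_noase_pp <- vapply(seq_len(T), function(t) {
      qN[t] * prod((1 - qN)[-t])
    }, numeric(1))
    map_idx <- apply(L, 1L, which.max)   # which.max: first max = N < M < S order
    map_tied <- apply(L, 1L, function(row) sum(row == max(row)) > 1L)
  } else {
    if (T > 12L) stop("classify_gene: enumeration limited to 12 tissues")
    cfg <- as.matrix(expand.grid(rep(list(1:3), T))[, T:1, drop = FALSE])
    logpost <- apply(cfg, 1L, function(sidx) {
      sum(L[cbind(seq_len(T), sidx)]) +
        log(config_prior(ASE_STATES[sidx]))
    })
    post <- exp(logpost - logsumexp(logpost))
    post <- post / sum(post)
    cls <- apply(cfg, 1L, function(sidx) configuration_class(ASE_STATES[sidx]))
    class_pp <- vapply(HET_CLASSES, function(cl) sum(post[cls == cl]), 0)
    q <- vapply(1:3, function(s) {
      vapply(seq_len(T), function(t) sum(post[cfg[, t] == s]), 0)
    }, numeric(T))
    q <- matrix(q, nrow = T, dimnames = list(tis, ASE_STATES))
    ts_pp <- vapply(seq_len(T), function(t) {
      sum(post[cfg[, t] > 1L & rowSums(cfg[, -t, drop = FALSE] > 1L) == 0L])
    }, numeric(1))
    ts_noase_pp <- vapply(seq_len(T), function(t) {
      sum(post[cfg[, t] == 1L & rowSums(cfg[, -t, drop = FALSE] == 1L) == 0L])
    }, numeric(1))
    best <- cfg[which.max(post), ]
    map_idx <- best
    map_tied <- rep(sum(post == max(post)) > 1L, T)
  }

  res$classifiable <- TRUE
  res$counts <- data.frame(tissue = tis, marine = x, total = n)
  res$state_posterior <- q
  res$class_pp <- class_pp
  res$pp_heterogeneity <- unname(class_pp["HET0"] + class_pp["HET1"])
  res$tissue_specific_pp <- stats::setNames(ts_pp, tis)
  res$tissue_specific_noase_pp <- stats::setNames(ts_noase_pp, tis)
  res$map <- stats::setNames(ASE_STATES[map_idx], tis)
  res$map_tied <- any(map_tied)
  res
}

#' @export
print.gene_classification <- function(x, ...) {
  if (!x$classifiable) {
    cat("Unclassifiable gene (fewer than 2 tissues above depth cutoff)\n")
    return(invisible(x))
  }
  cat("Tissues:", paste(x$tissues, collapse = ", "), "\n")
  cat("Class PP:", paste(sprintf("%s=%.3f", names(x$class_pp), x$class_pp),
                         collapse = " "), "\n")
  cat("MAP:", paste(x$map, collapse = ""), "\n")
  invisible(x)
}

#' Classify every gene in an allelic count table
#'
#' Sums counts across replicates within each analysis unit (tissue or
#' tissue-timepoint), applies the depth filter, and runs [classify_gene()]
#' per gene. Two presets mirror the usual analyses: `tissues = "late"`
#' restricts to timepoint-2 units (one unit per tissue); `tissues = "all"`
#' uses every tissue-timepoint unit.
#'
#' @param counts An `allelic_counts` data.frame.
#' @param priors Prior specification.
#' @param tissues `"late"`, `"all"`, or a character vector of unit labels
#'   (`tissue@timepoint`) to include.
#' @param min_reads Per-allele depth cutoff (default 10).
#' @param thresholds Posterior-probability call thresholds (default 0.9, 0.95).
#' @param config_prior See [classify_gene()].
#' @return A list (class `classification_table`) with `table` (one row per
#'   classifiable gene: class PPs, heterogeneity PP, MAP string, best class at
#'   each threshold, max tissue-specific PP and its tissue), `summary` (class
#'   counts at each threshold), and `unclassifiable` (gene ids).
#' @export
classify_all <- function(counts, priors = ase_priors(), tissues = "late",
                         min_reads = 10, thresholds = c(0.9, 0.95),
                         config_prior = NULL) {
  counts <- as.data.frame(counts)
  counts$unit <- paste(counts$tissue, counts$timepoint, sep = "@")
  if (identical(tissues, "late")) {
    counts <- counts[counts$timepoint == 2L, ]
    counts$unit <- counts$tissue
  } else if (!identical(tissues, "all")) {
    counts <- counts[counts$unit %in% tissues, ]
  }
  if (nrow(counts) == 0L) stop("classify_all: no counts left after unit selection")
  pooled <- stats::aggregate(
    counts[, c("marine_count", "freshwater_count")],
    by = list(gene_id = counts$gene_id, unit = counts$unit), FUN = sum)

  genes <- sort(unique(pooled$gene_id))
  rows <- vector("list", length(genes))
  unclassifiable <- character(0)
  for (i in seq_along(genes)) {
    g <- pooled[pooled$gene_id == genes[i], ]
    cl <- classify_gene(g$marine_count, g$freshwater_count, g$unit,
                        priors = priors, min_reads = min_reads,
                        config_prior = config_prior)
    if (!cl$classifiable) {
      unclassifiable <- c(unclassifiable, genes[i])
      next
    }
    ts_best <- which.max(cl$tissue_specific_pp)
    rows[[i]] <- data.frame(
      gene_id = genes[i],
      n_tissues = length(cl$tissues),
      pp_noase = cl$class_pp[["NOASE"]],
      pp_uniform = cl$class_pp[["UNIFORM_ASE"]],
      pp_het0 = cl$class_pp[["HET0"]],
      pp_het1 = cl$class_pp[["HET1"]],
      pp_het = cl$pp_heterogeneity,
      map = paste(cl$map, collapse = ""),
      map_tied = cl$map_tied,
      best_class = HET_CLASSES[which.max(cl$class_pp)],
      best_class_pp = max(cl$class_pp),
      ts_tissue = names(cl$tissue_specific_pp)[ts_best],
      ts_pp = unname(cl$tissue_specific_pp[ts_best]),
      stringsAsFactors = FALSE
    )
  }
  tab <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(tab) || nrow(tab) == 0L) {
    stop("classify_all: no classifiable genes (all below depth cutoff)")
  }
  rownames(tab) <- NULL
  summary <- do.call(rbind, lapply(thresholds, function(th) {
    called <- tab[tab$best_class_pp > th, ]
    data.frame(threshold = th,
               class = HET_CLASSES,
               n = vapply(HET_CLASSES, function(cl) sum(called$best_class == cl), 0L),
               n_het = sum(tab$pp_het > th),
               n_tissue_specific = sum(tab$ts_pp > th),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  structure(list(table = tab, summary = summary,
                 unclassifiable = unclassifiable,
                 thresholds = thresholds),
            class = "classification_table")
}
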