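# Gene-set sign test for lineage-specific selection on cis-regulation.
# Genes with ASE are divided by the upregulated allele (freshwater_up vs
# marine_up, from the sign of the allelic lfc); each gene set is tested for
# directional bias against the background of all direction-assigned ASE genes
# with a two-sided Fisher's exact test; significance is calibrated by
# shuffling the gene -> set assignment (directions fixed) and, for tissue
# groups, corroborated by combining per-tissue Fisher p-values with Fisher's
# method.

#' Assign per-gene ASE directions for a tissue or tissue group
#'
#' For a single tissue the direction is the sign of the allelic lfc among ASE
#' genes (`lfc > 0` marine_up, `lfc < 0` freshwater_up). For a group, a gene
#' keeps the shared sign of its ASE tissues; genes whose sign differs between
#' member tissues are discarded (`reason = "sign-conflict"`), as are genes
#' with an exactly zero lfc (`reason = "zero-lfc"`).
#'
#' @param ase An `ase_results` data.frame from [call_ase()].
#' @param tissues Character vector of tissue names forming the analysis unit.
#' @param timepoint Timepoint of the unit (default 2, late).
#' @return A data.frame (class `direction_table`) with `gene_id`,
#'   `direction`, `discarded`, `reason`.
#' @export
assign_directions <- function(ase, tissues, timepoint = 2L) {
  rows <- ase[ase$tissue %in% tissues & ase$timepoint == timepoint & ase$is_ase, ]
  if (nrow(rows) == 0L) {
    return(structure(data.frame(gene_id = character(0), direction = character(0),
                                discarded = logical(0), reason = character(0),
                                stringsAsFactors = FALSE),
                     class = c("direction_table", "data.frame")))
  }
  sgn <- split(sign(rows$lfc), rows$gene_id)
  gene_id <- names(sgn)
  dir <- character(length(sgn)); disc <- logical(length(sgn))
  reason <- rep(NA_character_, length(sgn))
  for (i in seq_along(sgn)) {
    s <- unique(sgn[[i]])
    if (any(s == 0)) { disc[i] <- TRUE; reason[i] <- "zero-lfc" }
    else if (length(s) > 1L) { disc[i] <- TRUE; reason[i] <- "sign-conflict" }
    else dir[i] <- if (s > 0) "marine_up" else "freshwater_up"
  }
  dir[disc] <- NA_character_
  out <- data.frame(gene_id = gene_id, direction = dir, discarded = disc,
                    reason = reason, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("direction_table", "data.frame")
  out
}

# internal: keep assigned genes only
.assigned <- function(directions) {
  directions[!directions$discarded, c("gene_id", "direction")]
}

#' Sign test for one gene set
#'
#' Two-sided Fisher's exact test on
#' \code{rbind(c(k_fw, k_m), c(K_fw - k_fw, K_m - k_m))} where the k's count
#' freshwater-up / marine-up directions among set members with assigned
#' directions and the K's count the background (all direction-assigned ASE
#' genes in the unit). Sets with fewer than `min_members` assigned members
#' are skipped.
#'
#' @param members Character vector of the set's gene ids.
#' @param directions A `direction_table` from [assign_directions()].
#' @param min_members Minimum assigned members (default 10).
#' @param exclude_set_from_background If `TRUE`, the set's own genes are
#'   removed from the background margins (default `FALSE`: standard 2x2
#'   construction with the set included in the totals).
#' @return One-row data.frame with counts, `fisher_p`, `skipped`, `reason`.
#' @export
set_sign_test <- function(members, directions, min_members = 10,
                          exclude_set_from_background = FALSE) {
  asg <- .assigned(directions)
  if (nrow(asg) == 0L) stop("set_sign_test: empty background (no assigned genes)")
  in_set <- asg$gene_id %in% members
  k_fw <- sum(in_set & asg$direction == "freshwater_up")
  k_m <- sum(in_set & asg$direction == "marine_up")
  K_fw <- sum(asg$direction == "freshwater_up")
  K_m <- sum(asg$direction == "marine_up")
  if (exclude_set_from_background) { K_fw <- K_fw - k_fw; K_m <- K_m - k_m }
  n_assigned <- k_fw + k_m
  if (n_assigned < min_members) {
    return(data.frame(k_freshwater_up = k_fw, k_marine_up = k_m,
                      K_freshwater_up = K_fw, K_marine_up = K_m,
                      fisher_p = NA_real_, skipped = TRUE,
                      reason = "min-members", stringsAsFactors = FALSE))
  }
  bg_fw <- if (exclude_set_from_background) K_fw else K_fw - k_fw
  bg_m <- if (exclude_set_from_background) K_m else K_m - k_m
  p <- fisher_exact_2x2(k_fw, k_m, bg_fw, bg_m)
  data.frame(k_freshwater_up = k_fw, k_marine_up = k_m,
             K_freshwater_up = if (exclude_set_from_background) K_fw + k_fw else K_fw,
             K_marine_up = if (exclude_set_from_background) K_m + k_m else K_m,
             fisher_p = p, skipped = FALSE, reason = NA_character_,
             stringsAsFactors = FALSE)
}

#' Sign test over a collection of gene sets
#'
#' @param sets A `gene_sets` list (named list of member vectors).
#' @param directions A `direction_table`.
#' @inheritParams set_sign_test
#' @return A data.frame, one row per set, as in [set_sign_test()] plus
#'   `set_id`.
#' @export
sign_test_sets <- function(sets, directions, min_members = 10,
                           exclude_set_from_background = FALSE) {
  rows <- lapply(names(sets), function(id) {
    r <- set_sign_test(sets[[id]], directions, min_members,
                       exclude_set_from_background)
    cbind(data.frame(set_id = id, stringsAsFactors = FALSE), r)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Category-shuffling permutation test for sign-test significance
#'
#' Shuffles the gene -> set assignment map (a single permutation of gene
#' labels per iteration, shared by all sets so overlap structure is
#' preserved; directions stay fixed) and recomputes every eligible set's
#' Fisher p. The permutation p-value is `(b + 1) / (n_perm + 1)` where `b`
#' counts permutations with a Fisher p at most the observed one, so the floor
#' at 10,000 permutations is 1/10001.
#'
#' Because the background margins are fixed under permutation, each set's
#' Fisher p depends only on its freshwater-up member count; p-values are
#' precomputed per set size, making the shuffle loop a table lookup.
#'
#' @param sets A `gene_sets` list.
#' @param directions A `direction_table`.
#' @param n_perm Number of permutations (default 10000).
#' @param seed RNG seed.
#' @param min_members Minimum assigned members per set (default 10).
#' @return A data.frame per set: observed counts, `fisher_p`, `perm_p`,
#'   `n_permutations`, `skipped`.
#' @export
permutation_test <- function(sets, directions, n_perm = 10000, seed = 1,
                             min_members = 10) {
  if (n_perm < 1) stop("permutation_test: n_perm must be >= 1")
  asg <- .assigned(directions)
  if (nrow(asg) == 0L) stop("permutation_test: no assigned genes")
  obs <- sign_test_sets(sets, directions, min_members)
  eligible <- which(!obs$skipped)
  obs$perm_p <- NA_real_
  obs$n_permutations <- ifelse(obs$skipped, NA_integer_, as.integer(n_perm))
  if (length(eligible) == 0L) return(obs)

  fw <- asg$direction == "freshwater_up"
  K_fw <- sum(fw); K_m <- sum(!fw)
  idx_list <- lapply(eligible, function(i) {
    which(asg$gene_id %in% sets[[obs$set_id[i]]])
  })
  sizes <- vapply(idx_list, length, 1L)
  # two-sided Fisher p as a function of k_fw, per distinct set size; k values
  # outside the feasible hypergeometric support can never occur
  ptab <- lapply(sort(unique(sizes)), function(m) {
    p <- rep(NA_real_, m + 1)
    k <- max(0, m - K_m):min(m, K_fw)
    p[k + 1] <- fisher_exact_2x2(k, m - k, K_fw - k, K_m - (m - k))
    p
  })
  names(ptab) <- as.character(sort(unique(sizes)))
  obs_p <- obs$fisher_p[eligible]
  b <- integer(length(eligible))
  with_seed(seed, {
    for (r in seq_len(n_perm)) {
      fwp <- fw[sample.int(length(fw))]
      for (j in seq_along(idx_list)) {
        k <- sum(fwp[idx_list[[j]]])
        if (ptab[[as.character(sizes[j])]][k + 1L] <= obs_p[j] * (1 + 1e-12)) {
          b[j] <- b[j] + 1L
        }
      }
    }
  })
  obs$perm_p[eligible] <- perm_pvalue(b, n_perm)
  obs
}

#' Combine per-tissue sign-test p-values with Fisher's method
#'
#' @param p Vector of per-tissue Fisher p-values for one category (all > 0;
#'   floor upstream at machine epsilon).
#' @return Combined p-value (chi-square upper tail, df = 2k).
#' @export
combine_group_pvalues <- function(p) {
  fishers_method(p)
}

#' Dual-criterion report for tissue-group sign tests
#'
#' Flags gene sets significant both in the group permutation test and in the
#' combined per-tissue test, i.e. directional bias that is robust to
#' individual-tissue patterns.
#'
#' @param perm_results Data.frame from [permutation_test()] on the grouped
#'   unit (columns `set_id`, `fisher_p`, `perm_p`).
#' @param combined_results Data.frame with `set_id` and `combined_p`.
#' @param alpha Significance level for both criteria (default 0.05).
#' @return Merged data.frame with a logical `flagged` column.
#' @export
dual_criterion_report <- function(perm_results, combined_results, alpha = 0.05) {
  out <- merge(perm_results, combined_results, by = "set_id", all.x = TRUE)
  out$flagged <- !is.na(out$perm_p) & out$perm_p <= alpha &
    !is.na(out$combined_p) & out$combined_p <= alpha
  out[order(out$set_id), , drop = FALSE]
}

#' Full sign-test analysis for a tissue group
#'
#' Runs the grouped-direction permutation sign test, the per-tissue tests
#' combined with Fisher's method (only for categories eligible in every
#' member tissue), and the dual-criterion report.
#'
#' @param ase An `ase_results` data.frame.
#' @param sets A `gene_sets` list.
#' @param tissues Tissues forming the group.
#' @param timepoint Timepoint (default 2).
#' @param n_perm Permutations (default 10000).
#' @param seed RNG seed.
#' @param alpha Significance level (default 0.05).
#' @param min_members Minimum assigned set members (default 10).
#' @return A list with `group` (permutation results), `per_tissue`,
#'   `combined`, and `report`.
#' @export
sign_test_analysis <- function(ase, sets, tissues, timepoint = 2L,
                               n_perm = 10000, seed = 1, alpha = 0.05,
                               min_members = 10) {
  grp_dir <- assign_directions(ase, tissues, timepoint)
  grp <- permutation_test(sets, grp_dir, n_perm = n_perm, seed = seed,
                          min_members = min_members)
  per_tissue <- lapply(tissues, function(tis) {
    d <- assign_directions(ase, tis, timepoint)
    if (nrow(.assigned(d)) == 0L) return(NULL)
    sign_test_sets(sets, d, min_members)
  })
  names(per_tissue) <- tissues
  per_tissue <- per_tissue[!vapply(per_tissue, is.null, TRUE)]
  combined <- data.frame(set_id = names(sets), combined_p = NA_real_,
                         stringsAsFactors = FALSE)
  if (length(per_tissue) > 0) {
    for (i in seq_len(nrow(combined))) {
      ps <- vapply(per_tissue, function(tab) {
        tab$fisher_p[tab$set_id == combined$set_id[i]]
      }, numeric(1))
      if (!anyNA(ps)) {   # eligible in every member tissue
        combined$combined_p[i] <- fishers_method(pmax(ps, .Machine$double.xmin))
      }
    }
  }
  report <- dual_criterion_report(grp, combined, alpha = alpha)
  list(group = grp, per_tissue = per_tissue, combined = combined,
       report = report)
}
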