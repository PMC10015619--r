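# End-to-end orchestration: a single flat config drives
# simulate -> ase-call -> heterogeneity -> dev-ase -> sign-test -> enrichment,
# with deterministic seeding, stage-tagged logging and a run manifest.

u_stop <- function(...) {
  stop(structure(class = c("hybridase_user_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' Default pipeline configuration
#'
#' All tuning constants of the pipeline in one place: FDR threshold 0.05,
#' posterior-probability call thresholds 0.9 and 0.95, per-allele depth
#' cutoff 10, minimum 10 assigned members per gene set, 10,000 permutations,
#' 1,000 resampling draws, density-bin occupancy 23.
#'
#' @return A named list (class `pipeline_config`).
#' @export
default_pipeline_config <- function() {
  structure(list(
    counts = NULL, sites = NULL, genes_bed = NULL, css_bed = NULL,
    ecopeaks_bed = NULL, qtl_bed = NULL, sets = NULL, orthologs = NULL,
    out_dir = "hybridase_out",
    simulate = FALSE, n_genes = 2000,
    fdr_threshold = 0.05,
    pp_thresholds = c(0.9, 0.95),
    min_reads_per_allele = 10,
    min_set_members = 10,
    n_perm = 10000,
    n_resample = 1000,
    bin_occupancy = 23,
    seed = 1,
    test = "binomial",
    group_name = "dental",
    group_tissues = c("VTP", "DTP", "mandible"),
    verbose = TRUE
  ), class = "pipeline_config")
}

#' Read a flat key-value pipeline config file
#'
#' One `key: value` (or `key = value`) pair per line; `#` starts a comment.
#' Values are parsed as numbers, `true`/`false`, or comma-separated lists;
#' everything else is a string. Unknown keys are an error. CLI flags override
#' config values.
#'
#' @param path Path to the config file.
#' @return A `pipeline_config` list merged over [default_pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) u_stop("config file not found: ", path)
  cfg <- default_pipeline_config()
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*[:=]\\s*(.*)$", ln))[[1]]
    if (length(m) != 3) u_stop("config: cannot parse line: ", ln)
    key <- m[2]; raw <- trimws(m[3])
    if (!key %in% names(cfg)) u_stop("config: unknown key: ", key)
    parts <- trimws(strsplit(raw, ",")[[1]])
    vals <- suppressWarnings(as.numeric(parts))
    value <- if (!anyNA(vals)) vals
    else if (length(parts) == 1 && tolower(parts) %in% c("true", "false")) {
      tolower(parts) == "true"
    } else parts
    cfg[[key]] <- value
  }
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  if (cfg$fdr_threshold <= 0 || cfg$fdr_threshold >= 1) {
    u_stop("config: fdr_threshold must lie in (0, 1)")
  }
  if (any(cfg$pp_thresholds <= 0 | cfg$pp_thresholds >= 1)) {
    u_stop("config: pp_thresholds must lie in (0, 1)")
  }
  for (key in c("min_reads_per_allele", "min_set_members", "n_perm",
                "n_resample", "bin_occupancy", "n_genes")) {
    if (cfg[[key]] < 1 || cfg[[key]] != floor(cfg[[key]])) {
      u_stop("config: ", key, " must be a positive integer")
    }
  }
  cfg
}

.require_inputs <- function(cfg, keys) {
  for (key in keys) {
    p <- cfg[[key]]
    if (is.null(p)) u_stop("config: required input '", key, "' not set")
    if (!file.exists(p)) u_stop("input file not found: ", p, " (", key, ")")
  }
}

#' Run the full pipeline
#'
#' Executes every stage from a single config and writes all outputs plus a
#' JSON run manifest (package version, seed, config hash, per-stage row
#' counts, and a combined md5 over all outputs — identical across reruns
#' with the same config and seed). When `simulate` is true the input files
#' are first generated under `out_dir/sim` and the remaining stages consume
#' them; otherwise every input path is validated before any stage runs.
#'
#' @param config A `pipeline_config` list ([default_pipeline_config()] or
#'   [read_pipeline_config()]).
#' @return The manifest, invisibly.
#' @export
run_all <- function(config) {
  cfg <- validate_pipeline_config(config)
  # fail fast on missing inputs before touching the filesystem
  if (!isTRUE(cfg$simulate)) {
    .require_inputs(cfg, c("counts", "sites", "genes_bed", "css_bed",
                           "ecopeaks_bed", "qtl_bed", "sets", "orthologs"))
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  vb <- isTRUE(cfg$verbose)
  stage <- function(name, expr) {
    pipeline_log(name, "start", verbose = vb)
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  manifest <- list(package = "hybridase",
                   version = as.character(utils::packageVersion("hybridase")),
                   seed = cfg$seed, stages = list())

  if (isTRUE(cfg$simulate)) {
    stage("simulate", {
      sim <- simulate_experiment(simulation_config(
        n_genes = cfg$n_genes, seed = cfg$seed))
      simdir <- file.path(cfg$out_dir, "sim")
      write_simulation(sim, simdir)
      cfg$counts <- file.path(simdir, "counts.tsv")
      cfg$sites <- file.path(simdir, "sites.tsv")
      cfg$genes_bed <- file.path(simdir, "genes.bed")
      cfg$css_bed <- file.path(simdir, "css_windows.bed")
      cfg$ecopeaks_bed <- file.path(simdir, "ecopeaks.bed")
      cfg$qtl_bed <- file.path(simdir, "qtl.bed")
      cfg$sets <- file.path(simdir, "gene_sets.tsv")
      cfg$orthologs <- file.path(simdir, "orthologs.tsv")
      manifest$stages$simulate <- list(n_genes = cfg$n_genes)
    })
  }
  .require_inputs(cfg, c("counts", "sites", "genes_bed", "css_bed",
                         "ecopeaks_bed", "qtl_bed", "sets", "orthologs"))
  outputs <- character(0)
  emit <- function(tab, name) {
    p <- file.path(cfg$out_dir, name)
    write_results_tsv(tab, p)
    outputs <<- c(outputs, p)
    p
  }

  counts <- stage("read", read_allelic_counts(cfg$counts))
  ase <- stage("ase-call", {
    r <- call_ase(counts, fdr = cfg$fdr_threshold, test = cfg$test)
    emit(r, "ase_results.tsv")
    s <- summarize_ase(r)
    emit(s$per_tissue, "ase_summary.tsv")
    emit(s$gene_profiles, "ase_gene_profiles.tsv")
    manifest$stages$ase_call <- list(n_rows = nrow(r), n_ase = sum(r$is_ase))
    r
  })

  stage("heterogeneity", {
    cl <- classify_all(counts, tissues = "late",
                       min_reads = cfg$min_reads_per_allele,
                       thresholds = cfg$pp_thresholds)
    emit(cl$table, "heterogeneity.tsv")
    emit(cl$summary, "heterogeneity_summary.tsv")
    manifest$stages$heterogeneity <- list(
      n_classified = nrow(cl$table),
      n_unclassifiable = length(cl$unclassifiable))
  })

  if (any(counts$timepoint == 1L) && any(counts$timepoint == 2L)) {
    stage("dev-ase", {
      d <- dev_ase(counts, ase, fdr = cfg$fdr_threshold)
      emit(d, "dev_ase.tsv")
      manifest$stages$dev_ase <- list(
        n_tested = sum(!d$untestable),
        n_significant = sum(d$bias != "no_change"))
    })
  } else {
    pipeline_log("dev-ase", "skipped: only one timepoint present", verbose = vb)
  }

  stage("sign-test", {
    sets <- read_gene_sets(cfg$sets, cfg$orthologs)
    st <- sign_test_analysis(ase, sets, tissues = cfg$group_tissues,
                             n_perm = cfg$n_perm,
                             seed = derive_seed(cfg$seed, "sign-test"),
                             alpha = cfg$fdr_threshold,
                             min_members = cfg$min_set_members)
    emit(st$report, "sign_test.tsv")
    manifest$stages$sign_test <- list(
      n_sets = length(sets), n_flagged = sum(st$report$flagged))
  })

  stage("enrichment", {
    genes <- read_bed(cfg$genes_bed, "gene")
    css <- read_bed(cfg$css_bed, "css_window")
    peaks <- read_bed(cfg$ecopeaks_bed, "ecopeak")
    qtl <- read_bed(cfg$qtl_bed, "qtl")
    sites <- filter_sites(read_site_counts(cfg$sites))$sites
    summ <- annotate_genes(genes, css, peaks, sites)
    ase_flag <- summ$gene_id %in% unique(ase$gene_id[ase$is_ase])
    binned <- bin_by_density(summ, ase_flag,
                             target_bin_occupancy = cfg$bin_occupancy,
                             verbose = vb)
    zt <- binned_permutation_test(binned, n_perm = cfg$n_perm,
                                  seed = derive_seed(cfg$seed, "css-perm"))
    emit(zt$per_bin, "css_bins.tsv")
    pk <- ecopeak_enrichment(summ, ase_flag, n_resample = cfg$n_resample,
                             seed = derive_seed(cfg$seed, "ecopeak"),
                             target_bin_occupancy = cfg$bin_occupancy)
    ch <- chromosome_enrichment(summ, ase_flag, n_resample = cfg$n_resample,
                                seed = derive_seed(cfg$seed, "chrom"),
                                target_bin_occupancy = cfg$bin_occupancy)
    emit(ch, "chromosome_enrichment.tsv")
    cand <- candidate_table(ase, summ, genes, qtl)
    emit(cand, "candidates.tsv")
    manifest$stages$enrichment <- list(
      css_perm_p = zt$perm_p, css_observed = zt$observed,
      ecopeak_fold = pk$fold, ecopeak_p = pk$p,
      n_candidates = nrow(cand))
  })

  md5s <- tools::md5sum(sort(outputs))
  manifest$outputs <- as.list(md5s)
  manifest$output_md5 <- as.character(
    tools::md5sum(textConnection2file(paste(md5s, collapse = ""))))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# write a string to a temp file and return its path (for hashing)
textConnection2file <- function(x) {
  f <- tempfile()
  writeLines(x, f)
  f
}
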