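# Synthetic-data generator: a complete stand-in for a two-ecotype F1-hybrid
# ASE experiment with known ground truth. The default design mirrors the
# emulated study: 7 tissues sampled at a late timepoint, of which 3 dental
# tissues are additionally sampled early, 2 replicates each; allelic counts
# are beta-binomial (theta drawn once per gene-tissue from the state prior,
# shared across replicates); a toy genome carries CSS windows, divergence
# peaks with configurable ASE-gene enrichment, and QTL intervals; one gene
# set is direction-biased, the rest are null.

#' Default tissue design
#'
#' Seven late-timepoint tissues; the three dental tissues (ventral tooth
#' plate, dorsal tooth plate, mandible) also sampled at the early timepoint.
#'
#' @return data.frame with columns `name`, `timepoint`.
#' @export
default_tissue_design <- function() {
  data.frame(
    name = c("brain", "eye", "liver", "skin", "VTP", "DTP", "mandible",
             "VTP", "DTP", "mandible"),
    timepoint = c(rep(2L, 7), rep(1L, 3)),
    stringsAsFactors = FALSE
  )
}

SIM_CLASSES <- c("NOASE", "UNIFORM_ASE", "HET0", "HET1", "TISSUE_SPECIFIC")

#' Build and validate a simulation configuration
#'
#' Defaults state the emulated world once: gene-wise ASE classes in
#' proportions giving ~40% of genes some ASE (of which roughly half are
#' heterogeneous), overdispersed sequencing depth, a 0.5-probability marine
#' direction applied gene-wide, and a toy genome in which ~10% of the
#' sequence lies in divergence peaks where ASE genes are placed at 2-fold
#' enrichment and CSS Z-scores are shifted upward.
#'
#' @param n_genes Number of genes (default 2000).
#' @param tissues data.frame(name, timepoint) of analysis units.
#' @param n_replicates Replicates per unit (default 2).
#' @param depth_mean Mean total reads per gene per replicate (negative
#'   binomial; default 100).
#' @param depth_dispersion Negative-binomial size parameter (default 2;
#'   larger = closer to Poisson).
#' @param class_proportions Named probabilities over
#'   NOASE/UNIFORM_ASE/HET0/HET1/TISSUE_SPECIFIC (must sum to 1).
#' @param priors State priors used to draw theta (default [ase_priors()]).
#' @param fixed_theta Optional named vector `c(M = , S = )` of fixed
#'   marine-up allelic fractions replacing prior draws for ASE states.
#' @param timepoint_switch_prob Probability a dental gene toggles its ASE
#'   state between timepoints (default 0.25).
#' @param biased_set_size,biased_set_direction_bias Size and
#'   freshwater-direction probability of the planted direction-biased set
#'   (defaults 30 and 0.9).
#' @param n_null_sets,null_set_size_range Number and size range of the
#'   random (null) gene sets.
#' @param n_chromosomes Chromosomes in the toy genome (default 5).
#' @param gene_length_meanlog,gene_length_sdlog Log-normal gene length
#'   parameters (default median 2 kb).
#' @param het_density_shape,het_density_mean Gamma distribution of per-gene
#'   het-site density per bp (default mean 0.005, i.e. ~1 site / 200 bp).
#' @param css_window_size CSS window size in bp (default 2500).
#' @param frac_genome_in_peaks Fraction of CSS windows inside divergence
#'   peaks (default 0.1).
#' @param peak_z_shift Z-score shift added to windows inside peaks
#'   (default 1.5).
#' @param ase_peak_enrichment Fold enrichment of ASE genes inside peaks
#'   (default 2).
#' @param n_qtl_per_chrom QTL intervals per chromosome (default 3).
#' @param seed Single global seed; every sub-stream derives from it.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 2000,
                              tissues = default_tissue_design(),
                              n_replicates = 2,
                              depth_mean = 100,
                              depth_dispersion = 2,
                              class_proportions = c(NOASE = 0.60,
                                                    UNIFORM_ASE = 0.10,
                                                    HET0 = 0.12,
                                                    HET1 = 0.08,
                                                    TISSUE_SPECIFIC = 0.10),
                              priors = ase_priors(),
                              fixed_theta = NULL,
                              timepoint_switch_prob = 0.25,
                              biased_set_size = 30,
                              biased_set_direction_bias = 0.9,
                              n_null_sets = 20,
                              null_set_size_range = c(10, 50),
                              n_chromosomes = 5,
                              gene_length_meanlog = log(2000),
                              gene_length_sdlog = 0.5,
                              het_density_shape = 2,
                              het_density_mean = 0.005,
                              css_window_size = 2500,
                              frac_genome_in_peaks = 0.1,
                              peak_z_shift = 1.5,
                              ase_peak_enrichment = 2,
                              n_qtl_per_chrom = 3,
                              seed = 1) {
  cfg <- as.list(environment())
  if (!all(SIM_CLASSES %in% names(class_proportions))) {
    stop("class_proportions must name all of: ", paste(SIM_CLASSES, collapse = ", "))
  }
  if (abs(sum(class_proportions) - 1) > 1e-9) {
    stop("class_proportions must sum to 1")
  }
  probs <- c(class_proportions, timepoint_switch_prob,
             biased_set_direction_bias, frac_genome_in_peaks)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (n_genes < 1 || n_replicates < 1 || n_chromosomes < 1) {
    stop("n_genes, n_replicates, n_chromosomes must be positive")
  }
  if (depth_mean <= 0 || depth_dispersion <= 0) stop("depth model must be positive")
  validate_priors(priors)
  class(cfg) <- "simulation_config"
  cfg
}

# Draw theta for one (state, direction): from the direction-consistent prior
# component, or the fixed magnitude when configured. Direction is the
# marine-up/freshwater-up side; N is direction-free.
.draw_theta <- function(state, direction, cfg) {
  if (state == "N") {
    comp <- cfg$priors$N
    k <- sample.int(nrow(comp), 1, prob = comp$weight)
    return(stats::rbeta(1, comp$alpha[k], comp$beta[k]))
  }
  if (!is.null(cfg$fixed_theta)) {
    th <- cfg$fixed_theta[[state]]
    return(if (direction == "marine_up") th else 1 - th)
  }
  comp <- cfg$priors[[state]]
  up <- comp$alpha > comp$beta          # marine-up components
  sub <- if (direction == "marine_up") comp[up, , drop = FALSE] else comp[!up, , drop = FALSE]
  if (nrow(sub) == 0L) sub <- comp
  k <- sample.int(nrow(sub), 1, prob = sub$weight / sum(sub$weight))
  stats::rbeta(1, sub$alpha[k], sub$beta[k])
}

# Late-timepoint state vector for one gene given its class; T = #late tissues
.draw_states <- function(cls, T) {
  ms <- function(n) sample(c("M", "S"), n, replace = TRUE)
  switch(cls,
    NOASE = rep("N", T),
    UNIFORM_ASE = rep(sample(c("M", "S"), 1), T),
    HET0 = {
      k <- if (T > 2) resample(2:(T - 1), 1) else T - 1   # >=1 ASE, >=1 N
      s <- rep("N", T)
      s[sample.int(T, k)] <- ms(k)
      s
    },
    HET1 = {
      kS <- resample(seq_len(T - 1), 1)                   # mixed M/S, all ASE
      s <- rep("M", T)
      s[sample.int(T, kS)] <- "S"
      s
    },
    TISSUE_SPECIFIC = {
      s <- rep("N", T)
      s[sample.int(T, 1)] <- ms(1)
      s
    })
}

#' Simulate a complete F1-hybrid ASE experiment
#'
#' Generates allelic counts, a site-level count table, a toy genome (gene,
#' CSS-window, EcoPeak and QTL intervals), gene sets (one planted
#' direction-biased set plus null sets), and ground-truth tables. All
#' randomness derives from `config$seed`; the same config yields identical
#' output.
#'
#' @param config A `simulation_config`.
#' @return A list: `counts` (allelic_counts), `sites` (site_counts), `genes`,
#'   `css_windows`, `ecopeaks`, `qtl` (interval_sets), `sets` (gene_sets),
#'   `truth` (list of `genes` and `unit_states` data.frames), `config`.
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, .simulate_experiment(config))
}

.simulate_experiment <- function(cfg) {
  n <- cfg$n_genes
  gene_id <- sprintf("g%05d", seq_len(n))
  tis <- cfg$tissues
  units <- paste(tis$name, tis$timepoint, sep = "@")
  late_idx <- which(tis$timepoint == 2L)
  early_idx <- which(tis$timepoint == 1L)
  T_late <- length(late_idx)
  if (T_late < 2L) stop("simulate_experiment: need >= 2 late tissues")

  cls <- sample(SIM_CLASSES, n, replace = TRUE,
                prob = cfg$class_proportions[SIM_CLASSES])
  direction <- sample(c("marine_up", "freshwater_up"), n, replace = TRUE)

  # per-gene per-unit latent state and theta
  state <- matrix("N", nrow = n, ncol = nrow(tis),
                  dimnames = list(gene_id, units))
  theta <- matrix(NA_real_, nrow = n, ncol = nrow(tis),
                  dimnames = list(gene_id, units))
  for (i in seq_len(n)) {
    s_late <- .draw_states(cls[i], T_late)
    state[i, late_idx] <- s_late
    for (j in early_idx) {
      s_l <- s_late[match(tis$name[j], tis$name[late_idx])]
      if (stats::runif(1) < cfg$timepoint_switch_prob) {
        state[i, j] <- if (s_l == "N") sample(c("M", "S"), 1) else "N"
      } else {
        state[i, j] <- s_l
      }
    }
    for (j in seq_len(nrow(tis))) {
      theta[i, j] <- .draw_theta(state[i, j], direction[i], cfg)
    }
  }

  # counts: depth ~ NB per gene/unit/replicate; marine ~ Binomial(depth, theta)
  reps <- seq_len(cfg$n_replicates)
  grid <- expand.grid(rep = reps, unit = seq_len(nrow(tis)),
                      gene = seq_len(n), KEEP.OUT.ATTRS = FALSE)
  depth <- as.integer(stats::rnbinom(nrow(grid), mu = cfg$depth_mean,
                                     size = cfg$depth_dispersion))
  marine <- as.integer(stats::rbinom(nrow(grid), depth,
                                     theta[cbind(grid$gene, grid$unit)]))
  counts <- data.frame(
    gene_id = gene_id[grid$gene],
    tissue = tis$name[grid$unit],
    timepoint = tis$timepoint[grid$unit],
    replicate = grid$rep,
    marine_count = marine,
    freshwater_count = depth - marine,
    stringsAsFactors = FALSE
  )
  counts <- counts[order(counts$gene_id, counts$tissue, counts$timepoint,
                         counts$replicate), ]
  rownames(counts) <- NULL
  class(counts) <- c("allelic_counts", "data.frame")

  # toy genome: gene slots laid out per chromosome, then peak-aware placement
  glen <- pmax(200L, as.integer(round(stats::rlnorm(
    n, cfg$gene_length_meanlog, cfg$gene_length_sdlog))))
  chrom_of_slot <- sort(rep_len(seq_len(cfg$n_chromosomes), n))
  slot_start <- integer(n); slot_end <- integer(n)
  chrom_len <- integer(cfg$n_chromosomes)
  for (ch in seq_len(cfg$n_chromosomes)) {
    idx <- which(chrom_of_slot == ch)
    gaps <- as.integer(round(stats::runif(length(idx), 500, 5000)))
    pos <- 1000L
    for (j in seq_along(idx)) {
      slot_start[idx[j]] <- pos
      pos <- pos + glen[idx[j]]
      slot_end[idx[j]] <- pos
      pos <- pos + gaps[j]
    }
    chrom_len[ch] <- pos + 10000L
  }
  chrom_name <- sprintf("chr%02d", seq_len(cfg$n_chromosomes))

  # CSS windows tile each chromosome; windows are peak members w.p.
  # frac_genome_in_peaks, adjacent peak windows merge into one EcoPeak
  css <- list(); peaks <- list()
  for (ch in seq_len(cfg$n_chromosomes)) {
    starts <- seq(0L, chrom_len[ch] - 1L, by = cfg$css_window_size)
    ends <- pmin(starts + cfg$css_window_size, chrom_len[ch])
    in_pk <- stats::runif(length(starts)) < cfg$frac_genome_in_peaks
    z <- stats::rnorm(length(starts)) + cfg$peak_z_shift * in_pk
    css[[ch]] <- data.frame(chrom = chrom_name[ch], start = starts, end = ends,
                            name = sprintf("%s_w%05d", chrom_name[ch],
                                           seq_along(starts)),
                            score = z, kind = "css_window",
                            stringsAsFactors = FALSE)
    if (any(in_pk)) {
      r <- rle(in_pk)
      hi <- cumsum(r$lengths); lo <- hi - r$lengths + 1L
      sel <- which(r$values)
      peaks[[ch]] <- data.frame(
        chrom = chrom_name[ch],
        start = starts[lo[sel]], end = ends[hi[sel]],
        name = sprintf("%s_pk%03d", chrom_name[ch], seq_along(sel)),
        score = NA_real_, kind = "ecopeak", stringsAsFactors = FALSE)
    }
  }
  css <- do.call(rbind, css)
  peaks <- do.call(rbind, peaks[!vapply(peaks, is.null, TRUE)])
  if (is.null(peaks) || nrow(peaks) == 0L) {
    stop("simulate_experiment: no EcoPeak was placed; increase frac_genome_in_peaks")
  }
  class(css) <- class(peaks) <- c("interval_set", "data.frame")

  # which slots fall inside a peak (any-bp overlap)
  slot_iv <- data.frame(chrom = chrom_name[chrom_of_slot], start = slot_start,
                        end = slot_end, name = sprintf("s%05d", seq_len(n)),
                        score = NA_real_, kind = "gene",
                        stringsAsFactors = FALSE)
  class(slot_iv) <- c("interval_set", "data.frame")
  slot_in_peak <- GenomicRanges::countOverlaps(
    intervals_to_granges(slot_iv), intervals_to_granges(peaks)) > 0L

  # place genes into slots with exact in-peak enrichment of ASE genes
  is_ase_gene <- cls != "NOASE"
  p0 <- mean(slot_in_peak)
  n_ase <- sum(is_ase_gene)
  n_ase_in <- round(min(1, cfg$ase_peak_enrichment * p0) * n_ase)
  if (n_ase_in > sum(slot_in_peak)) {
    stop(sprintf("simulate_experiment: infeasible placement (%d enriched genes, %d in-peak slots)",
                 n_ase_in, sum(slot_in_peak)))
  }
  slot_of_gene <- integer(n)
  in_slots <- which(slot_in_peak); out_slots <- which(!slot_in_peak)
  ase_ids <- which(is_ase_gene)
  ase_in <- resample(ase_ids, n_ase_in)
  ase_out <- setdiff(ase_ids, ase_in)
  slot_of_gene[ase_in] <- resample(in_slots, n_ase_in)
  pick_out <- resample(out_slots, length(ase_out))
  slot_of_gene[ase_out] <- pick_out
  rest_slots <- setdiff(seq_len(n), slot_of_gene[ase_ids])
  noase_ids <- which(!is_ase_gene)
  slot_of_gene[noase_ids] <- resample(rest_slots, length(noase_ids))

  genes <- data.frame(
    chrom = chrom_name[chrom_of_slot[slot_of_gene]],
    start = slot_start[slot_of_gene],
    end = slot_end[slot_of_gene],
    name = gene_id,
    score = NA_real_,
    kind = "gene",
    stringsAsFactors = FALSE
  )
  genes <- genes[order(genes$chrom, genes$start), ]
  rownames(genes) <- NULL
  class(genes) <- c("interval_set", "data.frame")

  # QTL intervals: a few per chromosome, ~5% of the chromosome each
  qtl <- do.call(rbind, lapply(seq_len(cfg$n_chromosomes), function(ch) {
    L <- chrom_len[ch]
    w <- as.integer(round(0.05 * L))
    st <- as.integer(round(stats::runif(cfg$n_qtl_per_chrom, 0, L - w)))
    data.frame(chrom = chrom_name[ch], start = st, end = st + w,
               name = sprintf("%s_qtl%02d", chrom_name[ch],
                              seq_len(cfg$n_qtl_per_chrom)),
               score = NA_real_, kind = "qtl", stringsAsFactors = FALSE)
  }))
  class(qtl) <- c("interval_set", "data.frame")

  # site-level counts: Poisson-placed het sites per gene; pooled gene counts
  # distributed multinomially across the gene's sites
  gl <- genes$end - genes$start
  gidx <- match(genes$name, gene_id)
  dens <- stats::rgamma(n, shape = cfg$het_density_shape,
                        scale = cfg$het_density_mean / cfg$het_density_shape)
  n_sites <- stats::rpois(n, dens * gl)
  tot_m <- tapply(counts$marine_count, counts$gene_id, sum)[genes$name]
  tot_f <- tapply(counts$freshwater_count, counts$gene_id, sum)[genes$name]
  site_rows <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    k <- n_sites[gidx[i]]
    if (k == 0L) next
    pos <- sort(sample.int(gl[i], min(k, gl[i]))) + genes$start[i]  # 1-based
    k <- length(pos)
    sm <- as.integer(stats::rmultinom(1, tot_m[i], rep(1, k)))
    sf <- as.integer(stats::rmultinom(1, tot_f[i], rep(1, k)))
    site_rows[[i]] <- data.frame(chrom = genes$chrom[i], pos = pos,
                                 gene_id = genes$name[i],
                                 marine_count = sm, freshwater_count = sf,
                                 stringsAsFactors = FALSE)
  }
  sites <- do.call(rbind, site_rows[!vapply(site_rows, is.null, TRUE)])
  if (is.null(sites)) {
    sites <- data.frame(chrom = character(0), pos = integer(0),
                        gene_id = character(0), marine_count = integer(0),
                        freshwater_count = integer(0))
  }
  rownames(sites) <- NULL
  class(sites) <- c("site_counts", "data.frame")

  # gene sets: one planted direction-biased set + null sets
  sets <- list()
  fw_pool <- gene_id[is_ase_gene & direction == "freshwater_up"]
  m_pool <- gene_id[is_ase_gene & direction == "marine_up"]
  sz <- cfg$biased_set_size
  n_fw <- stats::rbinom(1, sz, cfg$biased_set_direction_bias)
  if (n_fw > length(fw_pool) || (sz - n_fw) > length(m_pool)) {
    stop("simulate_experiment: not enough ASE genes for the biased set")
  }
  sets[["biased_set"]] <- sort(c(resample(fw_pool, n_fw),
                                 resample(m_pool, sz - n_fw)))
  if (cfg$n_null_sets > 0) {
    null_sets <- .simulate_null_sets(cfg$n_null_sets, cfg$null_set_size_range,
                                     gene_id)
    names(null_sets) <- sprintf("null_%03d", seq_len(cfg$n_null_sets))
    sets <- c(sets, null_sets)
  }
  class(sets) <- "gene_sets"

  truth_genes <- data.frame(
    gene_id = gene_id,
    class = cls,
    config_class = ifelse(cls == "TISSUE_SPECIFIC", "HET0", cls),
    direction = direction,
    chrom = genes$chrom[match(gene_id, genes$name)],
    start = genes$start[match(gene_id, genes$name)],
    end = genes$end[match(gene_id, genes$name)],
    in_ecopeak = slot_in_peak[slot_of_gene],
    n_sites = n_sites,
    snp_density = n_sites / glen[slot_of_gene],
    in_biased_set = gene_id %in% sets[["biased_set"]],
    stringsAsFactors = FALSE
  )
  truth_states <- data.frame(
    gene_id = rep(gene_id, each = nrow(tis)),
    tissue = rep(tis$name, n),
    timepoint = rep(tis$timepoint, n),
    state = as.vector(t(state)),
    theta = as.vector(t(theta)),
    stringsAsFactors = FALSE
  )

  list(counts = counts, sites = sites, genes = genes, css_windows = css,
       ecopeaks = peaks, qtl = qtl, sets = sets,
       truth = list(genes = truth_genes, unit_states = truth_states),
       config = cfg)
}

.simulate_null_sets <- function(n_sets, size_range, gene_ids) {
  lo <- size_range[1]; hi <- size_range[2]
  if (hi > length(gene_ids)) {
    stop("simulate_null_sets: set size exceeds number of genes")
  }
  lapply(seq_len(n_sets), function(i) {
    sz <- if (lo == hi) lo else resample(lo:hi, 1)
    sort(resample(gene_ids, sz))
  })
}

#' Simulate null gene sets
#'
#' Sets drawn uniformly at random from the supplied genes, ignoring their
#' directions — the calibration null for the sign test.
#'
#' @param n_sets Number of sets.
#' @param set_size_range `c(min, max)` member counts.
#' @param gene_ids Pool of gene ids.
#' @param seed RNG seed.
#' @return A `gene_sets` list named `null_001`, ...
#' @export
simulate_null_sets <- function(n_sets, set_size_range, gene_ids, seed = 1) {
  sets <- with_seed(seed, .simulate_null_sets(n_sets, set_size_range, gene_ids))
  names(sets) <- sprintf("null_%03d", seq_len(n_sets))
  class(sets) <- "gene_sets"
  sets
}

#' Write every simulated file to a directory
#'
#' Emits the formats the readers in this package consume: `counts.tsv`,
#' `sites.tsv`, `genes.bed`, `css_windows.bed`, `ecopeaks.bed`, `qtl.bed`,
#' `gene_sets.tsv`, `orthologs.tsv` (identity map), `truth_genes.tsv`,
#' `truth_states.tsv`.
#'
#' @param sim Output of [simulate_experiment()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(dir, x)
  write_allelic_counts(sim$counts, fp("counts.tsv"))
  write_site_counts(sim$sites, fp("sites.tsv"))
  write_bed(sim$genes, fp("genes.bed"))
  write_bed(sim$css_windows, fp("css_windows.bed"))
  write_bed(sim$ecopeaks, fp("ecopeaks.bed"))
  write_bed(sim$qtl, fp("qtl.bed"))
  write_gene_sets(sim$sets, fp("gene_sets.tsv"))
  members <- sort(unique(unlist(sim$sets, use.names = FALSE)))
  write_results_tsv(data.frame(source_gene = members, target_gene = members),
                    fp("orthologs.tsv"))
  write_results_tsv(sim$truth$genes, fp("truth_genes.tsv"))
  write_results_tsv(sim$truth$unit_states, fp("truth_states.tsv"))
  invisible(dir)
}
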