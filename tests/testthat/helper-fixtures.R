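# Shared fixtures, built in code at test time.

# minimal well-formed allelic count table
tiny_counts <- function() {
  data.frame(
    gene_id = rep(c("gA", "gB"), each = 4),
    tissue = rep(c("VTP", "VTP", "brain", "brain"), 2),
    timepoint = 2L,
    replicate = rep(1:2, 4),
    marine_count = c(60L, 55L, 30L, 35L, 10L, 12L, 50L, 48L),
    freshwater_count = c(20L, 25L, 30L, 28L, 11L, 9L, 52L, 50L),
    stringsAsFactors = FALSE
  )
}

# direction table with n genes, fw-up with probability p_fw
make_directions <- function(n, p_fw = 0.5, seed = 1) {
  set.seed(seed)
  data.frame(
    gene_id = sprintf("g%05d", seq_len(n)),
    direction = ifelse(runif(n) < p_fw, "freshwater_up", "marine_up"),
    discarded = FALSE, reason = NA_character_,
    stringsAsFactors = FALSE
  )
}

# genomic summary table with freely chosen density/z columns
make_summaries <- function(n, density = runif(n), z = rnorm(n),
                           in_peak = rep(FALSE, n), chrom = rep("chr01", n)) {
  data.frame(
    gene_id = sprintf("g%05d", seq_len(n)), chrom = chrom,
    start = seq_len(n) * 10L, end = seq_len(n) * 10L + 5L, length = 5L,
    n_sites = 0L, snp_density = density, css_z = z, in_ecopeak = in_peak,
    stringsAsFactors = FALSE
  )
}

# small cached simulation shared by several test files
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_experiment(simulation_config(n_genes = 400, seed = 99))
    }
    cache
  }
})
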