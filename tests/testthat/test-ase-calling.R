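# Site filter, exact binomial ASE test, BH adjustment and summaries.

test_that("site filter removes zero-allele and extreme-ratio sites", {
  sites <- data.frame(
    chrom = "chr01", pos = 1:4, gene_id = paste0("g", 1:4),
    marine_count = c(30L, 2048L, 10L, 1024L),
    freshwater_count = c(0L, 1L, 10L, 1L)
  )
  res <- filter_sites(sites)
  expect_equal(res$removed$reason[res$removed$pos == 1], "zero-allele")
  expect_equal(res$removed$reason[res$removed$pos == 2], "ratio")  # |log2| = 11
  expect_true(3 %in% res$sites$pos)                                # balanced kept
  expect_true(4 %in% res$sites$pos)                                # |log2| = 10 exactly, kept
  # idempotent
  again <- filter_sites(res$sites)
  expect_equal(again$sites, res$sites)
  expect_equal(nrow(again$removed), 0)
})

test_that("exact binomial test matches direct pmf summation", {
  expect_equal(binom_test_half(50, 100), 1)
  # frozen oracle: sum of Binomial(100, 0.5) pmf over outcomes with
  # probability <= that of 75
  expect_equal(binom_test_half(75, 100), 5.63628203421e-07, tolerance = 1e-9)
  # property: agreement with direct summation across a grid
  for (n in c(1, 7, 30, 101)) {
    d <- dbinom(0:n, n, 0.5)
    for (x in unique(c(0, floor(n / 3), floor(n / 2), n))) {
      expect_equal(binom_test_half(x, n),
                   sum(d[d <= d[x + 1] * (1 + 1e-12)]),
                   tolerance = 1e-12)
    }
  }
  # symmetry in the alleles
  expect_equal(binom_test_half(70, 100), binom_test_half(30, 100))
  expect_true(is.na(binom_test_half(0, 0)))
})

test_that("lfc uses the 0.5 pseudocount", {
  expect_equal(hybridase:::allelic_lfc(100, 25), log2(100.5 / 25.5))
  expect_equal(hybridase:::allelic_lfc(100, 25), 1.9786, tolerance = 1e-4)
  expect_equal(hybridase:::allelic_lfc(50, 50), 0)
  expect_true(is.finite(hybridase:::allelic_lfc(0, 0)))
})

test_that("BH adjustment matches the hand-executed step-up procedure", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.1, NaN)), "NA/NaN")
  # step-up oracle on random input
  set.seed(5)
  p <- runif(20)
  o <- order(p)
  q <- pmin(1, rev(cummin(rev(p[o] * 20 / seq_len(20)))))
  expect_equal(bh_adjust(p)[o], q)
})

test_that("call_ase pools replicates, adjusts within units, flags untestable", {
  counts <- tiny_counts()
  counts <- rbind(counts, data.frame(gene_id = "gZ", tissue = "VTP",
                                     timepoint = 2L, replicate = 1:2,
                                     marine_count = 0L, freshwater_count = 0L))
  res <- call_ase(counts, fdr = 0.05)
  gA_vtp <- res[res$gene_id == "gA" & res$tissue == "VTP", ]
  expect_equal(gA_vtp$marine_count, 115L)   # pooled across replicates
  expect_equal(gA_vtp$p_value, binom_test_half(115, 160))
  expect_true(res$untestable[res$gene_id == "gZ"])
  expect_true(is.na(res$fdr[res$gene_id == "gZ"]))
  expect_true(all(res$fdr >= res$p_value - 1e-12, na.rm = TRUE))
  expect_true(all(!res$is_ase | res$fdr < 0.05))
})

test_that("ase test is symmetric under allele swap", {
  counts <- tiny_counts()
  swapped <- counts
  swapped$marine_count <- counts$freshwater_count
  swapped$freshwater_count <- counts$marine_count
  a <- call_ase(counts); b <- call_ase(swapped)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
  expect_equal(a$lfc, -b$lfc, tolerance = 1e-12)
})

test_that("type-I error is nominal for simulated no-ASE genes", {
  set.seed(77)
  n_genes <- 4000
  depth <- rpois(n_genes, 300)
  x <- rbinom(n_genes, depth, 0.5)
  p <- binom_test_half(x, depth)
  for (alpha in c(0.01, 0.05)) {
    se <- sqrt(alpha * (1 - alpha) / n_genes)
    expect_lt(mean(p < alpha), alpha + 3 * se)
  }
})

test_that("beta-binomial variant handles overdispersed replicates", {
  set.seed(42)
  n_genes <- 300
  counts <- do.call(rbind, lapply(seq_len(n_genes), function(i) {
    th <- rbeta(2, 40, 40)   # replicate-level overdispersion, mean 0.5
    n <- rpois(2, 400)
    m <- rbinom(2, n, th)
    data.frame(gene_id = sprintf("g%04d", i), tissue = "liver", timepoint = 2L,
               replicate = 1:2, marine_count = m, freshwater_count = n - m)
  }))
  bino <- call_ase(counts, test = "binomial")
  bb <- call_ase(counts, test = "betabinomial")
  # all genes are null: the beta-binomial variant must be less anticonservative
  expect_lt(sum(bb$is_ase), sum(bino$is_ase))
  expect_true(all(bb$p_value >= bino$p_value - 1e-9))
})

test_that("summaries count tissue sharing and direction changes", {
  counts <- data.frame(
    gene_id = rep(c("g1", "g2"), each = 4),
    tissue = rep(rep(c("a", "b"), each = 2), 2),
    timepoint = 2L, replicate = rep(1:2, 4),
    # g1: strong marine-up in a, strong freshwater-up in b (direction change)
    # g2: ASE in tissue a only
    marine_count = c(200L, 200L, 10L, 10L, 150L, 150L, 50L, 50L),
    freshwater_count = c(50L, 50L, 180L, 180L, 50L, 50L, 50L, 50L)
  )
  res <- call_ase(counts)
  s <- summarize_ase(res)
  expect_equal(s$n_direction_change, 1L)
  g2 <- s$gene_profiles[s$gene_profiles$gene_id == "g2", ]
  expect_equal(g2$profile, "10")        # ASE in one of the two units
  expect_equal(g2$n_ase_units, 1)
  expect_equal(s$per_tissue$n_ase, c(2L, 1L))
})

test_that("recovered per-tissue ASE proportion tracks simulated truth", {
  sim <- simulate_experiment(simulation_config(
    n_genes = 300, depth_mean = 250, depth_dispersion = 1e6, seed = 17))
  res <- call_ase(sim$counts)
  truth <- sim$truth$unit_states
  truth$unit <- paste(truth$tissue, truth$timepoint, sep = "@")
  res$unit <- paste(res$tissue, res$timepoint, sep = "@")
  m <- merge(res, truth, by = c("gene_id", "unit"))
  # strong-ASE tissue-states should nearly all be detected at depth 500
  strong <- m[m$state == "S", ]
  expect_gt(mean(strong$is_ase), 0.95)
  # true-N states are rarely called: BH at 5% allows ~5% of the (mostly true)
  # calls to be false, which spread over the larger N pool stays well below 4%
  null <- m[m$state == "N", ]
  expect_lt(mean(null$is_ase), 0.04)
})
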