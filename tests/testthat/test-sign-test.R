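# Direction assignment, per-set Fisher test, permutation null, Fisher's
# method combination, dual criterion.

test_that("directions follow the lfc sign convention; conflicts discarded", {
  ase <- data.frame(
    gene_id = c("g1", "g2", "g2", "g3", "g4"),
    tissue = c("VTP", "VTP", "mandible", "VTP", "mandible"),
    timepoint = 2L,
    lfc = c(-1.0, 0.8, -0.6, 1.2, 0.4),
    is_ase = c(TRUE, TRUE, TRUE, TRUE, FALSE)
  )
  d <- assign_directions(ase, c("VTP", "mandible"))
  # lfc < 0 means the freshwater allele is higher
  expect_equal(d$direction[d$gene_id == "g1"], "freshwater_up")
  # up in marine in one tissue, freshwater in the other -> discarded
  expect_true(d$discarded[d$gene_id == "g2"])
  expect_equal(d$reason[d$gene_id == "g2"], "sign-conflict")
  # ASE in a single group tissue: that tissue's sign carries
  expect_equal(d$direction[d$gene_id == "g3"], "marine_up")
  # non-ASE rows do not contribute
  expect_false("g4" %in% d$gene_id)
})

test_that("set sign test matches fisher.test and applies the 10-member rule", {
  dirs <- make_directions(100, p_fw = 0.5, seed = 2)
  dirs$direction <- rep(c("freshwater_up", "marine_up"), 50)
  members <- dirs$gene_id[dirs$direction == "freshwater_up"][1:10]
  res <- set_sign_test(members, dirs)
  expect_false(res$skipped)
  expect_equal(res$k_freshwater_up, 10)
  # oracle: stats::fisher.test on the same table
  want <- stats::fisher.test(rbind(c(10, 0), c(40, 50)))$p.value
  expect_equal(res$fisher_p, want, tolerance = 1e-9)

  # set proportions equal to background -> p = 1
  bal <- c(dirs$gene_id[dirs$direction == "freshwater_up"][1:5],
           dirs$gene_id[dirs$direction == "marine_up"][1:5])
  expect_equal(set_sign_test(bal, dirs)$fisher_p, 1)

  # fewer than 10 assigned members -> skipped
  res9 <- set_sign_test(members[1:9], dirs)
  expect_true(res9$skipped)
  expect_equal(res9$reason, "min-members")

  # background-exclusion option changes margins but not counts
  rex <- set_sign_test(members, dirs, exclude_set_from_background = TRUE)
  expect_equal(rex$k_freshwater_up, 10)
  expect_equal(stats::fisher.test(rbind(c(10, 0), c(40, 50)))$p.value,
               rex$fisher_p, tolerance = 1e-9)
})

test_that("permutation preserves structure, floors at 1/(N+1), reproducible", {
  dirs <- make_directions(400, p_fw = 0.5, seed = 8)
  # a set made entirely of freshwater-up genes: more extreme than any shuffle
  fw_ids <- dirs$gene_id[dirs$direction == "freshwater_up"]
  m_ids <- dirs$gene_id[dirs$direction == "marine_up"]
  # "balanced" mirrors the background composition exactly -> fisher p = 1
  k <- round(30 * length(fw_ids) / nrow(dirs))
  sets <- structure(list(planted = fw_ids[1:30],
                         balanced = c(fw_ids[31:(30 + k)], m_ids[1:(30 - k)])),
                    class = "gene_sets")
  r1 <- permutation_test(sets, dirs, n_perm = 400, seed = 31)
  r2 <- permutation_test(sets, dirs, n_perm = 400, seed = 31)
  expect_identical(r1, r2)                       # bit-for-bit reproducible
  expect_equal(r1$perm_p[r1$set_id == "planted"], 1 / 401)
  expect_gt(r1$perm_p[r1$set_id == "balanced"], 0.9)
  expect_error(permutation_test(sets, dirs, n_perm = 0), "n_perm")
})

test_that("permutation p-values are valid (exchangeable null) ", {
  # directions iid Bernoulli(0.5); sets drawn blind to direction
  dirs <- make_directions(600, p_fw = 0.5, seed = 12)
  sets <- simulate_null_sets(120, c(15, 40), dirs$gene_id, seed = 13)
  res <- permutation_test(sets, dirs, n_perm = 199, seed = 14)
  for (alpha in c(0.05, 0.1, 0.25)) {
    se <- sqrt(alpha * (1 - alpha) / nrow(res))
    expect_lte(mean(res$perm_p <= alpha), alpha + 3 * se)
  }
})

test_that("Fisher's method matches the chi-square closed form", {
  expect_equal(combine_group_pvalues(c(0.1, 0.1)),
               pchisq(9.21034, df = 4, lower.tail = FALSE), tolerance = 1e-5)
  expect_equal(combine_group_pvalues(c(0.1, 0.1)), 0.0561, tolerance = 1e-3)
  expect_equal(combine_group_pvalues(c(1, 1, 1)), 1)
  # monotone in every argument
  expect_lt(combine_group_pvalues(c(0.05, 0.1)),
            combine_group_pvalues(c(0.1, 0.1)))
  expect_error(combine_group_pvalues(c(0, 0.1)), "> 0")
})

test_that("dual criterion flags only sets significant in both approaches", {
  perm <- data.frame(set_id = c("a", "b", "c"),
                     fisher_p = c(0.001, 0.001, 0.5),
                     perm_p = c(0.002, 0.2, 0.6))
  comb <- data.frame(set_id = c("a", "b", "c"),
                     combined_p = c(0.01, 0.01, 0.9))
  rep <- dual_criterion_report(perm, comb, alpha = 0.05)
  expect_equal(rep$flagged, c(TRUE, FALSE, FALSE))
})

test_that("a planted direction-biased set is recovered end to end", {
  sim <- simulate_experiment(simulation_config(
    n_genes = 400, depth_mean = 300, depth_dispersion = 1e6,
    n_null_sets = 30, seed = 55))
  ase <- call_ase(sim$counts)
  st <- sign_test_analysis(ase, sim$sets, tissues = c("VTP", "DTP", "mandible"),
                           n_perm = 500, seed = 56)
  rep <- st$report
  expect_true(rep$flagged[rep$set_id == "biased_set"])
  # no sign-conflicted gene sneaks into the counts
  dirs <- assign_directions(ase, c("VTP", "DTP", "mandible"))
  expect_true(all(is.na(dirs$direction[dirs$discarded])))
})
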