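# Priors, marginal likelihoods and the multi-tissue classifier, checked
# against independent oracles: closed-form Beta densities, numerical
# quadrature, and brute-force enumeration over all 3^T configurations.

test_that("prior densities match closed forms and are symmetric", {
  # N density at its mode: independent closed form via log-gamma
  d_oracle <- exp(lgamma(4000) - 2 * lgamma(2000) + 1999 * log(0.25))
  expect_equal(prior_density(0.5, "N"), d_oracle, tolerance = 1e-10)
  expect_equal(prior_density(0.5, "N"), 50.4595, tolerance = 1e-4)

  th <- seq(0.05, 0.95, by = 0.05)
  for (s in c("N", "M", "S")) {
    expect_equal(prior_density(th, s), prior_density(1 - th, s),
                 tolerance = 1e-12)
  }
  # strong-ASE prior dominates at extreme frequencies
  expect_gt(prior_density(0.92, "S"), prior_density(0.92, "M"))
  expect_gt(prior_density(0.92, "S"), prior_density(0.92, "N"))
  expect_error(prior_density(1, "N"), "strictly")
})

test_that("no-ASE dominance interval is (0.47, 0.53) and symmetric", {
  iv <- dominance_interval()
  expect_equal(unname(iv), c(0.47, 0.53))
  # unrounded endpoints symmetric about 0.5
  iv6 <- dominance_interval(rounding = 6)
  expect_equal(unname(iv6[1]), 1 - unname(iv6[2]), tolerance = 1e-5)
  # N strictly dominates at the centre
  expect_gt(prior_density(0.5, "N"),
            max(prior_density(0.5, "M"), prior_density(0.5, "S")))
})

test_that("log marginals match numerical quadrature", {
  # oracle: midpoint quadrature of Binomial(n, theta) against each prior
  # mixture on a 1e5-point grid
  quad <- function(x, n, comp) {
    th <- seq(1 / 2e5, 1 - 1 / 2e5, length.out = 1e5)
    dens <- rep(0, length(th))
    for (k in seq_len(nrow(comp))) {
      dens <- dens + comp$weight[k] * stats::dbeta(th, comp$alpha[k], comp$beta[k])
    }
    log(mean(stats::dbinom(x, n, th) * dens))
  }
  pr <- ase_priors()
  expect_equal(log_marginal(60, 100, "N"), quad(60, 100, pr$N), tolerance = 1e-6)
  cases <- expand.grid(x = c(0, 10, 50, 99), n = 100)
  for (s in c("N", "M", "S")) {
    got <- log_marginal(cases$x, cases$n, s)
    want <- mapply(function(x, n) quad(x, n, pr[[s]]), cases$x, cases$n)
    expect_equal(got, want, tolerance = 1e-6)
  }
  # empty data carries no evidence; symmetry under allele swap
  expect_equal(log_marginal(0, 0, "M"), 0)
  for (s in c("N", "M", "S")) {
    expect_equal(log_marginal(17, 60, s), log_marginal(43, 60, s),
                 tolerance = 1e-12)
  }
  expect_error(log_marginal(-1, 5, "N"), "0 <= x <= n")
  # no underflow at extreme depth
  expect_true(is.finite(log_marginal(999000, 1e6, "S")))
})

# brute-force oracle: enumerate all 3^T configurations, multiply per-tissue
# marginals, normalize, then sum by class
enumeration_oracle <- function(x, n, priors = ase_priors()) {
  T <- length(x)
  L <- sapply(c("N", "M", "S"), function(s) log_marginal(x, n, s, priors))
  L <- matrix(L, nrow = T)
  cfg <- as.matrix(expand.grid(rep(list(1:3), T)))
  logw <- apply(cfg, 1, function(sidx) sum(L[cbind(seq_len(T), sidx)]))
  w <- exp(logw - max(logw)); post <- w / sum(w)
  cls <- apply(cfg, 1, function(sidx) {
    s <- c("N", "M", "S")[sidx]
    if (all(s == "N")) "NOASE"
    else if (all(s == "M") || all(s == "S")) "UNIFORM_ASE"
    else if (any(s == "N")) "HET0" else "HET1"
  })
  vapply(c("NOASE", "UNIFORM_ASE", "HET0", "HET1"),
         function(cl) sum(post[cls == cl]), 0)
}

test_that("classifier equals 3^T enumeration and behaves on clear cases", {
  # balanced everywhere -> NOASE
  cl <- classify_gene(rep(50, 7), rep(50, 7))
  expect_gt(cl$class_pp[["NOASE"]], 0.9)
  # one imbalanced tissue among balanced ones -> HET0, correct tissue flagged
  # (min_reads lowered so the 95:5 tissue passes the depth filter)
  cl2 <- classify_gene(c(95, rep(50, 6)), c(5, rep(50, 6)),
                       tissues = paste0("t", 1:7), min_reads = 0)
  expect_equal(names(which.max(cl2$class_pp)), "HET0")
  expect_equal(names(which.max(cl2$tissue_specific_pp)), "t1")

  # enumeration oracle on random genes, 1e-10 relative error
  set.seed(301)
  for (i in 1:25) {
    T <- sample(2:7, 1)
    n <- rpois(T, 200) + 25
    x <- rbinom(T, n, runif(T, 0.1, 0.9))
    x <- pmin(pmax(x, 12), n - 12)   # keep all tissues above the depth filter
    got <- classify_gene(x, n - x)$class_pp
    want <- enumeration_oracle(x, n)
    expect_equal(unname(got), unname(want), tolerance = 1e-10)
    expect_equal(sum(got), 1, tolerance = 1e-9)
  }
})

test_that("explicit configuration prior reproduces the uniform fast path", {
  x <- c(90, 55, 40); n <- c(120, 100, 95)
  fast <- classify_gene(x, n - x)
  slow <- classify_gene(x, n - x, config_prior = function(s) 1)
  expect_equal(fast$class_pp, slow$class_pp, tolerance = 1e-10)
  expect_equal(unname(fast$tissue_specific_pp),
               unname(slow$tissue_specific_pp), tolerance = 1e-10)
})

test_that("depth filter and unclassifiable flag follow the >10 reads/allele rule", {
  # one tissue above cutoff only -> unclassifiable
  cl <- classify_gene(c(50, 10, 5), c(50, 10, 200))
  expect_false(cl$classifiable)
  # a tissue with exactly 10 reads on one allele is excluded
  cl2 <- classify_gene(c(50, 10, 40), c(50, 40, 40), tissues = c("a", "b", "c"))
  expect_true(cl2$classifiable)
  expect_equal(cl2$tissues, c("a", "c"))
  expect_equal(cl2$excluded_tissues, "b")
})

test_that("PP(N) grows with depth at a balanced allelic fraction", {
  pps <- vapply(c(30, 100, 300, 1000, 3000), function(n) {
    cl <- classify_gene(c(n / 2, 50), c(n / 2, 50))
    cl$state_posterior[1, "N"]
  }, numeric(1))
  expect_true(all(diff(pps) > 0))
})

test_that("classify_all recovers truth and respects nested thresholds", {
  sim <- shared_sim()
  cl <- classify_all(sim$counts, tissues = "late")
  expect_true(all(abs(rowSums(cl$table[, c("pp_noase", "pp_uniform",
                                           "pp_het0", "pp_het1")]) - 1) < 1e-9))
  # every gene counted at 0.95 is counted at 0.9
  s90 <- cl$summary[cl$summary$threshold == 0.9, ]
  s95 <- cl$summary[cl$summary$threshold == 0.95, ]
  expect_true(all(s95$n <= s90$n))
  expect_true(all(s95$n_het <= s90$n_het))
  # majority agreement with simulated truth on confident calls
  truth <- sim$truth$genes
  m <- merge(cl$table, truth, by = "gene_id")
  conf <- m[m$best_class_pp > 0.9, ]
  expect_gt(mean(conf$best_class == conf$config_class), 0.8)
})
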