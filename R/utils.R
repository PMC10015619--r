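# Shared statistical primitives and small helpers used across the pipeline.

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjustment. A thin validating wrapper around
#' [stats::p.adjust()] that rejects missing or out-of-range p-values instead
#' of silently propagating them.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of adjusted p-values (FDR), capped at 1.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(is.nan(p))) {
    stop("bh_adjust: p-values contain NA/NaN")
  }
  if (any(p < 0 | p > 1)) {
    stop("bh_adjust: p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Two-sided exact binomial test against 0.5
#'
#' Minimum-likelihood two-sided rule: the p-value is the sum of probabilities
#' of all outcomes whose point probability does not exceed that of the
#' observed outcome. For the symmetric null p = 0.5 the rejection region is
#' the two symmetric tails, so the sum has the closed form
#' `min(1, 2 * P(X <= min(x, n - x)))`. Outcomes whose probability ties the
#' observed one exactly are included in the rejection sum.
#'
#' @param x Number of successes (marine-allele reads), vectorized.
#' @param n Total trials (total allelic reads), vectorized.
#' @return p-values; `NA` where `n == 0` (untestable).
#' @export
binom_test_half <- function(x, n) {
  if (any(x < 0 | n < 0 | x > n)) stop("binom_test_half: need 0 <= x <= n")
  m <- pmin(x, n - x)
  p <- pmin(1, 2 * stats::pbinom(m, n, 0.5))
  p[n == 0] <- NA_real_
  p
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Direct enumeration of the hypergeometric distribution under fixed margins;
#' the two-sided p-value sums the probabilities of all tables whose point
#' probability is at most that of the observed table (relative tolerance
#' 1e-7, as is conventional). Vectorized over table entries.
#'
#' @param a,b,c,d Cell counts of the table \code{rbind(c(a, b), c(c, d))}.
#' @return Two-sided p-values.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(a, n); b <- rep_len(b, n)
  c <- rep_len(c, n); d <- rep_len(d, n)
  if (any(c(a, b, c, d) < 0)) stop("fisher_exact_2x2: negative cell count")
  vapply(seq_len(n), function(i) {
    m1 <- a[i] + c[i]          # column-1 total (white balls)
    m2 <- b[i] + d[i]          # column-2 total (black balls)
    r1 <- a[i] + b[i]          # row-1 total (draws)
    if (r1 == 0 || (m1 + m2) == 0) return(1)
    supp <- max(0, r1 - m2):min(r1, m1)
    pmf <- stats::dhyper(supp, m1, m2, r1)
    pobs <- stats::dhyper(a[i], m1, m2, r1)
    min(1, sum(pmf[pmf <= pobs * (1 + 1e-7)]))
  }, numeric(1))
}

#' Combine p-values with Fisher's method
#'
#' X^2 = -2 * sum(log(p_i)) is referred to a chi-square distribution with
#' 2k degrees of freedom (upper tail).
#'
#' @param p Numeric vector of p-values in (0, 1\].
#' @return Combined p-value.
#' @export
fishers_method <- function(p) {
  if (length(p) == 0L) stop("fishers_method: no p-values supplied")
  if (anyNA(p)) stop("fishers_method: p-values contain NA")
  if (any(p <= 0)) stop("fishers_method: p-values must be > 0 (floor upstream)")
  if (any(p > 1)) stop("fishers_method: p-values must be <= 1")
  x2 <- -2 * sum(log(p))
  stats::pchisq(x2, df = 2 * length(p), lower.tail = FALSE)
}

# Add-one permutation p-value estimator: never 0, floor 1/(n_perm + 1).
perm_pvalue <- function(n_as_extreme, n_perm) {
  (n_as_extreme + 1) / (n_perm + 1)
}

# log(sum(exp(x))) without overflow
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Evaluate an expression under a temporary RNG seed, restoring global state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Derive a deterministic 31-bit sub-stream seed from a master seed and a tag.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 69069 + h * 1013 + 1) %% 2147483647)
}

# sample() that never falls into the scalar-x trap (sample(5, 1) == sample(1:5, 1))
resample <- function(x, size, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}

# Stage-tagged logging to stderr.
pipeline_log <- function(stage, ..., verbose = TRUE) {
  if (isTRUE(verbose)) {
    message(sprintf("[%s] %s", stage, paste0(...)))
  }
  invisible(NULL)
}

# log2 allelic fold change with 0.5 pseudocount per allele (marine over
# freshwater); finite for zero counts.
allelic_lfc <- function(marine, freshwater) {
  log2((marine + 0.5) / (freshwater + 0.5))
}
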