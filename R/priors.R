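# Beta-mixture priors over the allelic fraction for the three per-tissue ASE
# states: N (no ASE), M (moderate ASE), S (strong ASE). Each state's prior is
# a weighted mixture of Beta components; the defaults are sharply separated so
# that a tissue's allelic counts can be attributed to one state.

ASE_STATES <- c("N", "M", "S")

#' Default ASE-state priors
#'
#' Returns the prior specification used by the multi-tissue heterogeneity
#' classifier: one weighted Beta mixture per state.
#'
#' Defaults:
#' \itemize{
#'   \item N (no ASE): Beta(2000, 2000) — tightly concentrated at 0.5,
#'     allowing only technical deviation.
#'   \item M (moderate ASE): 1/2 Beta(80, 36) + 1/2 Beta(36, 80) — symmetric
#'     mixture with modes near 0.69 / 0.31.
#'   \item S (strong ASE): 1/2 Beta(80, 7) + 1/2 Beta(7, 80) — symmetric
#'     mixture with modes near 0.92 / 0.08.
#' }
#'
#' The M and S mixtures are direction-agnostic: a marine-biased and a
#' freshwater-biased tissue of equal magnitude share a state. Direction is
#' carried separately by the sign of the allelic log2 fold change.
#'
#' @return A named list with elements `N`, `M`, `S`, each a data.frame with
#'   columns `weight`, `alpha`, `beta`.
#' @examples
#' pr <- ase_priors()
#' pr$S
#' @export
ase_priors <- function() {
  list(
    N = data.frame(weight = 1,          alpha = 2000,      beta = 2000),
    M = data.frame(weight = c(0.5, 0.5), alpha = c(80, 36), beta = c(36, 80)),
    S = data.frame(weight = c(0.5, 0.5), alpha = c(80, 7),  beta = c(7, 80))
  )
}

#' Read a prior specification from file
#'
#' One line per mixture component: `state weight alpha beta`, whitespace
#' separated, `state` in \{N, M, S\}. Lines beginning with `#` are ignored.
#'
#' @param path Path to the priors file.
#' @return A prior specification as returned by [ase_priors()].
#' @export
read_priors <- function(path) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           col.names = c("state", "weight", "alpha", "beta"),
                           colClasses = c("character", rep("numeric", 3)),
                           stringsAsFactors = FALSE)
  if (!all(tab$state %in% ASE_STATES)) {
    stop("read_priors: states must be one of N, M, S")
  }
  pr <- lapply(ASE_STATES, function(s) {
    rows <- tab[tab$state == s, c("weight", "alpha", "beta")]
    rownames(rows) <- NULL
    rows
  })
  names(pr) <- ASE_STATES
  validate_priors(pr)
  pr
}

validate_priors <- function(priors) {
  if (!all(ASE_STATES %in% names(priors))) {
    stop("priors must define states N, M and S")
  }
  for (s in ASE_STATES) {
    comp <- priors[[s]]
    if (nrow(comp) == 0L) stop("state ", s, " has no mixture components")
    if (abs(sum(comp$weight) - 1) > 1e-9) {
      stop("state ", s, " mixture weights must sum to 1")
    }
    if (any(comp$alpha <= 0 | comp$beta <= 0)) {
      stop("state ", s, " has non-positive Beta parameters")
    }
  }
  invisible(priors)
}

#' Prior density of the allelic fraction under one ASE state
#'
#' @param theta Allelic fraction(s), strictly inside (0, 1).
#' @param state One of `"N"`, `"M"`, `"S"`.
#' @param priors Prior specification; defaults to [ase_priors()].
#' @return Density values (weighted sum of Beta densities).
#' @export
prior_density <- function(theta, state, priors = ase_priors()) {
  state <- match.arg(state, ASE_STATES)
  if (any(theta <= 0 | theta >= 1)) {
    stop("prior_density: theta must lie strictly in (0, 1)")
  }
  comp <- priors[[state]]
  out <- numeric(length(theta))
  for (k in seq_len(nrow(comp))) {
    out <- out + comp$weight[k] * stats::dbeta(theta, comp$alpha[k], comp$beta[k])
  }
  out
}

#' Dominance interval of the no-ASE prior
#'
#' The contiguous interval around theta = 0.5 on which the N (no ASE) prior
#' density strictly exceeds both the M and the S mixture densities. Endpoints
#' are located by bisection to 1e-6 and then rounded. With the default priors
#' this interval is (0.47, 0.53): allelic fractions within it are a priori
#' attributed to technical noise rather than ASE.
#'
#' @param priors Prior specification.
#' @param rounding Decimal places for the reported endpoints (default 2).
#' @return Numeric vector `c(low, high)`.
#' @export
dominance_interval <- function(priors = ase_priors(), rounding = 2) {
  validate_priors(priors)
  gap <- function(x) {
    prior_density(x, "N", priors) -
      pmax(prior_density(x, "M", priors), prior_density(x, "S", priors))
  }
  if (gap(0.5) <= 0) {
    stop("dominance_interval: N prior does not dominate at theta = 0.5")
  }
  # bracket the crossing on each side of 0.5 by stepping outward
  bracket <- function(dir) {
    step <- 0.005
    x <- 0.5
    repeat {
      xn <- x + dir * step
      if (xn <= 1e-9 || xn >= 1 - 1e-9) {
        stop("dominance_interval: no crossing found toward ", dir)
      }
      if (gap(xn) <= 0) return(sort(c(x, xn)))
      x <- xn
    }
  }
  bisect <- function(lo, hi) {
    # invariant: gap changes sign between lo and hi (either order)
    flo <- gap(lo)
    for (i in 1:60) {
      if (abs(hi - lo) < 1e-9) break
      mid <- (lo + hi) / 2
      fm <- gap(mid)
      if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
    }
    (lo + hi) / 2
  }
  b_lo <- bracket(-1)
  b_hi <- bracket(+1)
  low <- bisect(b_lo[2], b_lo[1])   # gap > 0 at inner end
  high <- bisect(b_hi[1], b_hi[2])
  round(c(low = low, high = high), rounding)
}

#' Log marginal likelihood of allelic counts under one ASE state
#'
#' Beta-binomial mixture marginal: integrates Binomial(n, theta) over the
#' state's Beta-mixture prior,
#' log sum_k w_k C(n, x) B(x + a_k, n - x + b_k) / B(a_k, b_k),
#' computed in log space via log-gamma. Finite for all valid inputs; equals 0
#' (log 1) when `n = 0`. Vectorized over `x` and `n`.
#'
#' @param x Marine-allele read count(s).
#' @param n Total read count(s), same length or recyclable.
#' @param state One of `"N"`, `"M"`, `"S"`.
#' @param priors Prior specification.
#' @return Log marginal probabilities.
#' @export
log_marginal <- function(x, n, state, priors = ase_priors()) {
  state <- match.arg(state, ASE_STATES)
  len <- max(length(x), length(n))
  x <- rep_len(x, len); n <- rep_len(n, len)
  if (any(x < 0 | n < 0 | x > n)) stop("log_marginal: need 0 <= x <= n")
  comp <- priors[[state]]
  lc <- lchoose(n, x)
  terms <- matrix(NA_real_, nrow = len, ncol = nrow(comp))
  for (k in seq_len(nrow(comp))) {
    a <- comp$alpha[k]; b <- comp$beta[k]
    terms[, k] <- log(comp$weight[k]) + lc +
      lbeta(x + a, n - x + b) - lbeta(a, b)
  }
  apply(terms, 1L, logsumexp)
}
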