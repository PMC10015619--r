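---
title: "Models and methods in hybridase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in hybridase}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridase)
```

# The problem

In an F1 hybrid between two diverged ecotypes (here: marine and freshwater
stickleback), both parental alleles of every gene sit in the same cellular
environment. Unequal allelic expression (allele-specific expression, ASE)
therefore isolates *cis*-acting regulatory divergence from *trans* effects.
`hybridase` implements the downstream analysis of such an experiment from
gene-level allelic read counts: per-tissue ASE calling, multi-tissue
heterogeneity classification, developmental differential ASE, a gene-set sign
test for polygenic selection on *cis*-regulation, and SNP-density-controlled
enrichment of ASE genes in genomic regions of repeated ecotype divergence.

The sampling design the package (and its simulator) assumes is seven tissues
at a late developmental timepoint, of which the three dental tissues (ventral
and dorsal pharyngeal tooth plates, mandible) are additionally sampled at an
early timepoint, with two replicates per unit. None of the tissue names are
hard-coded; any design with at least two tissues works.

# ASE calling

**Site filter.** Gene-level counts are built from allelic counts at
heterozygous sites, which are vulnerable to mapping bias and genotyping
error. `filter_sites()` removes sites whose pooled counts show
|log2(marine/freshwater)| > 10 or zero reads on one allele. Pooling across
all libraries (rather than per library) is a choice the upstream literature
leaves open; it is logged so it can be audited. The filter is idempotent.

**Test.** Replicates are pooled per gene and tissue-timepoint and the marine
fraction is tested against 0.5 with a two-sided exact binomial test using the
minimum-likelihood rule (all outcomes no more probable than the observed one
count toward the p-value; outcomes tying the observed probability are
included). For the symmetric null this reduces to the closed form
`min(1, 2 * pbinom(min(x, n - x), n, 0.5))`. This replaces the negative
binomial Wald test a DESeq2-based analysis would use: with counts pooled
(as the downstream stages pool them anyway) the exact test needs no dispersion
estimation and is exact at any depth. A beta-binomial variant
(`call_ase(..., test = "betabinomial")`) guards against replicate
overdispersion; its per-tissue overdispersion is a method-of-moments estimate
from replicate allelic fractions, and it is never anti-conservative relative
to the binomial test.

The allelic log2 fold change is `log2((m + 0.5)/(f + 0.5))`; the 0.5
pseudocount keeps it finite for zero counts. Benjamini–Hochberg adjustment is
applied within each tissue-timepoint, mirroring per-contrast adjustment;
genes with zero pooled depth are flagged untestable and excluded from the
adjustment. The default ASE call threshold is FDR < 0.05 (0.1 supported).

# Multi-tissue heterogeneity model

Each included tissue of a gene is in one of three latent states with a Beta
mixture prior on the marine allelic fraction θ:

* **N** (no ASE): Beta(2000, 2000) — essentially 0.5 plus technical noise;
* **M** (moderate): ½ Beta(80, 36) + ½ Beta(36, 80);
* **S** (strong): ½ Beta(80, 7) + ½ Beta(7, 80).

These are sharply separated by construction: the N density exceeds both
mixtures exactly on θ ∈ (0.47, 0.53) (computed by bisection in
`dominance_interval()`), so fractions in that band are attributed to noise.
The M and S priors are symmetric, hence direction-agnostic: a θ = 0.9 tissue
and a θ = 0.1 tissue share state S, and direction is reported separately via
the lfc sign.

The marginal likelihood of summed counts (x marine of n) under a state is the
beta-binomial mixture, computed in log space via log-gamma
(`log_marginal()`); it is finite up to n = 10^6 and equals 0 for n = 0.
Tissues with ≤ `min_reads` (default 10) reads on either allele are excluded;
genes with fewer than two remaining tissues are unclassifiable.

A gene's configuration is the state vector over its T tissues. Classes
partition the 3^T configurations: NOASE (all N), UNIFORM_ASE (all M or all
S), HET0 (≥1 ASE tissue and ≥1 N), HET1 (all ASE, magnitudes differ).
With the default uniform prior over configurations the posterior factorizes
across tissues, so class posteriors are products of per-tissue state
posteriors — e.g. PP(NOASE) = Πₜ qₜ(N), PP(HET0) = 1 − Πₜ qₜ(N) −
Πₜ(1 − qₜ(N)) — evaluated in closed form rather than by enumeration. The
package does not restate the configuration prior used by the framework it
follows (the original does not print one); uniform is the least-informative
enumerable choice, and `config_prior` accepts any weight function, which
switches to exhaustive enumeration (T ≤ 12). Tests verify the factorized
path against brute-force 3^T enumeration to 10^-10 relative error on
non-negligible posteriors.

Tissue-specific ASE for tissue t is s_t ∈ {M, S} with all other tissues N.
The converse pattern (a single N among otherwise-ASE tissues) is reported
separately as `tissue_specific_noase_pp`, since "the state is observed in
only one tissue" admits both readings. MAP ties are broken N < M < S and
flagged. Calls are reported at PP > 0.9 and > 0.95.

# Developmental differential ASE

For tissues sampled at both timepoints, genes with ASE at ≥1 timepoint are
tested for a change in allelic ratio with a two-sided Fisher's exact test on
the 2×2 table of replicate-pooled (marine, freshwater) counts at the two
timepoints, BH-adjusted within tissue. Significant genes are labeled
`early_bias` when |lfc_early| > |lfc_late| and `late_bias` otherwise (exact
ties go to `late_bias` deterministically and are flagged — ties are
measure-zero on real data); the mode is `timepoint_specific` when ASE is
called at exactly one timepoint and `magnitude_change` when at both.

# Sign test for selection on cis-regulation

Under neutrality, the direction of independent *cis* changes (marine- vs
freshwater-up) in a functionally coherent gene set should be unbiased
relative to the genome-wide background. Directions are the lfc signs of ASE
genes; in a tissue-group analysis a gene must have a consistent sign across
its ASE tissues or it is discarded (`sign-conflict`). Each set with ≥10
direction-assigned members is tested with a two-sided Fisher's exact test of
its direction split against the background of all direction-assigned ASE
genes (set included in the margins by default; exclusion is an option since
the convention is not fixed in the literature).

Significance is calibrated by shuffling the gene→set assignment 10,000 times
— a single permuted gene-label map per iteration shared by all sets, which
preserves set sizes, the direction multiset, and the overlap structure among
sets — and the permutation p is (b + 1)/(N + 1), flooring at 1/10001.
Because the table margins are invariant under this permutation, each set's
Fisher p depends only on its freshwater-up count, and the implementation
precomputes the p-value lookup per set size over the feasible hypergeometric
support, reducing each permutation to table lookups.

For a tissue group the per-tissue Fisher p-values of categories eligible in
every member tissue are combined with Fisher's method (X² = −2Σlog p, df =
2k); the final report flags categories significant in **both** the group
permutation test and the combined test.

A note on calibration testing: the Fisher p of a small set is discrete (a
size-20 set takes ~11 values), so its distribution under the null is
conservative, not continuously uniform — a plain Kolmogorov–Smirnov test
against Uniform(0,1) rejects for any correct exact test. The acceptance
suite therefore checks the randomized probability integral transform of the
observed p against its exact hypergeometric null law (exactly uniform iff
the machinery is calibrated) together with the rejection-rate bound
Pr(p ≤ α) ≤ α + 3SE.

# Genomic enrichment with SNP-density control

Power to detect ASE scales with the number of informative heterozygous sites
in a transcript, and site density itself covaries with local divergence — so
any comparison of ASE and background genes along the genome must control for
SNP density (informative het sites per bp of transcript). Genes are sorted
by density into equal-frequency bins of ~23 genes (matching roughly the
"hundreds of bins" regime of a full transcriptome at the default occupancy);
bins with fewer than 5 genes in either category are dropped from the CSS
comparison.

* **CSS Z test.** Each gene's CSS Z is the median score of divergence
  windows overlapping it by ≥1 bp (any-overlap and median are package
  choices; the aggregation is not fixed by the source literature). The
  statistic is the median over bins of (median Z of ASE − median Z of
  background); labels are shuffled within bins, preserving per-bin counts;
  the two-sided permutation p floors at 1/10001. Per-bin differences are
  also emitted. The aggregate-over-bins statistic was chosen over per-bin
  p-values to give a single genome-wide answer; both views are reported.
* **EcoPeak / chromosome enrichment.** Random gene sets matched to the ASE
  set's per-bin density profile are drawn (1,000 by default) from all genes
  (a `non_ase` background is available; under it, bins with too few
  background genes fall back to with-replacement sampling, logged). Fold
  enrichment is observed/mean-resampled in-peak count; per-chromosome counts
  get the analogous (b + 1)/(N + 1) p-values, flooring at 1/1001.
* **Candidates.** Genes with ASE that lie in a divergence peak and overlap a
  QTL interval are tabulated with their ASE tissues and QTL names.

# The synthetic world

`simulate_experiment()` generates the complete input set with ground truth.
Its defaults state the emulated conditions once and are not tuning knobs:

| parameter | default | rationale |
|---|---|---|
| class proportions | NOASE 0.60, UNIFORM 0.10, HET0 0.12, HET1 0.08, TISSUE_SPECIFIC 0.10 | ~40% of genes carry ASE somewhere, about half of those heterogeneous, tissue-specific patterns prominent — the regime the emulated study reports |
| depth | NB(mean 100, size 2) per gene/replicate | overdispersed RNA-seq allelic coverage; recovery tests pass the depth their criterion states (500/allele = mean 500 × 2 replicates) |
| θ | drawn once per gene-tissue from the state prior, direction-consistent component | cis effects are gene properties; replicates share the biology; direction is typically maintained across tissues |
| direction | one Bernoulli(0.5) per gene | applied to all its ASE tissues |
| timepoint switch | 0.25 per dental gene | produces a sizeable timepoint-specific fraction |
| genome | 5 chromosomes, lognormal gene lengths (median 2 kb), CSS windows of 2.5 kb, 10% of windows in peaks, peak Z shift +1.5 | toy genome large enough for binning and overlap tests |
| het-site density | Gamma(2, mean 0.005/bp), sites Poisson-placed | ~1 informative site per 200 bp; site table distributes pooled gene counts multinomially over sites (exercises the site filter without read-level simulation) |
| ASE peak placement | exact 2× enrichment | the in-peak ASE gene count is set to round(2 · p₀ · n_ASE), so recomputed enrichment equals the configuration up to rounding |
| biased set | 30 genes, 90% freshwater-up | the planted signal for sign-test power |

What the generator does **not** emulate: read-level mapping bias (the site
filter is exercised on counts, not reads), correlation between SNP density
and ASE detectability (counts are generated independently of density, so the
density control is tested for unbiasedness, not for confounder removal on
real data), linkage between neighboring genes, and the real stickleback
genome's coordinates. A green recovery test therefore establishes that the
statistical machinery is correct on data matching its model assumptions —
not that the model assumptions hold for any particular real dataset.

# Numerical choices

* All likelihood math in log space; `log_marginal` is finite for n up to
  10^6; mixture sums use log-sum-exp.
* Dominance-interval endpoints by bisection to 1e-6, then rounded (default 2
  decimals).
* Binomial/Fisher two-sided rules include outcomes whose probability ties
  the observed one (relative tolerance 1e-7 for the hypergeometric, matching
  common practice).
* Permutation/resampling p-values use the add-one estimator (b + 1)/(N + 1):
  never zero, floors 1/10001 and 1/1001 at the default iteration counts.
* Every stochastic routine takes an explicit seed and restores the caller's
  RNG state; pipeline sub-stages derive distinct sub-seeds (< 2^31) from the
  single run seed.
* TSV output renders floats at 6 significant digits and is byte-stable
  across reruns.

# Known limitations

* The heterogeneity classifier assumes tissues are independent given their
  states (no shared-θ grouping across tissues within a configuration).
* The beta-binomial variant's overdispersion estimate is crude (two
  replicates carry little information); it is a guard, not an inference
  target.
* Fisher's-method combination requires a category to be eligible in every
  member tissue; categories failing eligibility get no combined p and can
  only be flagged by the permutation route — hence never by the dual
  criterion, which is the intended conservative behavior.
* With `background = "non_ase"` and extreme ASE fractions the resampling
  falls back to with-replacement draws, which slightly understates the null
  variance; the default all-gene background avoids this.
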