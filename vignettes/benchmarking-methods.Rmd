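---
title: "Benchmarking differential abundance and beta-diversity methods for 16S OTU tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking differential abundance and beta-diversity methods for 16S OTU tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(ampliconbench)
```

# The problem

A 16S amplicon survey yields an OTU-by-sample matrix of read counts with
three pathologies that break textbook assumptions: extreme sparsity
(typically 80–95% zeros), library sizes varying by orders of magnitude, and
overdispersion — per-OTU variance far exceeding the mean. Differential
relative abundance (DA) testing applies a two-group test to every OTU, and
methods differ wildly in how they cope. `ampliconbench` quantifies that
difference with three instruments: a null-label false-positive-rate (FPR)
protocol, an in-silico spike-in retrieval experiment scored by AUC, and a
beta-diversity optimization grid scored by PERMANOVA *R*².

# The synthetic world

Because the package must be testable without clinical cohorts, the
generator `generateTable()` emulates the three pathologies with the
simplest adequate mechanism — a gamma-Poisson (negative binomial) model:

* OTU mean abundances follow a power law in rank,
  $a_r \propto r^{-\gamma}$ (default $\gamma = 1$, a typical rank-abundance
  slope for marker-gene surveys);
* library-size factors are log-normal (`libSizeLogSd = 1` spans roughly two
  orders of magnitude across 100 samples);
* counts are NB with $\mathrm{Var} = \mu + \varphi\mu^2$
  (default $\varphi = 0.5$).

Sparsity is not a separate knob: a single global abundance scale $c$ is
solved by `uniroot` so that the *expected* zero fraction
$\overline{(1+\varphi\mu)^{-1/\varphi}}$ equals `targetSparsity`
(default 0.85, the middle of the real-data range). Two consequences are
worth knowing:

* With only 1,000 simulated OTUs, hitting 85% zeros forces shallower
  library sizes (hundreds of reads) than a real survey with tens of
  thousands of taxa would have. Depth *variation*, which is what drives
  method behaviour, is preserved.
* The realized mean–variance relation across samples mixes biological
  overdispersion with depth variation. Recovering $\varphi$ therefore
  requires conditioning on depth; the tests use the method-of-moments
  estimator $\hat\varphi = \sum[(x-\hat\mu)^2-\hat\mu]/\sum\hat\mu^2$ with
  $\hat\mu_{ij} = \hat b_i L_j$, which lands within 50% of truth at the
  default size. Likewise, a lone read in an otherwise-zero row cannot
  evidence overdispersion, so the per-OTU "variance > mean" check is
  asserted for OTUs with mean ≥ 0.5 (empirically ~100% there).

What a green test on this world does **not** establish: phylogenetic
correlation between OTUs, compositional interactions, chimeras and
sequencing error are all absent, and the null FPR calibration shown here
says nothing about model-misspecification failure modes that only real
taxon-abundance structure can trigger.

`permuteWithinOtus()` provides the complementary null: each OTU row of a
(real or synthetic) table is independently permuted across samples,
preserving every OTU-marginal distribution exactly while destroying
within-sample structure. One seed drives a per-OTU stream (the per-OTU
versus global seeding question is internal bookkeeping; results depend only
on the single user-facing seed).

# Spike-ins

`assignLabels()` draws `max(1, round(p·n))` cases uniformly; the draw is
the null hypothesis. Spike targets are chosen per relative-abundance
tertile (ranked by overall mean relative abundance, ties broken by OTU id,
remainder rows assigned to the lower tertiles) among OTUs present in at
least one case sample. Three schemes modify *case samples only*:

* **multiplicative** — counts × m;
* **additive** — interpreting "mean proportion of non-zero counts" on the
  relative-abundance scale: with $\bar q$ the mean relative abundance of
  the OTU over its non-zero samples, each non-zero case cell gains
  $\mathrm{round}(\bar q \cdot m \cdot L_j)$. A pure count-scale reading
  would make the magnitude's meaning depend on sequencing depth, which is
  why the relative reading was chosen; zero cells stay zero either way;
* **mixed** — a seeded shuffle of the magnitude set cycled over the
  targets, recorded per OTU in the truth table.

After spiking, each case sample is rescaled to its original depth with
largest-remainder (Hamilton) rounding: integer counts, exact totals, zeros
map to zeros, remainder ties broken by row index. Conservation of library
sizes is asserted for every scheme.

# DA methods and the missing-p rule

The classical tests run exactly as a practitioner runs them:
`stats::t.test` (Welch) on relative abundances, the same on
log(count + 1) for the log *t* test (the pseudocount is applied on the
count scale and the values are *not* re-scaled afterwards — the operand of
the log is ambiguous in common usage, and this choice is isolated in
`daLogTTest()`), `stats::wilcox.test` with default exact/approximate
switching, and `MASS::glm.nb` with mean model
$\log\mu = \beta_0 + \beta_1\,\mathrm{case} + \log L_j$ (Wald p on
$\beta_1$; the reported statistic is $\hat\beta_1$, so `exp(statistic)` is
the fold-change estimate).

The permutation test is implemented in full: on relative abundances,
$S = \log(\bar x_{case}/\bar x_{ctrl})^2$; the null is estimated from
`nPerm` random label draws *reused across all OTUs* (one draw is one
column-weighting, so the whole null matrix is two matrix products);
$p = \#\{S_{perm} \ge S_{obs}\}/n_{perm}$ with no +1 smoothing, so p = 0 is
attainable. Decisions for degenerate cases: one zero group mean gives
$S = +\infty$ (ranked above all finite values), two zero means give
$S = 0$. Statistics are snapped to 10 significant digits before the ≥
comparison so mathematically tied permutations (e.g. the complement of the
observed split) count as ties irrespective of floating-point summation
order. An `exact = TRUE` mode enumerates all label splits for oracle
comparisons.

Every method obeys one rule: an OTU for which a method returns no p-value
gets p = 1. This is what makes "quantile of a spiked OTU = 1" observable
for filtering methods, and it is applied uniformly by `runDAMethod()`,
including to failing subprocess plugins (which additionally carry an error
flag rather than vanishing from the record stream).

# Experiment grids

`experimentGrid()` declares datasets × case proportions × iterations ×
methods (× spike configurations). Per-iteration seeds derive from the
master seed through a counter-based multiplicative hash, so within one
iteration every method sees the identical label assignment and truth set,
runs are reproducible bit-for-bit, and no global RNG state leaks.
Iterations are drawn independently per case proportion. `gridSize()`
reproduces the full study-design bookkeeping (17,550 FPR runs, 175,500
spiked runs, 11,700/117,000 for the six subsets at the 50% proportion,
5,850/58,500 for the within-OTU-permutation dataset; total 386,100).

FPR uses the strict inequality p < 0.05 and is fixed at α = 0.05 for
headline records. AUC uses mid-rank tie handling — with permutation tests
ties are routine, and counting them ½ is what makes an all-ties method
score 0.5 rather than an artefactual 0 or 1.

# Beta-diversity grid

Normalization factors are implemented in the package: TSS (division by
library size); CSS with the data-driven quantile chosen as the first level
where the median absolute deviation of sample quantiles from the mean
sorted-count reference destabilizes (relative change > 0.1, floor 0.5) and
a global scaling constant of 1000; TMM with a 30%/5% M/A trim, asymptotic
inverse-variance weights and geometric-mean-1 factors (matches
`edgeR::calcNormFactors` to machine precision in tests); and
median-of-ratios size factors with per-OTU geometric-mean references over
non-zero counts (log-scale median, geometric-mean-1 scaling; matches
`DESeq2::estimateSizeFactorsForMatrix` with supplied geometric means
exactly). TMM fails loudly on tables so sparse that a sample shares no
positive OTU with the reference; `betaGrid()` records such cells with an
error status instead of dropping them.

Transformations: $\ln(x+c)$ with the zero-preserving correction
$-\ln c$ applied only for $c < 1$ (so $x=0 \mapsto 0$ for every
pseudocount); square and cubic roots; identity. The default pseudocount
presets are 1, 0.01 and 1e-4; the grid accepts arbitrary values (1e-5 is a
commonly used extreme).

Distances: Bray-Curtis and Euclidean via vegan; Jensen-Shannon divergence
implemented here (natural log, $0\log 0 := 0$, no square root — the
divergence itself, not its metric root); UniFrac via phyloseq with the
*normalized* weighted variant as default (bounded in [0,1]). JSD and the
UniFracs are treated as normalization-independent and computed once per
transformation, replicated across normalization rows with a
`replicated` flag — mirroring how such grids are reported in practice.

PERMANOVA runs through `vegan::adonis2` (999 permutations by default,
strata supported); *R*² is deterministic given the distance matrix and
grouping, and the test suite verifies it against a brute-force Gower
sum-of-squares decomposition on random instances.

`agglomerateOtus()` merges OTUs closer (cophenetic tree distance) than the
given quantile of the pairwise distance distribution, using single-linkage
closure and naming each cluster after its highest-count member. The
threshold is the empirical (type-1) quantile with strict inequality, and
exact-zero pairs always merge: interpolated quantiles sit strictly above
the minimum distance for any positive level, which would make the
"no pair qualifies" limit unreachable.

# Numerical and scale choices in the tests

* The type-I calibration criterion runs 150 null label draws of the
  Wilcoxon, Welch *t* and permutation tests on the default 1,000 × 100
  synthetic table; the permutation test uses 1,000 permutations there
  (the reference protocol's 10,000 changes the p-value resolution, not the
  0.05-threshold FPR, and keeps the suite inside its time budget).
* The magnitude-monotonicity criterion is scaled to 25 iterations on a
  250 × 50 table. Medians over 25 iterations carry Monte-Carlo error of
  about 0.02, and the permutation test's AUC plateaus above magnitude 10
  on this world, so adjacent magnitudes are compared with two standard
  errors of the median difference, plus a strict requirement that the
  top magnitude beats the bottom one.
* The NB fold-change recovery simulation plants its signal in 100 OTUs on
  top of a fixed-depth background row. Spiking *all* OTUs would inflate
  case library sizes and let the offset absorb the effect — a useful
  reminder that the offset model measures composition, not absolute load.

# Known limitations

* The generator draws OTUs independently; methods whose failure modes
  depend on inter-OTU correlation or compositional coupling will look
  better here than on real data.
* CSS's data-driven quantile follows the published description of the
  reference procedure; exact tie behaviour of the original implementation
  is not reproducible in this environment and is covered by fixed-quantile
  fixtures instead.
* External DA tools are reached through the plugin contract only; their
  p-value semantics are the plugin author's responsibility, with the
  missing-p rule as the safety net.
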