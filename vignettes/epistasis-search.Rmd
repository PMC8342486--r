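---
title: "Exhaustive epistasis search with epibit: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exhaustive epistasis search with epibit: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epibit)
```

This vignette is the package's account of its statistical model, its
numerical choices, and the scope of what its simulation-based tests can and
cannot show.

## The model

epibit scores sets of bi-allelic SNVs for association with a binary
case/control phenotype.  A genotype is one of 0/0, 0/1, 1/1 (coded 0, 1, 2);
an m-SNV tuple therefore has $3^m$ possible genotype combinations, and the
data for a tuple reduce without loss to a $3^m \times 2$ contingency table
of case and control counts per combination.

Two statistics are computed from the table.  The *purity* of a set holding
$x$ cases and $y$ controls is

$$p(x, y) = \frac{x^2 + y^2}{(x+y)^2} \in [0.5, 1],$$

the Gini-style homogeneity of the set (0.5 = perfectly mixed, 1 = all one
cohort).  The *combined association power* of a tuple is the count-weighted
mean purity over the table rows,

$$\beta = \sum_{i=1}^{3^m} \frac{x_i + y_i}{n}\,
          \frac{x_i^2 + y_i^2}{(x_i + y_i)^2},$$

and the *interaction effect size* is

$$\alpha_{G^m} = \beta_{G^m} - \max_{i} \beta_{G^{m-1}_i},$$

the gain over the best $(m-1)$-subset.  $\beta$ is monotone non-decreasing
under adding an SNV to the tuple (refining a partition can only increase
weighted purity), which has two consequences used throughout: only the
$(m-1)$-subsets need to be examined in the $\alpha$ maximum (their maximum
dominates all smaller subsets), and $\alpha \ge 0$ always — a materially
negative $\alpha$ can only be a counting bug.  For $m = 1$ the subtracted
baseline is the purity of the whole cohort (`betaZero()`), so order-1
$\alpha$ is an ordinary single-marker association score.

A high $\beta$ does *not* imply interaction: one strongly associated SNV
inflates the $\beta$ of every tuple containing it.  $\alpha$ isolates the
joint part, which is the quantity of interest in epistasis analysis; the
package ranks by $\alpha$ by default and reports both.

## The counting engines

The per-tuple cost is dominated by building the contingency table, so the
package implements it three ways and cross-checks them:

* **1-Vector engine** (`countOneVector`, the production path): each cohort's
  genotypes are packed one byte per sample per SNV with the 2-bit genotype
  in the low bits, plus pre-shifted copies at 2, 4 and 6 bits built once at
  encoding time.  For a tuple, the slot-$j$ vector at shift $2(j-1)$ is
  OR-combined into a single byte vector; a 256-bin histogram of that vector
  is the table, rows read off at the $3^m$ legal byte patterns
  ($r = \sum_i g_i 3^{i-1}$, first slot fastest-varying).  The cost per
  tuple is $O(ms)$ independent of $3^m$.  Since a byte holds four 2-bit
  fields, orders are capped at $m \le 4$; widening to 16-bit words would
  double the combined-vector length and was deliberately not done.
* **3-Vector engine** (`countThreeVector`, reference): per SNV, three
  1-bit-per-sample indicator vectors packed into 64-bit words; each of the
  $3^m$ combinations is counted by AND-ing $m$ indicators and popcounting,
  at cost $O(3^m \cdot m \cdot s/64)$.
* **Naive grouping** (`countNaive`, oracle): per-sample row computation and
  tabulation in plain R.

The contract is the byte histogram, not any particular word packing: the
engines must agree cell-by-cell, for ragged cohort sizes (including sizes
not divisible by 8 or 64 — the word packing in the 3-Vector path pads its
last word with zero bits, which count nothing), and any byte outside the
legal patterns raises an error rather than being silently dropped.  The test
suite fuzzes this three-way equivalence over hundreds of random instances
across orders 1–4.

## The search

`exhaustiveSearch()` enumerates combinations in colexicographic order via
the combinatorial number system (`colexUnrank()` is the fixed bijection from
ranks to tuples).  `partitionCombinations()` splits $[0, C(n,m))$ into
contiguous ranges differing in size by at most one; ranges are processed
independently and merged, so output is identical for any worker count.
Before an $\alpha$ scan at order $m$, all $C(n, m-1)$ lower-order $\beta$
values are computed once into a dense flat array indexed by the sorted tuple
(position $\sum_j i_j n^{j-1}$).  The dense layout wastes memory (only
sorted index positions are used) but makes the per-tuple subset lookups
O(1); it is capped at $2^{27}$ entries (1 GiB of doubles), which covers
order-4 scans up to ~500 SNVs — consistent with the intended use after
candidate filtering.

Output determinism: tuples are reported with their SNV ids sorted
(C-locale), ranked by the chosen metric descending with ties broken by the
lexicographic id tuple.  Re-running with permuted input columns yields the
same set of (tuple, β, α) values.  `bestMode()` reports, per SNV and order,
the containing tuple with the highest α.

## Significance

The sampling distributions of α and β are not known analytically, so
`nullDistribution()` builds them empirically: the phenotype labels are
permuted (preserving cohort sizes) and the statistic recomputed.  Genotypes
are fixed under permutation, so each sample's table row is computed once and
only the case/control column assignment is redrawn — for α this includes
recomputing the $(m-1)$-subset βs under the same permutation.

Two p-values are reported, both one-sided (only larger α/β are extreme):

* `empiricalPvalue()` — the plain exceedance ratio
  (# permuted ≥ observed)/n_perm, e.g. 20 of 1000 gives 0.02.  The observed
  value is *not* added to the null (no +1 convention); the ratio can
  therefore reach 0, which simply means "below the resolution 1/n_perm".
* `fittedPvalue()` — for genuinely small p-values, a continuous distribution
  is fitted to the null and $1 - \mathrm{CDF}(\text{obs})$ reported.  The
  null of α/β is positive and right-skewed, so a Gamma is fitted by maximum
  likelihood after shifting the samples just below their minimum
  (shift $= \min - \max(10^{-8}, 10^{-3}\,\mathrm{range})$; the margin keeps
  every shifted value strictly positive, without which the Gamma likelihood
  degenerates at the minimum).  If the Gamma fit fails to converge a Normal
  is used; a zero-variance null falls back to the empirical ratio with a
  warning.  Results are floored at the smallest positive double.

`bonferroni()` corrects per order with the exact test count $C(n, m)$ —
100, 4950 and 161,700 tests for orders 1–3 at 100 SNVs.  No FDR option is
provided in this version.  Default n_perm is 1000; a seed is required so
published runs are reproducible.

## The simulator

`simulateDataset()` emulates the standard penetrance-model benchmark for
epistasis tools: $m$ truth SNVs drawn under Hardy–Weinberg equilibrium from
the model's MAFs, disease status Bernoulli(penetrance of the genotype
combination), batches rejection-sampled until the requested case and
control counts are met exactly (cap: 100 batches of twice the target size),
noise SNVs independent of the phenotype with MAFs uniform in
`noiseMafRange` (default 0.05–0.5, the post-QC MAF spectrum of a typical
GWAS panel), truth columns at seeded random positions.  Default study
conditions follow the usual benchmark design: 100 SNVs, 2000 samples
(1000/1000), 100 replicate datasets for a power estimate.

The model library covers the canonical shapes: `xorPairModel()` (parity
penetrance; at MAF 0.5 it is *strict and pure* — no marginal or subset
association whatsoever), `parityTripletModel()`, `thresholdModel()` (with
marginal effects), `marginalModel()`, `flatModel()` (null).  External
models load from a small JSON interchange format.  The widely used
published benchmark model tables live in supplementary material of their
respective papers, not in any text this package can regenerate from, so the
power evaluation here is property-based: a fully penetrant strict-and-pure
pair must be detected essentially always, a flat-penetrance null at chance
level $1/C(n,2)$, and power must grow with sample size.
`detectionPower()` scores a model as the fraction of replicates whose
planted tuple ranks first by α; anything ranked above the truth counts as a
false positive.

`simulateMixedOrderDataset()` plants three independent truth components in
one dataset — a marginal SNV, a pure parity pair and a pure parity triplet,
all at MAF 0.5 with penetrance
$0.5 + e_1(g_A-1)/2 + e_2\,\pi(g_B,g_C)/2 + e_3\,\pi(g_D,g_E,g_F)/2$
(clipped to [0,1], $\pi = \pm 1$ the parity of the summed codes) — so that
each order's search should surface its own truth variable at the top.

What the simulator does *not* emulate, and hence what passing tests do not
establish about real data: linkage disequilibrium between SNVs (all columns
independent), population structure and relatedness, genotyping error and
missingness, covariates, and quantitative phenotypes.  On real panels these
produce correlated tests and confounded associations that the statistics
here do not model; the permutation p-values remain valid per tuple, but
top-ranked tuples should be interpreted with LD structure in mind.

## Numerical choices and degenerate inputs

* Counts stay exact integers through counting; statistics are computed in
  double precision.
* Empty contingency rows contribute nothing to β: purity(0, 0) is defined
  as 0 and the row's weight is 0, avoiding 0/0.
* α clamp: values in $(-10^{-12}, 0)$ from floating-point cancellation are
  clamped to 0; anything more negative raises an internal-consistency error
  instead of being hidden.
* Ties: the α subtraction uses the max of the subset βs (ties among subsets
  are irrelevant); ranked output breaks metric ties by the lexicographic
  SNV-id tuple, radix (C-locale) sorted, so output files are byte-stable
  across platforms and worker counts.
* Constant SNVs are legal input; a pair of constant SNVs has α = 0 exactly.
* Missing genotypes are rejected at load time by default; the opt-in
  `dropMissingSamples` removes whole samples (and says how many).  Silent
  imputation is deliberately not offered, since every statistic is a pure
  function of the counts.
* Multi-allelic VCF records are refused with a pointer to upstream
  normalization; heterozygote phasing (0/1, 1/0, 0|1, 1|0) is collapsed —
  the statistics are genotype-based.

## Problem sizes in the test suite

The suite verifies the engines and statistics at small, fast scales chosen
as this package's own test design: three-way engine equivalence over 500
random instances (cohorts 1–999, orders 1–4), monotonicity/range properties
over a few hundred fuzzed tuples, a 20-replicate detection-power run at the
full benchmark conditions (100 SNVs, 1000+1000 samples), null-calibration of
permutation p-values over 200 replicate null datasets (200 permutations
each), and mixed-order truth recovery at 30 SNVs.  Power and calibration
checks are stochastic with fixed seeds and tolerance bands stated in the
tests.

## Known limitations

* Order is capped at 4 by the byte layout; higher orders require a
  different packing with different complexity trade-offs.
* The dense β cache bounds order-4 α scans to panels of a few hundred SNVs;
  a sparse cache would lift this at some lookup cost.
* Worker partitioning is deterministic but executed sequentially in-process;
  the partitions are the unit a caller would distribute.
* The Gamma family for the fitted tail is a pragmatic choice validated by
  self-consistency against the empirical ratio in the null bulk and by
  parameter-recovery simulations, not a derived result; extreme tail
  probabilities inherit its extrapolation error.
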