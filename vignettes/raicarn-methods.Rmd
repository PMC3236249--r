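---
title: "Reproducibility ranking of spatial ICA components: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reproducibility ranking of spatial ICA components: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raicarn)
```

## The problem

Spatial independent component analysis (ICA) of resting-state fMRI is not a
deterministic procedure: rerunning the algorithm with a different random
initialisation, or on a different subset of subjects, produces a different
set of component maps, in an arbitrary order and with arbitrary signs. A
component is only worth interpreting if it shows up consistently. This
package quantifies that consistency: it matches components across R
repeated decompositions ("runs"), scores each matched component with a
normalized reproducibility statistic, and attaches a p-value against an
explicit null hypothesis of *no reproducibility*, so the analyst selects
components with a fixed objective cutoff instead of eyeballing correlation
thresholds.

## Matching and the reproducibility statistic

Each run contributes K spatial maps over the same V in-mask voxels. The
cross-realization correlation matrix (CRCM) is the RK × RK matrix of
absolute Pearson correlations between all maps of all runs; absolute
values are used because an ICA map's polarity is arbitrary. Matching is
greedy: the largest between-run entry seeds a matched pair; each remaining
run contributes its best-matching component (when the two seed components
disagree about a run's best candidate, the candidate with the larger
correlation to its seed wins, ties going to the smaller component index);
matched components are then eliminated and the process repeats K times.
Within-run entries never participate in matching — two components of one
decomposition cannot be the "same" component.

Every matched component ends up with exactly one member per run, and
jointly the K matched components partition all RK (run, component) pairs —
an invariant the test suite asserts on every kind of input. The
reproducibility of a matched component is the mean of the R(R−1)/2
pairwise absolute correlations among its members: 1 for perfect
replication, near 0 for unrelated maps. Correlations are averaged
*unthresholded*, so no correlation cutoff has to be chosen.

Tie-breaking everywhere is lexicographic (smallest run, then component
index): on continuous data ties have measure zero, but determinism must
survive degenerate inputs such as duplicated runs. Zero-variance components
(flat maps, e.g. produced by masking accidents) are retained with a flag
and their correlations are defined as 0, so component indices stay aligned
across runs; dropping them would silently desynchronise every downstream
index.

## The permutation null

The null hypothesis is that *no* component reproduces across runs — any
component of any run could equally have come from any other run. It is
simulated by randomly permuting all RK component labels and re-partitioning
them into R pseudo-runs of K (consecutive blocks of the permuted label
sequence), then rerunning the matching on the permuted problem. Because
the statistic only depends on correlations, the permutation is applied
directly to the stored CRCM rows/columns — mathematically identical to
reshuffling the maps themselves and orders of magnitude faster. This is
why the CRCM computes and stores within-run correlations by default: after
relabelling, two components from one original run can land in different
pseudo-runs, and their correlation must be available.

Each of S permutations yields K null reproducibility values; the pooled
S·K values form the null distribution, and a matched component's p-value
is the fraction of pooled null values at or above its observed statistic
(inclusive). S defaults to 100, giving a pool of 100·K and a p-value
resolution of 1/(100·K); the p-value 0 is reported as "< 1/pool" rather
than smoothed, with a +1 pseudo-count variant available behind a flag.
Selection uses the raw fixed cutoff alpha = 0.05 by default;
Benjamini–Hochberg adjustment is available but off, since a fixed
objective cutoff is the reference behaviour.

Two properties of this null are worth understanding before interpreting
p-values:

* It *preserves the observed structure*: the null pool is built from the
  observed correlations, only the run labels are broken. With genuinely
  reproducible structure in a *small* problem, a random permutation
  occasionally reassembles an entire matched cluster, placing null mass at
  the observed value itself. With the R and K of realistic analyses
  (tens of runs) this probability is negligible, but in toy examples
  (e.g. exact duplicate runs, R·K ≈ 20) the p-value of a perfectly
  reproducible component is *not* small — the method is honest about the
  fact that duplicated data cannot testify about reproducibility.
* Under a true null (pure noise runs), observed and permuted statistics
  are exchangeable, so p-values are uniform — the test suite checks this
  with a Kolmogorov–Smirnov test over 200 replicate experiments.

## Two-group comparisons

For comparing groups A and B, components are matched across the pooled
runs of both groups; each matched component then gets a reproducibility
score and p-value restricted to A's members (against a null built from A's
own CRCM) and likewise for B. Only components separately significant in
both groups are flagged as candidates for between-group contrasts.

## How many subjects per group-ICA run?

When runs are group-ICA fits on random d-subsets of N subjects, the
subsets must be diverse, or the runs are near-copies and reproducibility
is overstated. For a fixed pair of subjects, the probability of
co-occurring in one random d-subset is d(d−1)/(N(N−1)); the planner takes
a user bound beta on this probability (default 0.05) and returns the
largest d with d(d−1) ≤ beta·N(N−1). At N = 23 and beta = 0.05 this gives
d = 5. The number of runs G should be as large as the budget allows;
results stabilise by around G = 50, the default. Groups are drawn
independently and uniformly without replacement within a group — the
diversity constraint bounds the *expected* co-occurrence count G·p, not
each realisation.

## From selected components to displayable maps

Selected components are turned into group-average statistic maps in four
steps:

1. **Sign alignment.** Members are re-signed using raw (signed)
   correlations against a reference member (the one with the largest
   summed absolute correlation to the rest). The common polarity remains
   arbitrary — a "negative" network is the same network.
2. **Rank-based Gaussianisation.** Each member map's intensity
   distribution is transformed to normality by mapping mid-ranks through
   the standard-normal quantile function. The operation
   `rank_gauss_transform()` also offers the per-voxel variant (each
   voxel's R values transformed across runs), but the pipeline uses the
   per-map transform: transforming within a voxel's column replaces every
   voxel by the *same* symmetric quantile multiset, which makes the
   group mean identically zero and would render the group t map
   uninformative. The per-map transform instead tames heavy-tailed map
   intensities while preserving each map's spatial ordering, which is
   what the subsequent group test needs.
3. **Group-average t map.** A one-sample t statistic per voxel
   (mean/(sd/√R), R−1 degrees of freedom); equivalent to ordinary least
   squares with a single group-average design.
4. **Mixture thresholding.** The t values are modelled as a three-class
   mixture: a central Student-t null plus a positive and a negative Gamma
   class on the half-lines, representing supra-null non-Gaussian
   structure. Voxels whose Gamma posterior exceeds tau (default 0.5, the
   maximum-a-posteriori rule) are labelled active.

### Mixture details

The mixture density is
pi_t·t_ν(x) + pi₊·Gamma(x; k₊, θ₊)·1{x>0} + pi₋·Gamma(−x; k₋, θ₋)·1{x<0},
fitted by EM. Choices that were genuinely open, and how they were fixed:

* **Degrees of freedom ν.** Fixed to R−1 by default — the sampling
  distribution of the t map under the per-voxel null. An `"estimate"`
  option profiles ν by an inner one-dimensional optimisation; note that on
  pure-t data the Gamma classes absorb part of the tails, biasing the
  estimated ν upward, which is why the fixed default is preferred.
* **Gamma support.** Gammas sit on the half-lines with no location shift.
  (Other mixture-based thresholding traditions shift the Gamma away from
  zero; without a stated shift we keep the simpler unshifted form — a
  documented divergence to revisit.)
* **Initialisation.** Values below the 2.5% quantile seed the negative
  Gamma, above the 97.5% quantile the positive Gamma, the middle the t
  class, with method-of-moments Gamma starts. The M-step uses weighted
  Gamma maximum likelihood (Newton on the shape), so the log-likelihood
  trace is non-decreasing — asserted on every fit in the tests.
* **Numerical guards.** Class fractions are floored at 1e−6 and a class at
  the floor is reported degenerate with its parameters frozen; tolerance
  is 1e−6 on the mean log-likelihood, at most 500 iterations.

On pure Student-t input the Gamma fractions collapse (the tests require
pi₊ + pi₋ < 0.02 on 50,000 draws from t with ν = 22), and a planted 20%
positive-Gamma contamination is recovered to within 0.05 — so the mixture
separates "null map" from "structured map" rather than thresholding
arbitrary percentiles.

## The synthetic generator

`synthetic_spec()`/`generate_runs()` define the study conditions all
simulation tests run under. Defaults: R = 10 runs, K = 8 components,
V = 2000 voxels, 4 planted sources, snr = 1. Planted sources are sparse
maps — 5% active voxels with Gamma(shape 4, scale 1) amplitudes,
normalised to unit standard deviation — because empirical IC maps look
like a central Gaussian bulk plus a one-sided heavy tail, and the mixture
stage needs genuine positive tails to find. Each run receives every
planted source with a random sign flip and at a random component slot
(forcing the matcher to handle both identifiability ambiguities of ICA),
plus iid Gaussian noise with standard deviation 1/snr; remaining slots are
pure-noise components. At snr = 1 the expected between-run correlation of
a planted component is 1/(1 + 1/snr²) = 0.5, comfortably above the null
matching level of iid maps at V = 2000 (≈ 0.05) — a regime where detection
should be essentially certain, and the tests require ≥ 95% of replicates
to select all planted components with exactly correct membership.

The planted sources are drawn from a substream that depends only on the
seed and the source dimensions, so adding runs does not change the
sources. What the generator does **not** emulate: spatial autocorrelation
(voxels are independent), hemodynamics and physiological noise, component
splitting/merging across model orders, and between-subject anatomical
variability. Passing tests on this generator therefore demonstrate the
statistical machinery — matching, calibration, power, recovery — not
robustness to the full messiness of real fMRI.

`generate_group_timeseries()` and `group_ica_harness()` provide the
temporal-concatenation group-ICA path: per-subject demeaning, per-subject
(or pooled) PCA reduction, temporal concatenation, whitening, and a
caller-injected unmixing backend; a compact symmetric fixed-point ICA
(`fastica_backend`) is bundled as the default backend, and an identity
backend returns the whitened principal-component maps.

## Problem sizes and runtime

The test suite and examples run at the generator's default scale
(R = 10, K = 8, V = 2000): one CRCM takes ~10 ms and a 100-permutation
null pool ~0.2 s, so 200-replicate calibration studies complete in about
a minute on one CPU. Null calibration uses 200 replicates × 100
permutations; power uses 50 replicates; mixture recovery uses 20,000-value
samples across 20 seeds.

## Degenerate inputs and edge rules

* A single run cannot enter the analysis (matching and the statistic are
  undefined at R = 1).
* Masks must be shared: volumes entering one analysis are flattened by a
  single common mask, row-major over the grid restricted to the mask.
  When per-run masks differ, intersect them upstream and pass the
  intersection — correlations over differing supports are not comparable.
* NaN entries in a CRCM are a validation error, never silently skipped.
* Zero-variance voxels in the t map get t = 0 with a flag; constant
  columns under Gaussianisation map to 0 with a flag.
* All randomness (null permutations, group draws, synthesis) flows from a
  single master seed through derived substreams; identical configuration
  and seed reproduce every output byte-for-byte.

## Known limitations

Reproducibility is not biological relevance: a consistently recurring
artifact (motion, vasculature) is highly reproducible. The analysis ranks
and selects; it does not interpret. The permutation null conditions on the
observed correlation structure, which makes it data-driven but also means
pathological inputs (exact duplicates, tiny R·K) yield conservative
p-values, as described above. And the greedy matcher, like the original,
is order-dependent by construction: it maximises each extraction locally
rather than solving a global assignment problem.

```{r example, eval = FALSE}
# A complete synthetic analysis at the default study scale
sim <- generate_runs(synthetic_spec(R = 10, K = 8, V = 2000,
                                    n_planted = 4, snr = 1, seed = 7))
fit <- raicarn(sim$runs, n_sims = 100, seed = 42)
summary(fit)
tm <- reproducible_tmaps(fit)
mix <- fit_tgg_mixture(tm[1, ], dof = attr(tm, "dof"))
table(classify_voxels(mix, tm[1, ]))
```
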