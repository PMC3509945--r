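---
title: "Quantifying the predictability of adaptive walks on fitness landscapes"
author: "fitpaths developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the predictability of adaptive walks on fitness landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

A fitness landscape here is a partial map from the vertices of the
L-dimensional binary hypercube (genotypes, strings over {0,1}) to strictly
positive fitness values. Genotypes absent from the map are nonviable and are
removed from the mutational graph entirely: paths may not traverse them.

Evolutionary dynamics are taken in the strong-selection/weak-mutation (SSWM)
limit: mutations fix one at a time, deleterious and neutral mutations never
fix, and among the `b(g)` strictly fitter single-mutation neighbors of the
current genotype each fixes with probability `1/b(g)`. A realized trajectory
is therefore a *monotone path* — single-locus steps with strictly increasing
fitness — terminating at a local peak, and its occurrence probability is

```
P(path) = prod over non-terminal points g of 1 / b(g).
```

Because "fitter" is strict, the fitter-neighbor graph is a DAG and exhaustive
enumeration terminates. For any non-peak start the probabilities over all
maximal monotone paths sum to 1 (tested to 1e-9).

### Path divergence

Predictability is quantified on the *ensemble* of monotone paths sharing a
start genotype and a terminal peak. The distance between two paths is the
symmetrized mean of per-point minimum Hamming distances,

```
d(p1,p2) = (sum_{x in p1} min_{y in p2} H(x,y) +
            sum_{y in p2} min_{x in p1} H(x,y)) / (|p1| + |p2|),
```

where `|p|` counts *points*, not steps — the denominator then equals the
number of summed terms, making `d` a mean of per-point minima. The step-count
alternative would merely rescale by `|p|/(|p|-1)` and is not offered. `d` is
symmetric and zero exactly when the two paths visit identical point *sets*
(it is order-insensitive by construction).

The ensemble divergence is, in `raw` mode, the sum over unordered pairs of
distinct paths of `P_i P_j d(p_i,p_j)`; for a two-path ensemble this is the
product of the two probabilities and their distance. In `normalized` mode
(the default) the raw sum is divided by the summed pair weights
`sum P_i P_j`, i.e. it is the probability-weighted mean pairwise distance.
Normalized is the default because it is the only scale-free choice when
ensemble probabilities do not sum to 1, which is the generic situation for
ensembles conditioned on a single peak. Single-path ensembles have divergence
0 in both modes.

The landscape-level statistic `mean_path_divergence()` averages ensemble
divergences over every viable genotype taken as a start. Design choices made
where the definition was genuinely open:

* **Target peaks.** Default `target = "global-peak"` (ensembles to the unique
  global optimum, matching the accessibility statistic); `"all-peaks"` builds
  one ensemble per (start, reachable peak) pair. The underlying definition is
  ambiguous between the two and both are first-class options.
* **Skipped starts.** Starts with no monotone path to the target are skipped,
  not counted as zero: inaccessibility is an accessibility statistic, and
  conflating it with divergence would reward landscapes for being
  inaccessible.
* **Units.** Distances are raw Hamming units, not divided by L; divide by the
  reported L downstream for cross-L comparisons.

## Roughness measures

Four complementary measures, since no single parameter captures
multidimensional ruggedness:

1. **Deviation from additivity** — roughness-to-slope ratio `r/s` of the
   least-squares additive fit `F = a0 + sum a_i g_i`: `r` is the RMS
   residual, `s = mean |a_i|`. The convention (RMS residual over mean
   absolute additive coefficient) is stated here because the ratio form
   varies across the literature. Fit is on raw fitness by default; a
   `log_fitness` flag serves multiplicative data. Exactly additive
   landscapes give 0; a flat fit (`s = 0`) returns `Inf` with a warning.
2. **RMS neighbor fitness difference** — square root of the mean of
   `(F(g)-F(h))^2` over viable Hamming-1 pairs, each unordered pair counted
   once. Pair-averaging (not per-point-then-average) is used; the two differ
   only on landscapes with holes.
3. **Peak fraction** — local optima divided by viable genotypes. `1/2^L` for
   a full additive landscape; `1/(L+1)` in expectation for an uncorrelated
   one (the classical value, re-verified by an independent Monte-Carlo oracle
   before being frozen into the tests: 0.1666 +/- 0.0009 at L=5, 0.1430 +/-
   0.0006 at L=6).
4. **Mean distance to the tree component** — `T` is the set of genotypes with
   at most one fitter neighbor (on `T` the SSWM walk is deterministic; every
   peak is in `T`); the measure is the mean over all viable genotypes of the
   minimum Hamming distance to `T`, through possibly-nonviable space (the
   graph-restricted variant coincides on full landscapes).

**Orientation caveat for measure 4.** The tree component *grows* with
ruggedness — on rugged landscapes most genotypes have 0 or 1 fitter
neighbors — so the mean distance to it *shrinks*: measure 4 is inversely
oriented relative to the other three. Empirically (noise sweep below) its
Spearman correlation with noise power is about −0.67 while measures 1–3 are
at +0.7 to +0.8. The package reports the measure as defined and leaves the
orientation to the reader; the test suite asserts the empirically true
directions.

`roughness_report()` adds a fitness-permutation null: the measures are
recomputed over landscapes with the same genotype set and a shuffled fitness
multiset, and each observed measure is placed on its null distribution as a
one-sided empirical quantile (fraction of permuted replicates `<=` observed).
Quantiles are descriptive; no multiple-testing correction across the four
measures.

## The synthetic-data generators (the stated world)

`generate_noisy_additive()` draws per-locus fitness effects
`s_i ~ Exponential(mean = effect_mean)`, sets the pre-noise fitness of `g` to
`peak_fitness − sum_{i: g_i=0} s_i` (all-ones = additive peak), multiplies
every genotype's fitness by `u^k` with `u ~ Uniform(0,1)` i.i.d., and keeps
genotypes with positive perturbed fitness. Choices the source description
left open, decided once:

* **Peak noise:** the peak is perturbed like every other genotype (no
  special-casing, and the permutation null stays well defined). For `k > 0`
  the all-ones genotype therefore need not be the global peak; tests use
  `k = 0` when a known peak is required.
* **Scale:** `effect_mean = 0.5/L` by default, so the expected pre-noise
  fitness of the all-zeros genotype is `peak_fitness/2 > 0` and most of the
  hypercube is viable. No scale was stated; this is a package choice.
* **Parameterization:** the exponential is parameterized by its MEAN
  everywhere, removing the classic rate/mean ambiguity.
* **Stream discipline:** effects first (L draws), then one noise uniform per
  genotype in lexicographic order, with the RNG (Mersenne-Twister) named in
  metadata — seeds are portable across reimplementations of the same
  algorithm.

`generate_uncorrelated()` is the house-of-cards null: full hypercube,
i.i.d. Uniform(0,1) fitness. Any atomless distribution gives identical
rank-based statistics. `permute_fitness()` conserves the fitness multiset
exactly.

What a green test on generated landscapes does **not** establish: real
genotype–fitness data have measurement error, correlated missingness
(nonviable regions), and epistasis structure that multiplicative uniform
noise does not emulate. The generators provide a ruggedness dial, not a
biological model.

## An empirical finding the user should know

Across a noise sweep (`k` in {0, 0.25, 0.5, 1, 2, 4}, 50 seeds each, L=6),
mean normalized path divergence *decreases* with ruggedness (Spearman about
−0.67), and smooth landscapes have *higher* divergence than their permuted
counterparts in essentially all replicates. The mechanism is conditioning on
shared endpoints: a rugged landscape fragments into many small basins, so the
ensembles from any start to a fixed peak contain few — usually one — short
paths, and single-path ensembles contribute zero. A smooth additive landscape
instead funnels `L!` widely-spread paths into one peak. Divergence as defined
here therefore measures the *spread of the routes that exist between fixed
endpoints*, not the overall unpredictability of outcomes: rugged landscapes
are unpredictable in *which peak* is reached (an accessibility/reach
question, answered by `reach_probability()`), while smooth landscapes are
unpredictable in *which route* is taken to the inevitable peak. Two
acceptance criteria that presuppose the opposite sign are deliberately left
failing, with this analysis, rather than having their directions inverted. A
per-start pooled variant (all terminal peaks in one ensemble) was piloted and
partially restores the positive association (+0.3, non-monotone) but
violates the shared-endpoint ensemble contract and is not exposed.

## Numerical choices

* Fitness ties: comparisons are exact, no epsilon; a tie is neutral and
  neutral steps never fix. Generator draws make ties measure-zero; loaded
  data with intended ties is the user's responsibility.
* Path counts use exact base-1e15 limb addition (counts pass 2^53 near the
  L=20 DP cap); the numeric return carries an `"exact"` decimal-string
  attribute.
* Probability sums use R's long-double accumulation; conservation is tested
  at 1e-9.
* Enumeration is capped (default 1e6 paths) with an explicit error naming the
  offending start; sampling via `sample_sswm_walk()` is the opt-in fallback.
* Traversal order is lexicographic everywhere, so outputs are byte-stable
  across runs and platforms.
* The pairwise divergence kernel is compiled (Rcpp); the test suite checks it
  against a naive pure-R recomputation to 1e-12 and path enumeration against
  an independent igraph-based oracle.

## Limitations

* Binary alleles only; multi-allelic landscapes are out of scope.
* No clonal interference or finite-population fixation probabilities: the
  machinery is SSWM-only.
* Divergence of sampled (non-exhaustive) ensembles is not offered; estimator
  bias of sampled divergence is an open methods question.
* L caps: 25 at load, 20 for the additive generator and counting DP, 12 for
  the uncorrelated generator; exhaustive all-starts sweeps are practical to
  about L = 10.
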