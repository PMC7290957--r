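---
title: "Scoring Y-STR loci for population differentiation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring Y-STR loci for population differentiation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ystrdiff)
```

This vignette is the package's own account of its statistical machinery:
the models and estimators, the assumptions they lean on, the parameters
worth tuning, and the design choices made where several defensible options
existed.

## 1. Input model and quality control

A haplotype table holds one row per male sample — sample id, population id,
and one allele call (a repeat count) per Y-STR locus. Because the Y
chromosome does not recombine, the row is a single haplotype, and every
statistic here treats it as the sampling unit.

Raw genotyping output contains call classes that break frequency-based
analysis, and `qc_filter()` removes the *whole haplotype* when any analysis
locus carries one of them:

* **null** calls — empty cells or sentinel tokens (`""`, `NA`, `null`,
  `-`, `.`), plus anything unparseable;
* **intermediate** (microvariant) alleles — non-integer repeat counts such
  as `13.2`, which are real alleles but incommensurable with the
  repeat-count arithmetic of the distance metric;
* **multi-valued** calls such as `17,18` — duplications at a nominally
  single-copy locus.

Whole-haplotype removal (rather than per-locus masking) keeps every locus's
sample size identical within a population, which the AMOVA and the mAFD
comparison across loci both implicitly assume. A record with several
problems is counted once under the first applicable reason in the fixed
order null → intermediate → multi-valued; the order is arbitrary but frozen
so QC reports are reproducible. The report carries both global and
per-population removal counts, since either grouping can be the relevant
one when auditing a compilation.

Two structural conventions: the multi-copy loci (DYS385a/b, DYF387S1a/b)
are excluded from analysis panels — their two unordered values do not fit a
single-locus frequency spectrum — and the nested pair DYS389I/II is
decomposed by `adjust_dys389()`, which replaces DYS389II with
DYS389II − DYS389I because the DYS389II amplicon physically contains
DYS389I. The decomposition runs *after* QC: subtraction is only meaningful
once both calls are known integers, and applying it to microvariant calls
would silently corrupt them. A table-level flag refuses a second
application, since the operation is not idempotent.

## 2. The AFD statistic and the mAFD ranking

For one locus and two populations with allele-frequency vectors $f_1, f_2$:

$$\mathrm{AFD} = \tfrac12 \sum_{i} \lvert f_{i1} - f_{i2} \rvert$$

summed over the **union** of alleles observed in either population, with
absent alleles contributing frequency zero. The union is the only
dataset-complete choice for the summation index: any fixed global allele
registry either misses alleles or pads both spectra with shared zeros,
neither of which changes the value — so the union convention is also the
canonical one. AFD is half an L1 distance, hence symmetric, bounded in
$[0, 1]$, and satisfies the triangle inequality; the property tests assert
all three on random spectra.

The per-locus score is the **mAFD**: the unweighted arithmetic mean of AFD
over all $\binom{P}{2}$ unordered population pairs. It is unweighted by
population size deliberately — the score is meant to characterize the locus
across a roster of populations, not to estimate a population-size-weighted
average, and weighting would let a few large samples dominate the ranking.
`mafd_table()` ranks loci by descending mAFD with ties broken
lexicographically by locus name, so the ranking is deterministic.

The package ships a reference ranking (`reference_mafd()`) for the 23
single-copy Yfiler Plus loci, estimated from a 41-population compilation of
20,927 quality-filtered haplotypes, together with per-locus mutation-rate
point estimates and binomial 95% intervals. Its headline features — DYS392
largest (0.3802), YGATAH4 smallest (0.1845), 9 of the top 15 loci from the
Yfiler set — are asserted exactly in the test suite. No mAFD value exceeds
0.4: single Y-STR loci are individually weak differentiators, which is
precisely why ranking and panel construction matter.

`mafd_rate_correlation()` quantifies how much of the ranking mutation rate
explains. On the reference table both coefficients are small and negative
(Pearson r ≈ −0.20, Spearman ρ ≈ −0.27, neither significant at n = 23),
supporting the reading that drift and founder effects, not mutation
pressure, drive between-population allele-frequency differences. Zero
variance in either variable is reported as a flagged degenerate result
rather than an error, since constant mutation-rate columns are a legitimate
input.

**Sliding panels.** `sliding_panels()` windows the descending ranking
(default width 15, step 1), so the first panel is the top-15 and the last
the minimum-15; 23 ranked loci give 9 panels. Comparing the two extreme
panels is the package's built-in validation of the ranking.

## 3. AMOVA Φst and permutation testing

Pairwise population distances are fixation indices from a two-level
analysis of molecular variance on inter-haplotype distances. With
$\delta^2_{ij}$ the squared distance between haplotypes $i, j$:

$$SSD_T = \frac{1}{N}\sum_{i<j}\delta^2_{ij}, \qquad
  SSD_W = \sum_k \frac{1}{n_k}\sum_{i<j \in k}\delta^2_{ij},$$

$\sigma^2_w = SSD_W/(N-P)$,
$\sigma^2_a = (SSD_A/(P-1) - \sigma^2_w)/n_c$ with
$n_c = (N - \sum_k n_k^2/N)/(P-1)$, and

$$\Phi_{ST} = \frac{\sigma^2_a}{\sigma^2_a + \sigma^2_w}.$$

The default inter-haplotype distance is the **sum of squared repeat-count
differences** over the panel loci, giving the $R_{ST}$-analogue that is the
standard choice for STR haplotypes under stepwise mutation; a Hamming
metric (count of differing loci, the $F_{ST}$-analogue) is available via
`hap_dist_spec()`, and results are labeled with the metric used. Which of
the two a given legacy analysis used is often unknowable, which is exactly
why both are exposed and neither is asserted as "the" distance.

Numerical conventions:

* Variance-component estimates can make $\Phi_{ST}$ slightly **negative**
  (identical populations hover around zero). Estimates are reported as
  computed; clamping to zero happens only at MDS input, where a
  dissimilarity must be non-negative, and can be disabled
  (`clamp_negative = FALSE`).
* The permutation p-value uses the add-one estimator
  $p = (\#\{\Phi^{perm} \ge \Phi^{obs}\} + 1)/(n_{perm} + 1)$, which never
  returns 0 and is exactly valid under the null. The default
  $n_{perm} = 10{,}000$ with $\alpha = 0.05$ matches common practice for
  forensic population comparisons; the test suite uses 30–500 permutations,
  which changes only the resolution of p, not the estimator.
* Each population pair draws its permutations from an RNG stream derived
  from the global seed and the *sorted* pair ids, so a distance matrix is
  reproducible whatever the order pairs are computed in, and
  `phist(A, B) = phist(B, A)` including p-values.
* The permutation comparison uses a $10^{-12}$ tolerance on
  $\Phi^{perm} \ge \Phi^{obs}$ so that ties produced by identical
  partitions are counted as exceedances rather than lost to floating-point
  noise.

`compare_distance_matrices()` aligns the population pairs of two matrices,
orders them by ascending reference distance (the line-chart convention for
panel comparisons), and reports the fractions of pairs that increased,
decreased, or tied under the alternative panel, with a configurable tie
tolerance (default $10^{-12}$).

## 4. Multidimensional scaling

`classical_mds()` is Torgerson's classical scaling: double-center the
squared dissimilarities and take the top-$k$ spectral decomposition
(delegated to `stats::cmdscale`, which implements exactly this). It is
exact — zero stress — whenever the input distances are Euclidean, which the
tests assert on planar point sets via Procrustes residuals below $10^{-8}$.
Three determinism conventions make embeddings byte-reproducible: axes
ordered by eigenvalue, configuration centered at the origin, and each
axis's first nonzero coordinate made positive (sign of an eigenvector is
otherwise arbitrary). Rank-deficient inputs are padded with zero axes; an
all-zero dissimilarity matrix embeds as all points at the origin with
stress defined as 0.

Misfit is Kruskal's stress-1,
$\sqrt{\sum_{i<j}(\hat d_{ij} - d_{ij})^2 / \sum_{i<j} d_{ij}^2}$.
Φst matrices are generally non-Euclidean, so stress is nonzero and worth
reporting alongside every plot. `smacof_refine()` optionally improves a
configuration by iterated Guttman transforms, whose stress sequence is
provably non-increasing (asserted as a property test); iteration stops at a
stress decrease below `tol` ($10^{-10}$) or `max_iter` (300). Raw clamped
distances are embedded as-is — no standardization or monotone
transformation is applied, and nonmetric MDS is out of scope — so the
embedding answers "how far apart are these populations on this panel", not
"in what order".

## 5. The synthetic-data generator

`simulate_populations()` is a forward Wright–Fisher simulator of haploid
haplotypes on a **star phylogeny**: one ancestral population of `pop_size`
haplotypes accumulates standing variation for `burn_in` generations, then
each daughter population is founded by `founder_size` draws, expands
immediately to `pop_size`, and drifts independently for its
`generations_since_split`. Mutation is the strict single-step model — each
locus mutates with its per-generation rate, moving ±1 repeat with equal
probability — with a reflecting boundary at 1 repeat so counts stay
physical. Ancestral repeat counts are drawn from the typical Y-STR modal
range 10–17, except DYS389II, which is set 14–18 repeats above DYS389I so
the nested-amplicon decomposition stays positive under drift.

Defaults (5 populations × 100 haplotypes, founder 50, 50 generations since
split, 300 burn-in generations, the reference per-locus mutation rates of
order $10^{-4}$–$10^{-2}$) were chosen once to emulate *moderate*
differentiation: under them per-locus mAFD spans roughly 0.01–0.65 with
mean ≈ 0.3, the same order as real global compilations, and Φst between
populations is clearly positive but far from fixation. Realistic effective
sizes for matching any particular dataset are unknown; the parameters are
exposed rather than claimed calibrated.

What the simulator deliberately does **not** emulate: migration and
admixture between populations after the split, non-star topologies (a
balanced tree can be approximated by nesting calls, but no tree argument is
offered), multi-step mutations, locus-specific allele-size constraints, and
linkage of mutation events across loci within a transmission. Passing tests
therefore demonstrate that the statistics behave correctly under a clean
drift-plus-stepwise-mutation null — not that the pipeline's numerical
output on real compilations would match any published value.

Two auxiliary generators support calibration work: `sample_from_spectra()`
draws haplotypes from explicitly prescribed allele spectra (loci
independent), so the analytic AFD of the generating spectra is known and
panmictic data are produced by reusing one spectrum set under two labels;
`inject_qc_noise()` plants null/microvariant/duplicated calls at known
rates to exercise the QC accounting.

## 6. Pipeline orchestration and reproducibility

`run_characterization()` executes ingest → QC → DYS389 adjustment → mAFD
ranking → sliding panels → distance matrices → comparison → MDS. The two
extreme panels (top-15, minimum-15) always receive the full distance +
comparison + MDS treatment, since their contrast is the point of the
ranking. Every stage failure is re-raised with the stage name. All
randomness — simulation and permutation streams — derives from the single
configured seed, and `write_run_report()` output is byte-identical across
reruns; provenance (package version, seed, MD5 of the deparsed
configuration) is written alongside the artifacts.

Test-suite problem sizes were chosen to keep the default run fast while
leaving the asymptotics visible: oracle equivalence on ≤ 10 haplotypes per
population, calibration at 500 replicates × 500 permutations, simulator
monotonicity over 20 seeds at population size 30–40, and spectrum recovery
at n = 10,000 within 0.02 absolute. These are the package's own choices of
instance size; all statistics scale to the defaults (10,000 permutations,
dozens of populations) linearly in pairs and permutations.

## 7. Known limitations

* mAFD depends on the population roster: it is a property of a locus *in a
  collection*, not a universal constant. Adding populations shifts values,
  though rank order is empirically fairly stable.
* The AMOVA here is strictly two-level; hierarchical designs
  (regions/populations) are out of scope.
* Negative Φst values, while reported, have no population-genetic
  interpretation beyond "no detectable differentiation".
* Classical MDS on strongly non-Euclidean Φst matrices can misorder close
  pairs; check `stress` and consider `smacof_refine()` before reading fine
  structure off a plot.
* Microvariant alleles are removed, not modeled; loci where microvariants
  are common (e.g. DYS458) lose real signal at QC.
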