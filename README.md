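# ystrdiff

Characterizing individual Y-STR loci for their contribution to population
differentiation.

## The problem

Y-chromosomal short tandem repeats (Y-STRs) are typed as a single
non-recombining haplotype and are routinely used to resolve population
structure through pairwise genetic distances and multidimensional scaling
(MDS). Commercial panels (Yfiler, 17 loci; Yfiler Plus, 27 loci) bundle loci
of very different behavior, and adding loci to a panel does not uniformly
shrink pairwise distances — some population pairs move further apart. That
raises a marker-selection question: *which individual loci carry the
population-differentiation signal?*

`ystrdiff` implements a per-locus differentiation score and the evaluation
machinery around it, for forensic and population geneticists choosing or
auditing Y-STR panels.

## The statistics

**AFD.** For one locus and two populations with allele-frequency vectors
*f*<sub>1</sub>, *f*<sub>2</sub>, the allele frequency difference is half
the L1 distance over the union of observed alleles:

> AFD = ½ Σ<sub>i</sub> | f<sub>i1</sub> − f<sub>i2</sub> |

AFD is 0 for identical spectra and 1 for disjoint allele sets. The
**mAFD** of a locus is the unweighted mean of AFD over all C(P, 2)
unordered population pairs; loci are ranked by it, and sliding 15-marker
panels are built down the ranking (23 ranked loci → 9 panels).

**Panel evaluation.** Pairwise genetic distances between populations are
Φ<sub>ST</sub>-type fixation indices from a two-level AMOVA on
inter-haplotype distances (default: sum of squared repeat-count differences,
the R<sub>ST</sub>-analogue appropriate under stepwise mutation; a Hamming
option gives the F<sub>ST</sub>-analogue). Significance comes from
permutation tests (haplotypes reshuffled between the two populations,
add-one p-value estimator, default 10,000 permutations, α = 0.05).
Distance matrices are embedded in 2-D by classical (Torgerson) MDS with
Kruskal stress-1 as diagnostic, optionally refined by SMACOF.

**Synthetic data.** A seeded star-split Wright–Fisher forward simulator
(per-locus stepwise mutation, founder bottlenecks, optional QC-noise
injection) generates multi-population haplotype tables so every stage is
testable without external data.

## Worked example

```r
library(ystrdiff)

# packaged reference ranking: 23 single-copy Yfiler Plus loci scored on a
# 41-population compilation of 20,927 haplotypes
ref <- reference_mafd()
head(as.data.frame(ref), 5)
#>    locus   mafd n_pairs mutation_rate in_yfiler
#> 1 DYS392 0.3802      NA      0.000496      TRUE
#> 2 DYS438 0.3507      NA      0.000351      TRUE
#> 3 DYS635 0.3379      NA      0.004210      TRUE
#> 4 DYS481 0.3359      NA      0.004880     FALSE
#> 5 DYS449 0.3271      NA      0.009440     FALSE

sp <- sliding_panels(ref)            # 9 windows of 15 loci
sum(sp$panels$top_15$loci %in% builtin_panels()$yfiler$loci)
#> [1] 9                              # 9 of the top 15 are Yfiler loci

# mAFD barely tracks the mutation rate: drift/founder effects dominate
mafd_rate_correlation(ref)[c("pearson_r", "spearman_rho")]
#> $pearson_r    [1] -0.2035801
#> $spearman_rho [1] -0.2677866

# full pipeline on simulated data: 5 populations x 100 haplotypes
cfg <- run_config(simulation_config(n_populations = 5, seed = 7),
                  n_perm = 1000, seed = 7)
run <- run_characterization(cfg)
summary(run)
#> Y-STR characterization run (seed 7, config 7a7ebb73)
#>   haplotypes retained: 500/500; populations: 5; loci ranked: 23
#>   panels: 9 (window 15, step 1)
#>   mAFD range: DYS389II 0.6200 (max) ... DYS393 0.0060 (min)
#>   panel top_15     mean Phi-st 0.2498, MDS stress-1 0.0228
#>   panel min_15     mean Phi-st 0.1738, MDS stress-1 0.1149
#>   comparison top_15_vs_min_15: 100.0% of pairs increased
```

The summary reads: the 15 loci with the largest simulated mAFD produce
uniformly larger pairwise Φ<sub>ST</sub> than the 15 loci with the smallest
mAFD, and their MDS embedding reproduces the distance structure with far
lower stress — the mAFD ranking identifies the informative loci.
`write_run_report(run, "out/")` writes every artifact (QC JSON, mAFD TSV,
panels, PHYLIP + TSV distance matrices, MDS coordinates) deterministically;
`render_figures(run, "out/")` draws the ranked-distance line charts, the
mAFD/mutation-rate dual-series chart and the labeled MDS scatters.

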