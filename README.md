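# epientropy

Epiallele entropy analysis for whole-genome bisulfite sequencing (WGBS)
cohorts — quantifying *how variable* DNA methylation is, rather than how
high it is, and locating where that variability lives in a population.

The package is written for population epigenomics settings such as the
marine/freshwater stickleback system: two ecotypes, both sexes, per-read
methylation data, and externally defined region sets (divergence islands,
adaptation-associated haplotype peaks, promoters) in which epigenetic
stochasticity is compared between groups.

## The statistic

Each sequenced fragment reports the methylation state (M/U) of the CpGs it
covers. In a sliding window of *b* consecutive CpGs (default *b* = 5, step
1 CpG), fragments covering all *b* sites contribute their length-*b*
pattern — an **epiallele**. With *n<sub>i</sub>* reads showing the *i*-th of
*k* observed patterns and *N* reads total, the methylation entropy is

$$H = -\frac{1}{b}\sum_{i=1}^{k} \frac{n_i}{N}\,\log_2 \frac{n_i}{N}$$

(0 ≤ H ≤ 1 for a 5-CpG window with at least 2⁵ = 32 reads; windows below 32
pooled fragments are flagged instead of estimated). Pooled-group entropy is
decomposed as

*H*<sub>pooled</sub> = *H*<sub>within</sub> + *H*<sub>between</sub>,

where *H*<sub>within</sub> is the coverage-weighted mean of per-individual
entropies and *H*<sub>between</sub> — the component reflecting
inter-individual variation — equals the mutual information between
individual identity and epiallele, divided by *b*. Ecotype contrasts use
Δ = *H*<sub>between</sub><sup>freshwater</sup> −
*H*<sub>between</sub><sup>marine</sup> per window, per sex.

Around the statistic the package provides the full analysis path:

- **IO** — epiread TSV (per-fragment CpG patterns), BED region sets with
  flank expansion, C→T genotypes from VCF, count matrices, BED6 TSS tables
  (`readEpireads`, `readRegions`, `readVcfCt`, `scanCpGSites`, ...);
- **coverage matching** — 1-kb bin counts and per-sex group-minimum
  downsampling with reproducible per-cell RNG streams
  (`countFragmentsPerBin`, `groupMinimumTargets`, `downsampleReads`);
- **entropy core** — window building, epiallele tallying, entropy and its
  decomposition as a `RangedSummarizedExperiment` subclass
  (`buildWindows`, `tallyEpialleles`, `entropyProfile`, `deltaBetween`);
- **region analysis** — central-CpG window assignment, exact/tie-corrected
  Wilcoxon comparisons, decile decomposition of the freshwater bias
  (`assignWindows`, `compareGroups`, `quantileBias`, `regionEntropyTable`);
- **C→T control** — the same entropy machinery on genetic C/T haplotypes,
  separating mutation-driven from epigenetic signal
  (`genotypeToPatterns`, `ctEntropyProfile`, `classifyEntropySource`);
- **integration** — median-of-ratios normalization, per-ecotype expression
  variability, promoter ΔH vs Δvariance association with top-quartile
  candidates, β-value and chromatin-accessibility comparisons;
- **synthetic cohorts** — a seeded Dirichlet–multinomial generator with
  ground-truth tables and exact expected-entropy oracles
  (`simulateCohort`, `injectCtMutations`, `simulateExpression`,
  `expectedDecomposition`).

## Worked example

Simulate a cohort of 7 + 7 males under the default study conditions
(coverage 32 per 1-kb bin, 10% of windows in divergence islands, 4-fold
between-individual effect in freshwater DI windows), then run the standard
pipeline — coverage matching, per-ecotype entropy profiles, Δ, and the
DI-versus-background comparison:

```r
library(epientropy)

cohort <- simulateCohort(simConfig(nWindows = 300L, nFemalePerEcotype = 0L,
                                   seed = 42L))
cohort
#> epiCohort: 300 windows (30 in DIs), 14 samples, 134884 reads, seed 42

res <- runEntropyPipeline(cohort, sex = "male", seed = 42L)
res$profileFresh
#> EntropyProfile: 1496 windows x 7 samples (b = 5)
#>   qc: 298 ok, 1198 low_coverage, 0 few_samples
#>   H_between: median 0.1629 (n = 298 defined)

res$test
#>   statistic      p_value n_a n_b   median_a    median_b               method
#> 1      6809 4.226738e-11  29 269 0.07540068 0.003861998 normal approximation
```

The 1496-window universe is every sliding 5-CpG window; the 298 windows
passing the 32-fragment floor are the simulator's read-bearing ones. The
Wilcoxon comparison shows the divergence-island windows (n = 29 with
defined Δ) carrying a strongly elevated freshwater between-individual
entropy (median Δ 0.075 vs 0.004 in the background, p ≈ 4e−11).

Decomposing the freshwater bias over genome-wide deciles of |Δ| shows it
concentrating in the top quantiles, Q10 alone holding half of all
freshwater-preferring DI windows:

```r
qb <- quantileBias(res$delta, res$assignment)
qb[9:10, c("quantile", "n_region", "frac_fw_bias", "share_fw_bias")]
#>    quantile n_region frac_fw_bias share_fw_bias
#> 9        Q9        6        0.833        0.1786
#> 10      Q10       14        1.000        0.5000
```

`frac_fw_bias` is the fraction of DI windows in the quantile with Δ > 0;
`share_fw_bias` is the quantile's share of all freshwater-preferring DI
windows (shares sum to 1).

## Documentation

The methods vignette (`vignettes/methylation-entropy.Rmd`) describes the
model and its assumptions, every tunable parameter with its default and
rationale, what the synthetic-cohort generator does and does not emulate,
numerical conventions, and known limitations.
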