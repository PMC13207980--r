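---
title: "Epiallele entropy: model, estimators and design choices"
author: "epientropy"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Epiallele entropy: model, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The statistic

Whole-genome bisulfite sequencing reads methylation per molecule: each
fragment reports the methylated (M) / unmethylated (U) state of every CpG it
covers. Within a sliding window of `b` consecutive CpGs (default `b = 5`,
step 1 CpG), each fragment that covers **all** `b` sites contributes one
*epiallele* — its length-`b` pattern over {M, U}. With `n_i` reads showing
the i-th of the `k` distinct observed patterns and `N = sum(n_i)` reads in
total, the methylation entropy of the window is

$$H \;=\; -\frac{1}{b}\sum_{i=1}^{k}\frac{n_i}{N}\log_2\frac{n_i}{N},$$

with the `0 log 0 = 0` convention. For `b = 5` the pattern space holds
`2^5 = 32` epialleles, so `H` ranges from 0 (a single pattern) to 1 (all 32
patterns equiprobable, given enough reads). A window must hold at least 32
pooled fragments before `H` is reported (`minReads = 32`) — the coverage at
which the 5-CpG pattern space can in principle be saturated; below that the
plug-in estimator is dominated by its negative bias.

## Decomposition into within- and between-individual components

Cohort questions require knowing *where* the diversity lives. For a group of
individuals (samples) `s` with per-sample entropies `H_s` and read counts
`N_s`, the package computes

- `H_pooled`: entropy of the summed counts,
- `H_within = sum_s (N_s / N) H_s`, the coverage-weighted mean, and
- `H_between = H_pooled − H_within`.

`H_between` equals the mutual information between sample identity and
epiallele, divided by `b`; concavity of entropy makes it non-negative, and
the identity `H_pooled = H_within + H_between` is exact. Two extreme
epialleles illustrate the split: if every individual is internally pure but
individuals disagree (one all-M, one all-U), the pooled entropy is entirely
between-individual; if every individual holds the same 50/50 mixture, it is
entirely within-individual. "Between-individual entropy" has no single
canonical estimator in the field; the mutual-information decomposition is
this package's formalization, chosen because it is the unique decomposition
that is exact, non-negative and additive. Other readings (e.g. entropy of
per-sample mean methylation) can differ numerically, so cross-tool
comparisons of absolute values should be made with care.

Samples contribute to the decomposition only with `perSampleMin = 8` or more
reads in the window — a per-sample entropy over two or three reads is
degenerate and would leak spurious "within" diversity; this floor is the
package's own addition. With fewer than two qualifying samples the between
component is undefined (`qc = "few_samples"`).

The ecotype contrast is `delta = H_between(freshwater) − H_between(marine)`,
computed per window, per sex. Sexes are processed independently end to end,
matching the sex-stratified coverage matching below.

## Coverage matching

The plug-in entropy estimator rises with read count, so depth differences
masquerade as diversity differences. Before any entropy is computed,
fragments are counted in fixed 1-kb bins (a fragment belongs to the bin of
its first CpG — single assignment keeps bin read sets disjoint), the
minimum count over all samples of the same sex becomes the bin's target,
and every sample is downsampled to that target by sampling without
replacement. Both ecotypes share a sex pool, so freshwater–marine
comparisons within a sex are made at exactly equal depth. Each (sample, bin)
cell draws from its own RNG stream (seed plus a hash of the cell key) with
candidates pre-sorted by read id, so the surviving read set is reproducible
and independent of read-file order. After downsampling, recounting
reproduces the target matrix exactly — this is asserted, not assumed.

## Region analyses

Windows are assigned to region sets (divergence islands, EcoPeaks,
promoters) by the position of their central CpG — site `ceiling(b/2)` — an
unambiguous single-assignment rule that treats core and flank
symmetrically. Core intervals and
±50 kb flanks are kept distinct so core-versus-flank contrasts remain
possible. Group contrasts use the two-sided Wilcoxon rank-sum test: exact
enumeration of all rank configurations (tie-aware) when the two groups hold
at most 20 values, the tie-corrected normal approximation with continuity
correction otherwise.

The freshwater bias is decomposed over quantiles of `|delta|` whose edges
are computed over **all** windows (genome-wide), not region-restricted,
with edge ties falling to the lower quantile. Two distinct readings of the
quantile statistic are both natural, so both are reported: the fraction of
region windows in each quantile with `delta > 0`, and each quantile's
share of all freshwater-preferring region windows (shares sum to one).
The unit is the window; aggregating to whole regions first would need an
aggregation rule (mean, max, count-weighted) that is itself a modeling
choice, so it is left to the caller.

## The C→T genetic control

Bisulfite sequencing cannot distinguish a genetic T at a CpG from an
unmethylated C. If freshwater fish simply carried more C→T polymorphism in
divergence islands, methylation entropy would rise there with no epigenetic
cause. The control applies the identical entropy machinery to genetic C/T
alleles at the same windows' CpG sites, with haplotypes playing the role of
reads: each diploid contributes two length-`b` C/T patterns (`N = 2` per
individual; coverage floors drop to `perSampleMin = 2`, `minReads = 4`
accordingly). The haplotype as the unit of observation is the package's
choice, made for symmetry with WGBS entropy being a per-molecule quantity;
phased genotypes are used as-is, unphased heterozygotes being assigned to
haplotypes uniformly at random under a fixed seed, with
all-reference/all-alternate extremes available as sensitivity bounds. A mutation-driven signal shows up
in both statistics (their per-window deltas correlate strongly); a genuinely
epigenetic signal leaves the C→T entropy flat. `classifyEntropySource()`
encodes that decision rule at Wilcoxon α = 0.05 on the region windows.

## The synthetic cohort generator

No public per-read data at cohort scale is needed to exercise the pipeline:
`simulateCohort()` draws cohorts from a Dirichlet–multinomial hierarchy,
per window of `b` CpGs:

1. base epiallele distribution ~ symmetric Dirichlet(`alphaWithin`) over the
   `2^b` patterns;
2. each individual's distribution ~ Dirichlet(base / `tau`), where
   `tau = tauBetween`, multiplied by `diEffect` for freshwater individuals
   in divergence-island windows;
3. fragment count per individual per 1-kb bin ~ NegBin(`coverageMean`,
   size = `coverageDispersion`);
4. fragment epialleles ~ Multinomial.

`alphaWithin` and `tauBetween` are separately tunable dials for the
within- and between-individual components. As `tauBetween → 0` every
individual collapses onto the base distribution and `H_between` vanishes
(up to estimator bias); as `alphaWithin → 0` with large `tauBetween`,
individuals become near-monomorphic but mutually different — `H_within ≈ 0`
with positive `H_between`.

Defaults are fixed once as the study conditions: 16 freshwater and 16
marine fish (7 males and 9 females per ecotype), mean coverage 32 fragments
per 1-kb bin (the pooled-window coverage threshold), `diFraction = 0.1`,
`diEffect = 4`, `b = 5`, CpGs 25 bp apart (a 5-CpG window spans ~100 bp,
the scale of a sequenced fragment). `alphaWithin = 0.2` gives sparse
within-individual distributions with pooled entropies spread over roughly
0.2–0.8, and `tauBetween = 0.1` puts the between component near 10–20% of
the pooled entropy outside divergence islands — the regime in which a
four-fold `diEffect` produces a clear but not trivial elevation. Negative
binomial size 16 keeps per-bin coverage overdispersed (sd ≈ 10 at mean 32)
without frequently starving the sex-minimum below the per-sample floor.
Reads are window-aligned by default; `straddlingReads = TRUE` adds
fragments spanning adjacent windows to exercise the full-coverage exclusion
rule.

The truth table records each window's DI flag, realized `tau`, and every
individual's epiallele distribution. Conditional on those distributions and
realized read counts, the exact expectation of the plug-in entropy is
computable in closed form — the expectation decomposes over pattern
categories into binomial marginals, and pooled category counts are sums of
independent binomials handled by convolution (`expectedPluginEntropy()`,
`expectedDecomposition()`). The test suite uses these to verify that
realized between-entropy matches its conditional expectation to within
Monte-Carlo error, which is a much sharper check than comparing moments of
the generator's output with itself.

`injectCtMutations()` adds the genetic counterfactual: in `"genetic"` mode
each CpG site is selected with probability `rate`; selected sites in DI
windows receive high freshwater heterozygosity (allele frequency ~
Beta(2, 2)) against low-frequency variation elsewhere and in marine fish
(~ Beta(0.5, 9.5)), each read is assigned to one of its individual's two
haplotypes, and calls on T-haplotypes flip to U — exactly the confounding
the control must detect. `"epigenetic"` mode emits no variants. The
frequency asymmetry is the generator's device for giving the genetic mode a
directional, DI-localized signature mirroring the epigenetic one; nothing
of the kind is claimed about real populations.

`simulateExpression()` produces gene-by-sample negative-binomial counts
around log-normal base means (sdlog = 1), scaled by log-normal library
sizes so that normalization is non-trivial, with dispersion inflated by
`varEffect` in freshwater samples for a chosen gene set — a variance excess
with no mean shift, four replicates per ecotype by default.

### What the generator does and does not emulate

It reproduces the statistical skeleton the analysis relies on: pooled group
structure, separately tunable within/between heterogeneity, DI-localized
freshwater elevation, coverage heterogeneity at 1-kb scale, C→T
confounding, and group-specific expression variance. It does **not**
emulate spatial autocorrelation of methylation along chromosomes, distance
decay of epiallele similarity, bisulfite conversion errors, mapping biases,
or linkage between neighboring windows. Passing tests therefore demonstrate
correctness and statistical behavior of the estimators under the model, not
that any biological claim holds in real data.

## Numerical and degenerate-input choices

- log base 2 throughout; normalization by `b` exactly as the statistic is
  defined; `0 log 0 = 0`.
- Entropy is `NA` (never NaN) below coverage floors, with a `qc` flag
  recording why.
- `H_between` is stored as the raw difference; concavity guarantees it is
  non-negative up to floating point (tests tolerate −1e−12) and it equals
  the directly computed mutual information to 1e−10.
- Wilcoxon: exact enumeration up to n = 20 (at most 184,756 configurations);
  midranks for ties; `p = 1` returned when a degenerate variance makes the
  normal approximation undefined (all values tied).
- Quantile edges use R's default type-7 quantiles; ties at an edge go to
  the lower quantile.
- Dirichlet draws that underflow to all-zero gammas (possible at extreme
  concentrations) fall back to a point mass on the largest concentration.
- Median-of-ratios size factors follow the standard definition (per-gene
  geometric-mean reference over all-nonzero genes). Because the reference
  includes every sample, scaling one sample's library by `c` scales factor
  *ratios* by `c` exactly while all normalized values pick up a common
  `c^(1/n)`; tests assert this form rather than a per-column invariance
  that the definition cannot provide.
- Expression variability is reported as the n−1 sample SD per ecotype
  (variance available as an option). For ranking genes by variance excess
  the package's tests use SD of `log2(normalized + 1)`: on the raw scale
  the SD of a gene is proportional to its mean, so high-expression genes
  dominate any quartile cut; the log scale makes the spread comparable
  across genes and is the scale on which the documented recovery behavior
  (inflated genes in the top quartile with probability > 0.9 at four
  replicates per ecotype) holds.

## Problem sizes used by the test suite

Module tests run on cohorts of 20–200 windows. The end-to-end property
checks use the scale the analysis is designed for: 7 + 7 males, 500
windows (10% DI), coverage 32, with 20 seeded replicates for the power arm
(`diEffect = 4`, Wilcoxon p < 0.001 expected in ≥ 95% of replicates) and 20
for the null arm (`diEffect = 1`, rejection rate at α = 0.05 within the
95% binomial interval); 10 + 10 replicates of 300-window cohorts for the
C→T control's classification accuracy; 100 replicates of 10,000 genes for
the null entropy–expression association (|r| < 0.03 in ≥ 95%); 10,000
random windows for the decomposition identity and 1,000 random tallies for
the entropy oracle. `scripts/acceptance.R` recomputes the same quantities
at moderately reduced replicate counts and records the problem size next
to every number it reports.

## Known limitations

- The between-component estimator carries the plug-in entropy bias; it is
  shared by both ecotypes at matched coverage (which is why coverage
  matching precedes everything), but absolute `H_between` values should not
  be compared across coverage regimes.
- The region-level analysis treats windows as exchangeable; neighboring
  sliding windows share reads and are strongly dependent, so genome-wide
  p-values are calibrated only under the simulator's independent-window
  model. On real data, block resampling or window thinning would be needed
  for honest genome-wide inference.
- The C→T control consumes genotypes; it cannot detect somatic or
  unsequenced variation, and with random phasing its haplotype patterns
  are exact only at phased sites.
- Promoters are fixed 1-kb upstream windows; no transcript-isoform
  awareness.
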