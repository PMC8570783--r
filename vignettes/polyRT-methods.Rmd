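---
title: "Replication timing from read depth in polyploid tissues: methods and design"
author: "polyRT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Replication timing from read depth in polyploid tissues: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The signal and the model

In a proliferating tissue, a fraction *s* of cells is in S phase at the
moment of sampling. A locus that replicates early in S phase is present at
two copies in most S-phase cells, a late locus at one copy in most of them;
outside S phase every locus has one (relative) copy. Averaged over the
population, the expected relative copy number of locus *i* is

    c(i) = u(i) * [ (1 - s) + s * (1 + r(i)) ] * b(gc(i))

where `r(i)` is the fraction of S-phase cells that have already replicated
the locus, `u(i)` is the copy retention of underreplicated (UR) regions
(1 elsewhere, well below 1 inside UR regions of polytene tissues), and
`b(gc)` is the multiplicative GC-dependent coverage bias of library
preparation and sequencing. With cells spread uniformly over S-phase time
and a locus replicating when a cell's S-phase clock passes `1 - rt(i)`,
`E[r(i)] = rt(i)`: read depth is a direct, if faint, readout of replication
timing (RT). For `s = 0.15` the entire RT dynamic range spans 15% of depth,
while underreplication at retention `u = 0.3` removes 70% — the central
design problem of the pipeline is recovering the faint RT gradient without
letting the enormous UR signal leak into it.

The pipeline mirrors that decomposition:

1. **Windowing** — depth is tallied in windows containing a fixed number
   (1000) of *uniquely alignable* base pairs, so poorly mappable regions get
   wider windows rather than depressed counts.
2. **GC correction** — a robust local-regression fit of relative copy
   against window GC, with known UR/heterochromatin held out, divides out
   `b(gc)`.
3. **eUR discovery** — penalized change-point segmentation finds euchromatic
   regions of persistently low copy (≥ 1 SD below the mean, ≥ 50 kb,
   internal gaps shorter than 10 windows).
4. **Outlier filtering** — windows far from their local segment mean
   (2 SD on arms, 3 SD inside eUR) are masked, never altered.
5. **Dual normalization** — the mean and SD of the fully replicated arm
   windows anchor an affine transform applied to *all* windows; arms become
   exactly mean 0 / SD 1 ("rawRT") while UR windows keep their depressed
   values instead of compressing the arm scale.
6. **Smoothing** — a cubic smoothing spline per contiguity zone, then
   per-chromosome standardization, gives the RT profile; genome-wide ranked
   quartiles (Q1 earliest … Q4 latest) give a copy-number-free relative RT
   classification.
7. **Comparison** — replicate correlation and autocorrelation for QC, and
   one-way ANOVA on 50-kb windows with Bonferroni control for between-sample
   RT variants (adjacent significant windows merged; regions > 200 kb
   called variant).

# Parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `targetAlignable` | 1000 | bp | alignable content per window |
| `readLength` | 100 | bp | k-mer length for the alignability mask |
| `eurR2` | 0.04 | variance | segmentation noise assumption for eUR calling |
| `eurSD` | 1 | series SD | low-segment threshold |
| `eurMinLen` | 50 000 | bp | minimum eUR genomic span |
| `eurMaxGap` | 10 000 | bp (≙ 10 windows) | largest above-cutoff gap chained across |
| `outlierR2` | 0.06 | variance | segmentation noise assumption for outlier masking |
| `outlierSDArm` / `outlierSDEUR` | 2 / 3 | residual SD | outlier thresholds |
| `splineP` | 1e-15 | — | smoothing parameter, `p·Σ(y−f)² + (1−p)·∫f″²` with x in bp |
| `minZone` | 21 | windows | smallest smoothed zone (zones of > 20 windows) |
| `smoothMaxGap` | 5 000 | bp | largest missing span smoothed across |
| `variantWindow` | 50 000 | bp | ANOVA bin |
| `alpha` | 0.01 | — | Bonferroni-adjusted significance level (strict `<`) |
| `minRegion` | 200 000 | bp | variant regions must exceed this span (strict `>`) |
| `acfLags` | 1000 | lags | autocorrelation depth |
| `overlapFraction` | 0.5 | — | interval-assignment fraction (features and window labels) |
| `mergeDistance` | 11 | bp | region-merge distance for window-level merging |

# Numerical and design choices

**Change-point segmentation.** The piecewise-constant fits behind GC
masking, eUR discovery and outlier filtering use penalized least squares
solved exactly by optimal partitioning (PELT, compiled): minimize the sum
of within-segment squared errors plus `beta` per segment. The noise
parameter `r2` is interpreted as the assumed noise *variance on the scale
of the input series* — in the pipeline every series is first divided by its
mean, so `r2 = 0.04` means "treat fluctuations of SD 0.2 relative copies as
noise". The penalty is `beta = r2 * c(n)` with `c(n) = 5.9 + 0.87·log(n)`,
calibrated once by simulation so that pure Gaussian noise of variance `r2`
yields a single segment in at least 95% of runs for series lengths 50 to
20 000, then frozen. Larger `r2` therefore monotonically reduces
sensitivity. Missing values are bridged (they join the enclosing segment
and contribute no error); every segment must contain at least `minSeg = 5`
non-missing windows, which forbids chasing single-window spikes. Pruning is
disabled for series up to 512 points, where the recursion is exact by
construction; for long series the standard safe pruning is used. Rescaling
a series by `a` together with `r2` by `a²` leaves breakpoints unchanged.

**GC-bias fit.** The curve is a robust (`family = "symmetric"`) loess of
relative copy on window GC, degree 2, span 0.4, fit on at most 5000
deterministically thinned windows; predictions are clamped to the fitted GC
range and floored at 10% of the median to keep the division stable. Two
classes of windows are held out: the `exclude` regions the caller knows
about (annotated pericentric heterochromatin, any prior UR list), and
segmentation-detected low-copy segments *with a sharp genomic edge*. The
edge test (value just outside ≥ 1.5× value just inside, over 10-window
flanks) separates the two things a low segment can be: a copy dip switches
retention discontinuously at its border while GC varies smoothly, so it
jumps; a genuine deep GC-bias valley follows the GC track continuously, so
it does not — and must stay in the fit, because removing it would leave the
curve's tail unconstrained. This keeps the correction honest in both
directions: UR dips are not erased into the bias curve even when they sit
on a GC-extreme domain, and strong bias valleys are not mistaken for UR.

**Smoothing.** `splineP` follows the classical
`p·Σ(y−f)² + (1−p)·∫f″(x)²dx` parameterization with `x` the window genomic
midpoint in base pairs; internally this is handed to the standard
smoothing-spline solver as `lambda = ((1−p)/p)/range(x)³` on the
unit-scaled abscissa, which is the same criterion. At `p = 1e-15` and 1-kb
windows the equivalent kernel bandwidth is a few tens of kb — strong enough
to suppress Poisson noise at depth 100, gentle enough to preserve RT
domains of a few hundred kb. Zones are runs of non-missing windows split
wherever the genomic gap exceeds `smoothMaxGap` *or the region label
changes*: the copy-number step at an eUR/PH border is not replication
signal, and smoothing across it would bleed a multi-SD dip into its
neighbours. Zones with 20 or fewer windows are left missing. The smoothed
profile is standardized to mean 0 / SD 1 per chromosome over all
non-missing windows.

**Quartiles.** Assignment is by global rank (ties broken deterministically
in series order), which guarantees occupancies of n/4 ± 1; the reported
cutoffs are the 75th/50th/25th percentiles with R's default interpolation,
missing values removed. Q1 holds the highest (earliest) values.

**Variant calling.** Observations in each 50-kb bin are the constituent
1-kb rawRT values pooled across replicates (a replicate-means alternative
is available via `observations = "replicate_means"`). The F test is the
classical equal-variance one-way ANOVA; Bonferroni adjustment is
`min(1, p·m)` over all tested bins, the significance threshold a strict
`<`. Adjacent (book-ended) significant bins merge; merged regions must
strictly exceed 200 kb. Pooled 1-kb observations are spatially
autocorrelated, so nominal type-I error is not guaranteed analytically —
the null behaviour is measured, not assumed: the test suite runs 100 seeded
identical-truth comparisons and requires at least 95 to produce zero
variant regions.

**Open interpretation choices.** (i) Reads are assigned to windows by
their leftmost aligned reference coordinate, not the fragment midpoint.
(ii) The eUR gap rule counts windows of the grid (10 windows ≙ 10 kb of
alignable content), not raw genomic bp. (iii) The rawRT arm anchor is
computed genome-wide, with a per-chromosome switch
(`perChromosomeAnchor`); the smoothed track is standardized per
chromosome. (iv) The 50%-overlap convention is applied to the *feature*
span for feature–quartile assignment (with a switch to the window side)
and to the window span for arm/eUR/PH labelling, with PH winning ties.
(v) The last, short window of each chromosome is kept but flagged and
excluded from all normalization statistics.

# The synthetic-data generator

`simulateTruth()` / `simulateDepth()` emulate the statistical structure the
pipeline assumes, with every latent quantity retained as ground truth:

* a GC landscape (smoothed Gaussian field, mean ≈ 0.42, SD 0.06, 200-kb
  scale) and a block-structured uniquely-alignable mask (100-bp blocks kept
  with probability 0.85 on arms);
* a latent RT landscape: a Gaussian field at 500-kb domain scale,
  rank-uniformized per chromosome (a Gaussian copula). The smooth field
  supplies peaks, troughs and strong autocorrelation; the uniform marginal
  matches the broad spread of replication times across S phase seen in
  empirical profiles — a raw range-rescaled field would instead pile most
  of the genome into a narrow mid-range band;
* underreplicated regions (three per chromosome, 60–200 kb, copy retention
  `u = 0.3` — the retention value is a plausible choice, not an empirical
  estimate) and one pericentric-heterochromatin block per chromosome end
  (8% of the chromosome, retention 0.6, alignability halved), with latent
  RT pulled late inside both, since UR regions are late replicating;
* S-phase fraction 0.15 (the method assumes roughly ≥ 0.10), expected depth
  100 reads per window, log-quadratic GC bias `exp(-8·(gc - 0.40)²)`
  (the bias shape is a package choice; strictly positive, unimodal,
  peaked near typical GC), Poisson counts with an optional
  negative-binomial switch for overdispersion stress tests.

Gaussian smoothing uses a 5-sigma kernel support; truncating nearer leaves
kernel-edge discontinuities that riddle the field with micro-extrema.
Field edges are renormalized by the in-range kernel mass rather than padded
with replicated values, which would pin chromosome ends at spurious
extremes.

What the generator does **not** emulate: mappability structure at real
repeat families, fragment-length and strand effects, copy-number
polymorphisms, chimeric/duplicate reads (duplicates are assumed
pre-marked), biological replicate variability beyond counting noise
(replicates share the latent truth and differ only in Poisson draws), or
cell-cycle structure beyond the uniform-S model. Passing tests therefore
demonstrate correctness of the inference machinery under the stated model,
not robustness to every artefact of real libraries.

# Validation problem sizes

The test suite validates the pipeline at the default study conditions —
2 chromosomes × 20 Mb, depth 100, S fraction 0.15 — for profile recovery,
replicate agreement, quartile arithmetic and autocorrelation, and eUR
recovery over 20 seeds. The variant-calling null and power Monte Carlo
(100 seeded runs each) uses 1 chromosome × 4 Mb with 8 replicates per
group and a +0.5 rawRT-SD shift over an aligned 400-kb region; the UR
geometry is fixed clear of the shift window, since a copy dip inside it
would confound the power measurement with copy-number variance. With pooled
1-kb observations the per-bin noncentrality is `0.5·√(n/2)`, and 8
replicates (n ≈ 340 per group per bin) put per-bin power near 0.99 at the
Bonferroni threshold, so the detection check exercises the caller rather
than the sample-size arithmetic; two replicates per group — the bench
default for sequencing — cannot reach 95% detection of a 0.5-SD shift at
any genome size under Bonferroni control, which is worth remembering when
interpreting real-data variant fractions. Module tests run on 1 × 4 Mb
fixtures. `scripts/acceptance.R` recomputes the headline quantities at the
default scale from a fresh seed.

# Known limitations

* UR is never called inside pericentric heterochromatin; PH is an
  annotation input and is masked, matching the short-read mappability
  reality.
* A UR dip whose copy retention declines gradually at its borders (no edge
  jump) *and* which coincides with the genome's most extreme GC domain is
  unidentifiable from depth alone; the GC fit will absorb part of it.
* The ANOVA variant caller inherits the autocorrelation of 1-kb windows;
  its measured null behaviour is clean at the tested conditions, but the
  nominal p-values should not be read as calibrated probabilities.
* Absolute RT (hours into S phase) is out of scope; profiles are relative,
  and within UR regions only the quartile classification — not the rawRT
  level — is interpretable, because copy loss and late replication are
  confounded there.
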