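---
title: "The TUF suppression model: GC/CpG waves, nick density and amplification"
author: "tufscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The TUF suppression model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The phenomenon and the model

Short genomic elements of extreme GC content (roughly a kilobase at
70-85% G+C) can remain double-stranded under denaturation conditions
that melt the rest of the genome. An element that stays annealed tethers
its two flanking single strands next to each other, so when conditions
return to non-denaturing the flanks re-anneal almost instantly
(zero-order kinetics) instead of staying available to primers and
probes. The whole domain around the element — which we call a
Thermodynamically Ultra-Fastened (TUF) region — therefore amplifies and
hybridizes poorly.

The crucial sample-level twist is that the *reach* of this effect
depends on DNA integrity. A single-strand nick or a break between a
locus and the anchoring element physically disconnects the two, and the
locus behaves normally. If nicks occur as a Poisson process with rate
`rho` per bp (the sample's nick density), the probability that a locus
at distance `d` from the element is still connected is `exp(-rho * d)`.
tufscan's central quantitative assumption is that the expected signal
loss is proportional to that connection probability:

```
suppression(d) = A * exp(-rho * d),   d <= dMax
```

with `A` the full-suppression amplitude (in log-R-ratio units at the
probe level, or as a fraction of the PCR product for the PRT readout).
The exponential form is not fitted ad hoc: it *is* the Poisson
no-nick probability, with `A` absorbing how much signal a fully
tethered locus loses. The counter-intuitive consequence — intact,
freshly prepared DNA (low `rho`) suffers most, while old or sheared DNA
escapes — is reproduced by the generator and reversed by the in-silico
sonication and digestion treatments.

## The wave regression

On SNP arrays, the log R ratio (LRR) additionally carries smooth
sample-specific "waves" correlated with regional GC content at many
scales. tufscan models one sample's LRR as

```
LRR_i = b0 + sum_k gamma_k 1[stratum(i) = k]
      + sum_{m, w, p} beta[m,w,p] * (x[m,w,i] - mean_w)^p
      - A * exp(-rho * d_i)            (mechanistic suppression)
      + eps_i
```

where `x[m,w,i]` is the GC or CpG fraction of the window of size `w`
centered on probe `i`, `p` runs over polynomial degrees (default 2),
and the `gamma_k` are within-chip rescaling offsets for probe strips.
The regression (`fitWaveModel()`) estimates the intercept, stratum and
wave terms per sample by OLS after quantile normalization across
samples; corrected values are the residuals re-centered to the sample
mean (`correctLrr()`). A sample's wave extremity is summarized by the
largest-|Z| degree-1 GC term (`classifyExtremeSamples()`, threshold
|Z| = 30); degree-1 terms are used for the selector because their sign
carries the wave direction, while degree-2 terms are shared curvature.

Covariates are centered before polynomial expansion to limit
collinearity between degrees. Exactly collinear (aliased) terms are
dropped with a warning and flagged in the model rather than silently
zeroed. A hard error is raised only when there are fewer probes than
model terms plus one; below ten probes per term a warning marks the fit
as potentially unstable (small exact-recovery examples remain
expressible).

### Window sizes

The default content windows for `buildContentMatrix()` are 50, 100,
500, 1 k, 10 k, 50 k, 100 k, 250 k and 1 M bp. The exact term set is a
free choice of the analysis — published work in this area is not
consistent about whether eight or nine scales enter the model, and
some association tables include a 5 kb window absent from the
methods-level lists — so tufscan treats the window list as data-driven
configuration and never hard-codes a canonical set. The simulation
configs use {50, 100, 500, 1 k, 5 k}: on a 1 Mb synthetic contig,
windows of 50 kb and above would span an appreciable fraction of the
genome and be nearly constant across probes.

## What the generator emulates — and what it does not

`simulateGenome()` / `simulateCohort()` produce, with full ground
truth: an i.i.d.-base contig (default 1 Mb at 40% GC) carrying planted
extreme-GC elements (three of 1.5 kb at 80% GC); probes every 200 bp
(5000 probes); and a 54-sample cohort split 24 positive-wave /
19 negative-wave / 11 null, mirroring the validation cohort size used
in the experimental work this model descends from. Per-sample LRR
follows the model above with homoscedastic Gaussian noise (SD 0.05),
small per-strip offsets (SD 0.01 across 2 strata) and per-sample
baselines (SD 0.02).

Class semantics are a design decision the data sources leave open: the
*negative* class is the TUF-affected one (intact DNA, `rho = 2e-4`/bp,
`A = 0.8`), because mechanistic suppression lowers intensity near
high-GC elements and therefore drives the GC coefficient negative; the
*positive* class carries a concentration-style positive wave with no
suppression (`A = 0`); nulls carry neither. This makes the per-sample
Z at the planted window monotonically related to PRT performance,
which is what the Table-2-style association report measures. The
planted degree-1 amplitude (1.6 LRR per unit centered GC fraction,
with a degree-2 term of 12) was calibrated once, before the acceptance
suite was written, so that an extreme sample's planted-term Z is ~60
at the reference size — comfortably past the ±30 classification
threshold, as the extremes it emulates were.

The PRT readout is `rEq * (1 - min(A,1) * exp(-rho * d_prt) * linkage)`
plus readout noise, clipped at zero, with `rEq = 1.43` the
equal-efficiency test:reference ratio for the reference assay (an input
constant, not derived) and `d_prt = 1000` bp the assumed distance from
the test amplicon to its anchoring element. `applyFragmentation()`
updates ground truth for the two fragmentation treatments: digestion
breaks at restriction sites (deterministic), sonication at Poisson
breakpoints with rate `1/meanFragment`; a probe whose link is severed
gets distance `Inf`, and the PRT-side linkage factor is multiplied by
the no-break probability `exp(-d_prt/meanFragment)`.

The generator deliberately does **not** emulate: thermodynamic melting
(no nearest-neighbor model), WGA branching kinetics, heteroscedastic or
autocorrelated array noise, B-allele frequencies, genotype-cluster
re-estimation, repeats or realistic base composition structure
(CpG-island statistics arise only implicitly through the planted
elements). Passing tests therefore demonstrate that the estimators
recover the model's own mechanism at realistic sizes and noise — not
that real arrays are this well-behaved.

## Element discovery and distances

`findGcElements()` slides windows of width `minLength` (default 500 bp)
every `step` (50 bp), keeps windows with GC ≥ `minGc` (0.70), merges
overlapping/near-adjacent qualifying windows (gaps < one step), then
refines boundaries by trimming terminal non-GC bases and extending over
adjacent G/C runs. The thresholds are calibrated so that the archetypal
~1.1 kb, 73%-GC element sitting on a 40% background is recovered with
boundaries within one step; the detection procedure itself is this
package's own design — the phenomenon, not an algorithm, is what is
described in the literature. Boundary overshoot grows with element GC
(a window straddling the edge of an 80% element still clears the
threshold ~2 steps out), which is immaterial for distance annotation at
kilobase scales.

Distances (`annotateSusceptibility()`) are coordinate differences from
the probe position to the proximal element boundary (0 inside an
element), `Inf` beyond `dMax`. `dMax` defaults to 50 kb — generously
beyond the kilobase-scale decay lengths of interest — and is tightened
to 10 kb when *estimating* the decay, so the equal-count distance bins
(default 10) concentrate where the exponential actually bends.
`estimateNickRate()` fits `A * exp(-rho * d)` to bin means by
Levenberg-Marquardt least squares, initialized from a log-linear fit
on positive bins; an all-zero suppression profile short-circuits to
`A = 0` with `rho` flagged undefined.

## Copy-number calls and weak regions

The weak-signal display is a one-threshold classifier: LRR at or below
-0.3 reads as apparent copy number 1. The threshold is a free parameter
(no published LRR value corresponds to the weak row of such plots);
-0.3 sits between the suppressed and unsuppressed modes under the
default amplitude `A = 0.8`. `detectWeakRegions()` then reports maximal
runs of ≥ 5 consecutive probes where ≥ 50% of affected samples call
CN 1 — deliberately not an HMM: the target pattern is concordant,
contiguous signal loss, not genotype-aware segmentation.

## Association report

`table2Report()` correlates each sample's Z at a given (metric, window)
term with its mean PRT ratio, reporting Pearson and Spearman p-values
in a window-by-metric layout (largest window first). Spearman p-values
use exact enumeration of all `n!` rank permutations for `n ≤ 8` and the
t-approximation above; a Monte-Carlo permutation test is available.
Raw p-values are reported without multiple-testing correction, matching
how such tables are conventionally presented; callers can adjust
afterwards. On the full default cohort (planted waves *and* elements),
the suppressed class also drags element-scale windows (1-5 kb and
their CpG analogues) into significance — mechanistically real leakage,
since suppression is spatially anchored at high-GC elements; the
wave-only cohort isolates the planted 100 bp signal.

## Reproducibility and problem sizes

Every stochastic step takes an explicit seed; `runPipeline()` derives
stage seeds as `seed + 101 * stage_index` so stages can be rerun in
isolation, and identical config + seed give byte-identical outputs.
The test and acceptance workloads use the reference conditions
directly: 100 replicates for wave recovery and coefficient coverage
(5000 probes, noise SD 0.05), 100 replicates for nick-rate recovery
(`A = 0.5`, `rho = 5e-4`/bp, noise SD 0.1, eight elements), 20 cohort
replicates of the 54-sample association plus 2000 null replicates for
type-I calibration, all chosen to keep the complete run in the
low minutes on one CPU while leaving the Monte-Carlo margins far from
the pass boundaries.

## Known limitations

* Suppression and waves are additive on the LRR scale; saturation at
  very strong suppression is not modeled (PRT ratios are clipped at 0,
  LRR is not).
* Restriction matching is forward-strand only; the shipped enzymes are
  palindromic so no sites are missed, but non-palindromic enzymes
  would need both strands.
* `advise_digest` considers the nearest element only and assumes the
  reference locus is unaffected by the treatments, as observed
  experimentally.
* Quantile normalization forces identical marginal distributions; in
  cohorts where many samples share strong suppression it slightly
  redistributes the suppressed tail across samples (visible as
  attenuated negative-class Z at small cohort/probe counts).
* Circular molecules and multi-chromosome separation logic are out of
  scope; separation is evaluated on linear coordinates.
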