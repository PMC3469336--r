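# tufscan

Detection and correction of **Thermodynamically Ultra-Fastened (TUF)**
genome regions in SNP-array intensity data.

Some short genomic elements of extreme GC content (~1 kb at 70–85% G+C)
fail to denature under standard melting conditions. An element that
stays duplexed anchors its melted flanks next to each other, so they
re-anneal the moment conditions relax — and everything around the
element amplifies and hybridizes poorly. How far the damage reaches in
a *given DNA sample* depends on its nick density ρ (nicks/bp): a nick
between a locus and the element disconnects them, so the expected
signal loss at distance *d* is

```
suppression(d) = A · exp(−ρ·d)
```

the Poisson probability that no nick interrupts the link, scaled by the
full-suppression amplitude *A*. Intact, freshly prepared DNA (small ρ)
is hit hardest; sheared or digested DNA escapes. On arrays this rides
on top of smooth, sample-specific **GC/CpG waves** in the log R ratio
(LRR), which tufscan removes with a per-sample multi-window polynomial
regression:

```
LRR_i = b0 + Σ_k γ_k·1[stratum(i)=k]
      + Σ_{m,w,p} β[m,w,p]·(x[m,w,i] − x̄_w)^p  −  A·exp(−ρ·d_i)  +  ε_i
```

where `x[m,w,i]` is the GC or CpG fraction of a window of size *w*
centered on probe *i* (w from 50 bp to 1 Mb), *p* runs over polynomial
degrees, and γ are within-chip rescaling offsets. Per-term Z scores
(coefficient/SE) flag extreme-wave samples (|Z| > 30), and the
association between per-sample Z and paralogue-ratio-test (PRT)
performance is reported in a window-by-metric layout.

The package is for people who work with Illumina-style intensity data
or PCR assays that keep misbehaving in the same genomic neighborhoods:
it quantifies the wave, scores sample extremity, finds the anchoring
elements and weak-signal regions, estimates each sample's ρ from the
suppression-versus-distance decay, and — the practical payoff — tells
you which restriction digest or sonication regime will physically
separate your amplicon from its anchoring element
(`adviseDigest()`, `rankTreatments()`). A mechanistic synthetic-cohort
generator with full ground truth (`simulateGenome()`,
`simulateCohort()`, `simulatePrtReadout()`) backs every estimator with
recovery tests.

## Worked example

```r
library(tufscan)

cfg <- simulationConfig(seed = 1)       # 1 Mb genome, 3 TUF elements,
sim <- simulateGenome(cfg)              # 5000 probes, 54 samples
content <- buildContentMatrix(sim$genome, sim$manifest, cfg@windowSizes)
cs  <- simulateCohort(cfg, sim, content)
models <- fitCohortModels(quantileNormalize(cs$cohort), content)

models[["S25"]]                         # a TUF-affected sample
#> CorrectionModel for sample S25
#>   22 terms (degree 2; windows: 50, 100, 500, 1000, 5000)
#>   variance pre = 0.01768, post = 0.005652 (68.0% explained)
#>   max |Z| wave term: GC_w100_p2 (Z = 42.4)

head(varianceReport(models), 3)
#>   sample variance_pre variance_post variance_ratio prop_explained
#> 1    S01       0.0177       0.00355          0.201          0.799
#> 2    S02       0.0177       0.00356          0.202          0.798
#> 3    S03       0.0177       0.00369          0.209          0.791

table(classifyExtremeSamples(models)$label)
#> negative     null positive
#>       19       11       24
```

The wave regression explains ~80% of LRR variance for wave-planted
samples (their `variance_ratio` drops to ~0.2), and classification by
the largest-|Z| degree-1 GC term recovers the planted 24/19/11
positive/negative/null split exactly. Associating each sample's Z at
the 100 bp GC window with its simulated PRT ratio:

```r
ro <- simulatePrtReadout(cs$truth, seed = 2)
table2Report(models, ro)
#>   window gc_correlation_p gc_spearman_p cpg_correlation_p cpg_spearman_p
#> 1   5000         2.32e-11      6.22e-09          1.38e-18       3.19e-07
#> 2   1000         9.66e-03      3.83e-02          5.95e-01       7.80e-01
#> 3    500         5.74e-02      2.75e-02          1.43e-03       5.83e-03
#> 4    100         2.07e-18      1.72e-08          7.03e-02       1.99e-01
#> 5     50         9.38e-02      1.42e-01          5.96e-01       7.81e-01
```

The planted 100 bp GC window is overwhelmingly significant
(p ≈ 2×10⁻¹⁸); the element-scale windows (5 kb, and CpG at 5 kb) also
light up because the mechanistic suppression is spatially anchored at
high-GC elements — real leakage, not noise. The whole chain, from
genome simulation to the fragmentation advice table, also runs as one
reproducible pipeline:

```r
runPipeline(cfg, "tufscan_out")   # TSV/BED/FASTA outputs + run manifest
```

A thin command-line dispatcher over the same functions ships at
`inst/scripts/tufscan.R`
(`Rscript tufscan.R run --config cfg.yaml --outdir out`).

## Layout

* `R/` — S4 classes (`SimulationConfig`, `CohortTruth`, `TufCohort`,
  `WindowContentMatrix`, `CorrectionModel`, `RestrictionEnzyme`) and
  the six analysis stages: genome content, simulation, wave
  correction, TUF detection, PRT association, fragmentation advice,
  plus the pipeline orchestrator.
* `inst/extdata/` — published PRT assay coordinates and a
  palindromic restriction-enzyme table.
* `vignettes/tuf-model.Rmd` — the model, its assumptions, parameter
  choices and limitations.
* `tests/testthat/` — unit, property and acceptance suites with
  independent brute-force oracles.
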