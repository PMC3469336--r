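# Mechanistic generator: genome architecture, LRR generative model,
# fragmentation, PRT readout, and the direction of the mechanism.

test_that("background GC is binomial around the configured rate", {
  cfg <- simulationConfig(genomeLength = 100000L, nElements = 0L,
                          seed = 5L)
  sim <- simulateGenome(cfg)
  gc <- windowContent(sim$genome[["chr1"]], 50000, 99999, "GC")
  se <- sqrt(0.4 * 0.6 / 100000)
  expect_lt(abs(gc - 0.4), 3 * se)
})

test_that("planted elements are recovered by element discovery", {
  cfg <- simulationConfig(seed = 8L) # 3 elements, 1 Mb
  sim <- simulateGenome(cfg)
  expect_length(sim$elements, 3)
  det <- findGcElements(sim$genome[["chr1"]])
  expect_length(det, 3)
  ov <- GenomicRanges::countOverlaps(sim$elements, det)
  expect_true(all(ov == 1))
})

test_that("the generator is deterministic under a fixed seed", {
  cfg <- simulationConfig(genomeLength = 50000L, nElements = 1L,
                          probeSpacing = 500L, nSamples = 4L,
    classMix = c(positive = 1L, negative = 2L, null = 1L),
    windowSizes = c(50L, 100L), seed = 17L)
  a <- simulateGenome(cfg); b <- simulateGenome(cfg)
  expect_identical(as.character(a$genome), as.character(b$genome))
  ca <- simulateCohort(cfg, a); cb <- simulateCohort(cfg, b)
  expect_identical(lrrMatrix(ca$cohort), lrrMatrix(cb$cohort))
  c2 <- simulateGenome(cfg, seed = 18L)
  expect_false(identical(as.character(a$genome),
                         as.character(c2$genome)))
})

test_that("the null generative model is a constant matrix", {
  cfg <- simulationConfig(genomeLength = 20000L, nElements = 0L,
    probeSpacing = 200L, nSamples = 2L,
    classMix = c(positive = 0L, negative = 0L, null = 2L),
    windowSizes = c(50L, 100L), strataSd = 0, baselineSd = 0,
    noiseSd = 0, seed = 2L)
  cs <- simulateCohort(cfg, simulateGenome(cfg))
  expect_true(all(lrrMatrix(cs$cohort) == 0))
})

test_that("suppression at distance zero equals the full amplitude", {
  cfg <- simulationConfig(genomeLength = 20000L, nElements = 1L,
    elementLength = 1000L, probeSpacing = 100L, nSamples = 1L,
    classMix = c(positive = 0L, negative = 1L, null = 0L),
    windowSizes = c(50L,  100L),
    waveCoefs = defaultWaveCoefs()[0, ],
    strataSd = 0, baselineSd = 0, noiseSd = 0, seed = 4L)
  cs <- simulateCohort(cfg, simulateGenome(cfg))
  inside <- which(cs$truth@probes$distance == 0)
  expect_gt(length(inside), 0)
  A <- cfg@suppressionA[["negative"]]
  expect_equal(unname(lrrMatrix(cs$cohort)[inside, 1]),
               rep(-A, length(inside)))
})

test_that("noise variance matches the configured sigma", {
  cfg <- simulationConfig(nElements = 0L, nSamples = 1L,
    classMix = c(positive = 0L, negative = 0L, null = 1L),
    strataSd = 0, baselineSd = 0, noiseSd = 0.1, seed = 6L)
  cs <- simulateCohort(cfg, simulateGenome(cfg))
  v <- var(as.numeric(lrrMatrix(cs$cohort)))
  expect_lt(abs(v - 0.01) / 0.01, 0.05)
})

test_that("fragmentation separates probes from elements as expected", {
  cfg <- simulationConfig(genomeLength = 100000L, nElements = 1L,
    probeSpacing = 200L, nSamples = 1L,
    classMix = c(positive = 0L, negative = 1L, null = 0L),
    windowSizes = c(50L, 100L), seed = 12L)
  sim <- simulateGenome(cfg)
  cs <- simulateCohort(cfg, sim)
  truth <- cs$truth
  nFinite <- sum(is.finite(truth@probes$distance))
  expect_gt(nFinite, 10)
  # an enzyme with no sites changes nothing
  none <- restrictionEnzyme("none", "GCGCGCGCGCGC", 1)
  t0 <- applyFragmentation(truth, "digestion", enzyme = none,
                           sequence = sim$genome)
  expect_equal(t0@probes$distance, truth@probes$distance)
  # digestion is deterministic
  taq <- restrictionEnzyme("TaqI", "TCGA", 1)
  t1 <- applyFragmentation(truth, "digestion", enzyme = taq,
                           sequence = sim$genome)
  t2 <- applyFragmentation(truth, "digestion", enzyme = taq,
                           sequence = sim$genome)
  expect_identical(t1@probes$distance, t2@probes$distance)
  # fine sonication severs essentially every probe-element link
  t3 <- applyFragmentation(truth, "sonication", meanFragment = 20,
                           seed = 1L)
  away <- truth@probes$distance > 0 & is.finite(truth@probes$distance)
  expect_true(all(!is.finite(t3@probes$distance[away])))
})

test_that("sonication linkage survival follows the Poisson gap law", {
  cfg <- simulationConfig(genomeLength = 200000L, nElements = 1L,
    probeSpacing = 100L, nSamples = 1L,
    classMix = c(positive = 0L, negative = 1L, null = 0L),
    windowSizes = c(50L, 100L), dMax = 20000, seed = 14L)
  sim <- simulateGenome(cfg)
  truth <- simulateCohort(cfg, sim)$truth
  L <- 5000
  d <- truth@probes$distance
  band <- which(is.finite(d) & d > 2000 & d < 8000)
  kept <- replicate(40, {
    t1 <- applyFragmentation(truth, "sonication", meanFragment = L)
    mean(is.finite(t1@probes$distance[band]))
  })
  expected <- mean(exp(-d[band] / L))
  expect_lt(abs(mean(kept) - expected), 0.05)
})

test_that("PRT readout follows the suppression closed form", {
  cfg <- simulationConfig(genomeLength = 20000L, nElements = 0L,
    probeSpacing = 500L, nSamples = 3L,
    classMix = c(positive = 1L, negative = 1L, null = 1L),
    windowSizes = c(50L, 100L),
    nickRate = c(positive = 1e-3, negative = 1e-3, null = 1e-3),
    suppressionA = c(positive = 0, negative = 0.8, null = 0),
    prtNoiseSd = 0, prtDistance = 1000, seed = 19L)
  truth <- simulateCohort(cfg, simulateGenome(cfg))$truth
  ro <- simulatePrtReadout(truth)
  neg <- ro$ratio[truth@samples$class == "negative"]
  expect_equal(neg, 1.43 * (1 - 0.8 * exp(-1)))
  expect_equal(ro$ratio[truth@samples$class != "negative"],
               rep(1.43, 2))
  # physically separated: back to the equal-efficiency line
  expect_equal(simulatePrtReadout(truth, dPrt = Inf)$ratio, rep(1.43, 3))
  truth@prtLinkage <- 0
  expect_equal(simulatePrtReadout(truth)$ratio, rep(1.43, 3))
})

test_that("repairing nicks (lower rho) strictly worsens PRT ratios", {
  # ligase analogue: fewer nicks -> longer intact TUF link -> lower ratio
  rEq <- 1.43
  ratioAt <- function(rho) {
    cfg <- simulationConfig(genomeLength = 20000L, nElements = 0L,
      probeSpacing = 500L, nSamples = 1L,
      classMix = c(positive = 0L, negative = 1L, null = 0L),
      windowSizes = c(50L, 100L),
      nickRate = c(positive = rho, negative = rho, null = rho),
      prtNoiseSd = 0, seed = 23L)
    truth <- simulateCohort(cfg, simulateGenome(cfg))$truth
    simulatePrtReadout(truth)$ratio
  }
  rhos <- c(5e-3, 1e-3, 5e-4, 1e-4, 2e-5)
  ratios <- vapply(rhos, ratioAt, 0)
  expect_true(all(diff(ratios) < 0))
  expect_true(all(ratios < rEq))
})

test_that("sonication raises mean PRT ratios toward the maximum", {
  cfg <- simulationConfig(genomeLength = 30000L, nElements = 0L,
    probeSpacing = 500L, nSamples = 6L,
    classMix = c(positive = 0L, negative = 6L, null = 0L),
    windowSizes = c(50L, 100L), prtNoiseSd = 0.02, seed = 29L)
  truth <- simulateCohort(cfg, simulateGenome(cfg))$truth
  deltas <- vapply(1:5, function(s) {
    before <- mean(simulatePrtReadout(truth, seed = 100 + s)$ratio)
    sheared <- applyFragmentation(truth, "sonication",
                                  meanFragment = 100, seed = s)
    after <- mean(simulatePrtReadout(sheared, seed = 200 + s)$ratio)
    after - before
  }, 0)
  expect_true(all(deltas > 0))
  sheared <- applyFragmentation(truth, "sonication", meanFragment = 100,
                                seed = 1L)
  expect_lt(abs(mean(simulatePrtReadout(sheared, seed = 7L)$ratio) - 1.43),
            0.05)
})

test_that("class mix and seeds are validated", {
  expect_error(simulationConfig(nSamples = 10L,
    classMix = c(positive = 2L, negative = 2L, null = 2L)),
    "sum to nSamples")
  expect_error(simulationConfig(noiseSd = -1), "noiseSd")
})
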