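# Quantile normalization, the per-sample wave regression, correction,
# variance reporting and extreme-sample classification.

test_that("quantile normalization matches hand computation", {
  m <- cbind(a = c(2, 4, 6), b = c(1, 2, 3))
  qn <- quantileNormalize(m)
  expect_equal(unname(qn[, "a"]), c(1.5, 3.0, 4.5))
  expect_equal(unname(qn[, "b"]), c(1.5, 3.0, 4.5))
  # reversed ranks map through the same reference
  m2 <- cbind(a = c(6, 4, 2), b = c(1, 2, 3))
  qn2 <- quantileNormalize(m2)
  expect_equal(unname(qn2[, "a"]), c(4.5, 3.0, 1.5))
})

test_that("normalized columns share one distribution exactly", {
  set.seed(31)
  m <- matrix(rnorm(35), 5, 7)
  qn <- quantileNormalize(m)
  ref <- sort(qn[, 1])
  for (j in 2:7) expect_equal(sort(qn[, j]), ref)
  m[2, 3] <- NA
  expect_error(quantileNormalize(m), "missing")
  expect_error(quantileNormalize(matrix(1:5, ncol = 1)), "2 samples")
})

test_that("ties receive the average of the spanned reference values", {
  m <- cbind(a = c(1, 1, 5), b = c(10, 20, 30))
  qn <- quantileNormalize(m)
  expect_equal(unname(qn[1, "a"]), unname(qn[2, "a"]))
  expect_equal(sum(qn[, "a"]), sum(qn[, "b"]))
})

test_that("small fits reproduce the normal-equations solution", {
  set.seed(37)
  for (rep in 1:5) {
    content <- syntheticContent(20, windows = 100L, seed = rep)
    cm <- contentMatrix(content)
    y <- rnorm(20)
    mdl <- suppressWarnings(fitWaveModel(y, content, degree = 2L))
    # oracle: explicit centered polynomial design + normal equations
    X <- cbind(1,
      cm[, "GC_w100"] - mean(cm[, "GC_w100"]),
      (cm[, "GC_w100"] - mean(cm[, "GC_w100"]))^2,
      cm[, "CpG_w100"] - mean(cm[, "CpG_w100"]),
      (cm[, "CpG_w100"] - mean(cm[, "CpG_w100"]))^2)
    expected <- normalEqCoef(X, y)
    got <- unname(mdl@coefficients[c("(Intercept)", "GC_w100_p1",
      "GC_w100_p2", "CpG_w100_p1", "CpG_w100_p2")])
    expect_equal(got, expected, tolerance = 1e-10)
  }
})

test_that("constant response gives zero wave terms and zero residual", {
  content <- syntheticContent(60, windows = c(50L, 100L), seed = 3)
  mdl <- suppressWarnings(fitWaveModel(rep(0.25, 60), content))
  wave <- mdl@terms[!is.na(mdl@terms$metric), ]
  expect_true(all(abs(wave$estimate) < 1e-12))
  expect_equal(mdl@variancePost, 0)
  expect_equal(varianceExplained(mdl), 0) # variancePre is 0 too
})

test_that("a zero-noise planted wave is recovered exactly", {
  content <- syntheticContent(200, windows = c(50L, 100L), seed = 9)
  cm <- contentMatrix(content)
  x <- cm[, "GC_w100"] - mean(cm[, "GC_w100"])
  y <- 0.3 + 1.2 * x - 4 * x^2
  mdl <- suppressWarnings(fitWaveModel(y, content))
  expect_equal(unname(mdl@coefficients["GC_w100_p1"]), 1.2,
               tolerance = 1e-8)
  expect_equal(unname(mdl@coefficients["GC_w100_p2"]), -4,
               tolerance = 1e-8)
  corrected <- correctLrr(mdl, y, content)
  expect_lt(var(corrected), 1e-16)
  expect_equal(mean(corrected), mean(y))
})

test_that("stratum offsets are absorbed by the rescaling terms", {
  set.seed(41)
  content <- syntheticContent(300, windows = 100L, seed = 11)
  strata <- rep(c("s1", "s2", "s3"), each = 100)
  y <- c(rep(0, 100), rep(0.5, 100), rep(-0.2, 100))
  mdl <- suppressWarnings(fitWaveModel(y, content, strata = strata))
  expect_equal(unname(mdl@coefficients["stratums2"]), 0.5,
               tolerance = 1e-8)
  expect_lt(mdl@variancePost, 1e-16)
})

test_that("rank-deficient designs drop aliased terms with a warning", {
  content <- syntheticContent(100, windows = 100L, seed = 13)
  cm <- contentMatrix(content)
  cm[, "CpG_w100"] <- cm[, "GC_w100"] # perfectly aliased
  dup <- new("WindowContentMatrix", content = cm, windows = 100L,
             metrics = c("GC", "CpG"))
  expect_warning(mdl <- fitWaveModel(rnorm(100), dup), "aliased")
  expect_true(any(mdl@terms$aliased))
  expect_true(all(is.finite(mdl@terms$z[!mdl@terms$aliased])))
})

test_that("too few probes is an error", {
  content <- syntheticContent(5, windows = 100L, seed = 15)
  expect_error(suppressWarnings(fitWaveModel(rnorm(5), content)),
               "too few probes")
})

test_that("correction never inflates variance and checks its design", {
  set.seed(43)
  for (rep in 1:10) {
    content <- syntheticContent(150, windows = c(50L, 100L), seed = rep)
    y <- rnorm(150)
    mdl <- fitWaveModel(y, content)
    expect_lte(mdl@variancePost, mdl@variancePre)
    corrected <- correctLrr(mdl, y, content)
    expect_lte(var(corrected), var(y) + 1e-12)
    expect_equal(mean(corrected), mean(y))
  }
  mdl <- fitWaveModel(rnorm(150), syntheticContent(150, 100L, 1))
  other <- syntheticContent(150, c(50L, 100L), 2)
  expect_error(correctLrr(mdl, rnorm(150), other), "design mismatch")
})

test_that("per-term Z is standard normal under the null", {
  set.seed(47)
  content <- syntheticContent(1500, windows = c(50L, 100L), seed = 21)
  zs <- replicate(200, {
    mdl <- fitWaveModel(rnorm(1500, sd = 0.05), content)
    mdl@terms$z[mdl@terms$term == "GC_w100_p1"]
  })
  expect_gt(ks.test(zs, "pnorm")$p.value, 0.01)
})

test_that("extreme-sample labels flip exactly under LRR negation", {
  fx <- sharedWaveCohort()
  lrr <- lrrMatrix(fx$cohort)
  strata <- probeStrata(fx$cohort)
  cls <- classifyExtremeSamples(fx$models)
  negModels <- lapply(colnames(lrr), function(s)
    fitWaveModel(-lrr[, s], fx$content, strata, sample = s))
  names(negModels) <- colnames(lrr)
  clsNeg <- classifyExtremeSamples(negModels)
  swap <- c(positive = "negative", negative = "positive", null = "null")
  expect_equal(clsNeg$label, unname(swap[cls$label]))
  expect_equal(clsNeg$z, -cls$z, tolerance = 1e-10)
})

test_that("planted classes classify correctly at the default threshold", {
  fx <- sharedWaveCohort()
  cls <- classifyExtremeSamples(fx$models)
  expect_equal(cls$label, fx$truth@samples$class)
  picked <- cls$term[cls$label != "null"]
  expect_true(all(picked == "GC_w100_p1"))
})

test_that("the variance report separates affected from null samples", {
  fx <- sharedWaveCohort()
  vr <- varianceReport(fx$models)
  expect_equal(nrow(vr), 12)
  expect_true(all(vr$variance_post <= vr$variance_pre))
  byClass <- split(vr$variance_ratio, fx$truth@samples$class)
  expect_lt(max(byClass$positive, byClass$negative), 0.6)
  expect_gt(min(byClass$null), 0.9)
  path <- tempfile(fileext = ".tsv")
  varianceReport(fx$models, path)
  expect_equal(read.delim(path, comment.char = "#")$sample, vr$sample)
})
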