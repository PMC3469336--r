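# Independent brute-force oracles and small fixture builders. These
# deliberately avoid the package's own code paths: substring counting,
# IUPAC expansion, fragment assembly and normal equations are all
# re-derived from first principles here.

randSeq <- function(n, gc = 0.4) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Brute-force window content by explicit character counting.
naiveWindowContent <- function(seqstr, center, w, metric) {
  L <- nchar(seqstr)
  h <- floor(w / 2)
  a <- max(1, center - h); b <- min(L, center + h)
  chars <- strsplit(substr(seqstr, a, b), "")[[1]]
  valid <- chars %in% c("A", "C", "G", "T")
  eff <- sum(valid)
  if (metric == "GC") {
    if (eff == 0) return(NA_real_)
    return(sum(chars %in% c("G", "C")) / eff)
  }
  if (eff <= 1) return(NA_real_)
  ncg <- 0
  for (i in seq_len(length(chars) - 1))
    if (chars[i] == "C" && chars[i + 1] == "G") ncg <- ncg + 1
  ncg / (eff - 1)
}

iupacMap <- c(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT",
  S = "CG", W = "AT", K = "GT", M = "AC", B = "CGT", D = "AGT",
  H = "ACT", V = "ACG", N = "ACGT")

# Every concrete DNA string matching an IUPAC pattern.
iupacExpand <- function(pattern) {
  sets <- strsplit(iupacMap[strsplit(pattern, "")[[1]]], "")
  out <- ""
  for (s in sets) out <- as.vector(outer(out, s, paste0))
  out
}

# Brute-force restriction site scan by equality against the expansion.
naiveFindSites <- function(seqstr, recognition, cutOffset) {
  targets <- iupacExpand(recognition)
  k <- nchar(recognition)
  hits <- integer(0)
  for (i in seq_len(nchar(seqstr) - k + 1))
    if (substr(seqstr, i, i + k - 1) %in% targets)
      hits <- c(hits, i + cutOffset)
  hits
}

# Assemble fragments from cut positions (cut c starts a new fragment at
# base c) and test target/element co-membership.
fragmentOracle <- function(L, cuts, targetStart, targetEnd,
                           elementBoundary) {
  bounds <- sort(unique(c(1, cuts, L + 1)))
  frags <- cbind(bounds[-length(bounds)], bounds[-1] - 1)
  inFrag <- function(pos) which(frags[, 1] <= pos & frags[, 2] >= pos)
  fT1 <- inFrag(targetStart); fT2 <- inFrag(targetEnd)
  if (fT1 != fT2) return("destroyed")
  if (fT1 != inFrag(elementBoundary)) return("separated")
  "linked"
}

# OLS by explicit normal equations.
normalEqCoef <- function(X, y) {
  as.numeric(solve(t(X) %*% X, t(X) %*% y))
}

# All permutations of 1..n, generated by recursive insertion (distinct
# from the package's prefix-based generator).
allPermsByInsertion <- function(n) {
  perms <- list(1L)
  for (k in 2:n) {
    perms <- unlist(lapply(perms, function(p)
      lapply(seq_len(k), function(pos) append(p, k, after = pos - 1L))),
      recursive = FALSE)
  }
  do.call(rbind, perms)
}

# Small wave-only cohort shared across tests (built once per run).
.fixtureCache <- new.env(parent = emptyenv())

sharedWaveCohort <- function() {
  if (!is.null(.fixtureCache$cohort)) return(.fixtureCache$cohort)
  cfg <- simulationConfig(genomeLength = 200000L, nElements = 0L,
    probeSpacing = 100L, windowSizes = c(50L, 100L, 500L),
    nSamples = 12L, classMix = c(positive = 5L, negative = 4L, null = 3L),
    seed = 42L)
  sim <- simulateGenome(cfg)
  content <- buildContentMatrix(sim$genome, sim$manifest, cfg@windowSizes)
  cs <- simulateCohort(cfg, sim, content)
  models <- fitCohortModels(cs$cohort, content)
  .fixtureCache$cohort <- list(cfg = cfg, sim = sim, content = content,
    cohort = cs$cohort, truth = cs$truth, models = models)
  .fixtureCache$cohort
}

# Content matrix fixture with given column layout, filled uniformly.
syntheticContent <- function(n, windows, seed = 1) {
  set.seed(seed)
  metrics <- c("GC", "CpG")
  m <- matrix(runif(n * 2 * length(windows), 0.2, 0.6), nrow = n,
    dimnames = list(NULL, paste0(rep(metrics, each = length(windows)),
      "_w", rep(windows, 2))))
  new("WindowContentMatrix", content = m, windows = as.integer(windows),
      metrics = metrics)
}

# Build a genome with an element and a target amplicon at a known gap,
# optionally inserting enzyme sites at chosen positions.
advisorFixture <- function(seed = 1, gap = 1500, insertAt = integer(0),
                           site = "CCATGG") {
  set.seed(seed)
  left <- randSeq(4000, gc = 0.3)
  element <- randSeq(1200, gc = 0.85)
  spacer <- randSeq(gap, gc = 0.3)
  target <- randSeq(400, gc = 0.3)
  right <- randSeq(4000, gc = 0.3)
  s <- paste0(left, element, spacer, target, right)
  for (pos in insertAt)
    s <- paste0(substr(s, 1, pos - 1), site,
                substr(s, pos + nchar(site), nchar(s)))
  list(seq = s,
       element = genomicInterval("chr1", 4001, 5200),
       target = genomicInterval("chr1", 5201 + gap, 5600 + gap))
}

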