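## Mechanistic synthetic-cohort generator. The generative model for probe i
## of sample s is
##   LRR[s,i] = c_s
##            + sum_w sum_p beta_GC[s,w,p]  * (g[w,i] - mean(g[w,.]))^p
##            + sum_w sum_p beta_CpG[s,w,p] * (c[w,i] - mean(c[w,.]))^p
##            + gamma[s, stratum(i)]
##            - A_s * exp(-rho_s * d_i) * 1[d_i <= dMax]
##            + eps,  eps ~ N(0, noiseSd^2),
## where d_i is the gap from probe i to the proximal boundary of its
## nearest extreme-GC element. The exponential distance decay is the
## probability that no nick falls between probe and element when nicks are
## Poisson with rate rho_s per bp: an intact link transmits the full
## suppression, a severed one none, and averaging over molecules gives
## A_s * exp(-rho_s * d).

#' Build a simulation configuration
#'
#' Returns the study conditions for the synthetic TUF cohort; see
#' [SimulationConfig-class] for the meaning of each field. Defaults: a
#' 1 Mb contig at 40% GC with three planted 1.5 kb elements at 80% GC,
#' probes every 200 bp, and 54 samples split 24 positive-wave / 19
#' negative-wave / 11 null. Wave coefficients are planted at the 100 bp
#' GC window (degree 1 of opposite sign for the two extreme classes,
#' plus a shared degree-2 term); their amplitude is calibrated so an
#' extreme sample's planted-term Z score is ~60 in the reference
#' conditions (n = 5000 probes, noise SD 0.05). The negative class
#' carries the TUF suppression (A = 0.8 LRR units, nick rate 2e-4/bp:
#' intact DNA), the positive class a concentration-style wave without
#' suppression, the null class neither.
#'
#' @param genomeLength,backgroundGc,nElements,elementLength,elementGc
#'   genome architecture.
#' @param probeSpacing,windowSizes probe grid and content window sizes.
#' @param nSamples,classMix cohort size and class counts
#'   (positive/negative/null).
#' @param nickRate,suppressionA per-class nick rate (nicks/bp) and
#'   suppression amplitude (LRR units).
#' @param waveCoefs data.frame (class, metric, window, degree, beta).
#' @param nStrata,strataSd within-chip strata count and offset SD.
#' @param baselineSd,noiseSd per-sample baseline SD and probe noise SD.
#' @param dMax suppression reach in bp.
#' @param rEq equal-efficiency PRT ratio.
#' @param prtDistance,prtNoiseSd PRT assay geometry (bp) and readout noise.
#' @param seed base seed, recorded in all outputs.
#' @return a validated [SimulationConfig-class].
#' @export
simulationConfig <- function(genomeLength = 1000000L, backgroundGc = 0.40,
    nElements = 3L, elementLength = 1500L, elementGc = 0.80,
    probeSpacing = 200L,
    windowSizes = c(50L, 100L, 500L, 1000L, 5000L),
    nSamples = 54L,
    classMix = c(positive = 24L, negative = 19L, null = 11L),
    nickRate = c(positive = 5e-3, negative = 2e-4, null = 5e-3),
    suppressionA = c(positive = 0, negative = 0.8, null = 0),
    waveCoefs = defaultWaveCoefs(),
    nStrata = 2L, strataSd = 0.01, baselineSd = 0.02, noiseSd = 0.05,
    dMax = 50000, rEq = 1.43, prtDistance = 1000, prtNoiseSd = 0.03,
    seed = 1L) {
  cfg <- new("SimulationConfig", genomeLength = as.integer(genomeLength),
    backgroundGc = backgroundGc, nElements = as.integer(nElements),
    elementLength = as.integer(elementLength), elementGc = elementGc,
    probeSpacing = as.integer(probeSpacing),
    windowSizes = as.integer(windowSizes), nSamples = as.integer(nSamples),
    classMix = setNames(as.integer(classMix), names(classMix)),
    nickRate = nickRate, suppressionA = suppressionA,
    waveCoefs = waveCoefs, nStrata = as.integer(nStrata),
    strataSd = strataSd, baselineSd = baselineSd, noiseSd = noiseSd,
    dMax = dMax, rEq = rEq, prtDistance = prtDistance,
    prtNoiseSd = prtNoiseSd, seed = as.integer(seed))
  validObject(cfg)
  cfg
}

#' Default planted wave coefficients
#'
#' Degree-1 coefficients of opposite sign at the 100 bp GC window for the
#' positive and negative classes, plus a shared degree-2 term.
#'
#' @param beta1 degree-1 amplitude (LRR per unit centered GC fraction).
#' @param beta2 degree-2 amplitude.
#' @export
defaultWaveCoefs <- function(beta1 = 1.6, beta2 = 12) {
  data.frame(
    class = c("positive", "positive", "negative", "negative"),
    metric = "GC", window = 100L, degree = c(1L, 2L, 1L, 2L),
    beta = c(beta1, beta2, -beta1, beta2))
}

#' Simulate a genome with planted extreme-GC elements and a probe grid
#'
#' Background bases are i.i.d. at `backgroundGc`; elements are placed at
#' uniformly drawn, non-overlapping loci (minimum 5 kb apart and 1 kb
#' from contig ends) and filled with i.i.d. bases at `elementGc`; probes
#' sit every `probeSpacing` bp. Reproducible under a fixed seed.
#'
#' @param config a [SimulationConfig-class].
#' @param seed random seed (defaults to `config@seed`).
#' @return list with `genome` (named [Biostrings::DNAStringSet]),
#'   `elements` ([GenomicRanges::GRanges] with realized `gc_fraction`
#'   and `length_bp`), and `manifest` (probe data.frame).
#' @export
simulateGenome <- function(config, seed = config@seed) {
  set.seed(seed)
  L <- config@genomeLength
  gc <- config@backgroundGc
  bases <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                  prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  len <- config@elementLength
  starts <- integer(0)
  if (config@nElements > 0L) {
    margin <- 1000L
    minGap <- 5000L
    for (attempt in seq_len(10000L)) {
      cand <- sort(sample.int(L - len - 2L * margin,
                              config@nElements) + margin)
      if (config@nElements == 1L ||
          all(diff(cand) >= len + minGap)) { starts <- cand; break }
    }
    if (!length(starts))
      stop("could not place ", config@nElements,
           " non-overlapping elements; reduce nElements or elementLength")
    egc <- config@elementGc
    for (s in starts)
      bases[s:(s + len - 1L)] <- sample(c("A", "C", "G", "T"), len,
        replace = TRUE,
        prob = c((1 - egc) / 2, egc / 2, egc / 2, (1 - egc) / 2))
  }
  seqstr <- paste(bases, collapse = "")
  genome <- Biostrings::DNAStringSet(setNames(seqstr, "chr1"))
  elements <- if (length(starts)) {
    gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(starts,
                                                          width = len))
    prof <- .seqProfiles(seqstr)
    gr$gc_fraction <- (prof$csGC[GenomicRanges::end(gr) + 1L] -
      prof$csGC[GenomicRanges::start(gr)]) /
      (GenomicRanges::end(gr) - GenomicRanges::start(gr) + 1L)
    gr$length_bp <- GenomicRanges::width(gr)
    gr
  } else .emptyElements("chr1")
  pos <- seq.int(config@probeSpacing, L, by = config@probeSpacing)
  manifest <- data.frame(
    probe_id = sprintf("p%06d", seq_along(pos)),
    chrom = "chr1", pos = as.integer(pos), stringsAsFactors = FALSE)
  list(genome = genome, elements = elements, manifest = manifest)
}

.classLabels <- function(config) {
  rep(names(config@classMix), config@classMix)
}

.probeStrata <- function(n, nStrata) {
  paste0("strip", ceiling(seq_len(n) / ceiling(n / nStrata)))
}

#' Simulate the cohort LRR matrix with full ground truth
#'
#' Applies the generative model documented above to a simulated genome
#' and its content matrix. The truth object records every latent
#' quantity: element positions, per-probe distances, per-sample class,
#' nick rate, suppression amplitude, wave coefficients and stratum
#' offsets.
#'
#' @param config a [SimulationConfig-class].
#' @param sim output of [simulateGenome()].
#' @param content optional [WindowContentMatrix]; computed from the
#'   simulated genome when missing.
#' @param seed random seed (defaults to `config@seed + 1`).
#' @return list with `cohort` (a [TufCohort-class]) and `truth`
#'   (a [CohortTruth-class]).
#' @export
simulateCohort <- function(config, sim, content = NULL,
                           seed = config@seed + 1L) {
  set.seed(seed)
  manifest <- sim$manifest
  n <- nrow(manifest)
  if (is.null(content))
    content <- buildContentMatrix(sim$genome, manifest,
                                  windowSizes = config@windowSizes)
  cm <- contentMatrix(content)
  if (nrow(cm) != n) stop("content rows must match the manifest")
  centers <- colMeans(cm, na.rm = TRUE)
  classes <- .classLabels(config)
  N <- config@nSamples
  ids <- sprintf("S%02d", seq_len(N))
  samples <- data.frame(sample_id = ids, class = classes,
    rho = unname(config@nickRate[classes]),
    A = unname(config@suppressionA[classes]),
    baseline = rnorm(N, 0, config@baselineSd),
    stringsAsFactors = FALSE)
  waveCoefs <- do.call(rbind, lapply(seq_len(N), function(s) {
    wc <- config@waveCoefs[config@waveCoefs$class == classes[s], ,
                           drop = FALSE]
    if (!nrow(wc)) return(NULL)
    data.frame(sample_id = ids[s], metric = wc$metric, window = wc$window,
               degree = wc$degree, beta = wc$beta,
               stringsAsFactors = FALSE)
  }))
  if (is.null(waveCoefs))
    waveCoefs <- data.frame(sample_id = character(0), metric = character(0),
      window = integer(0), degree = integer(0), beta = numeric(0))
  strata <- .probeStrata(n, config@nStrata)
  strataLevels <- unique(strata)
  strataOffsets <- matrix(rnorm(N * length(strataLevels), 0,
                                config@strataSd),
    nrow = N, dimnames = list(ids, strataLevels))
  ann <- annotateSusceptibility(manifest, sim$elements, dMax = config@dMax)
  probes <- cbind(manifest, stratum = strata,
                  distance = ann$distance,
                  nearest_boundary = ann$nearest_boundary)
  supBase <- ifelse(is.finite(probes$distance), 1, 0)
  lrr <- matrix(0, nrow = n, ncol = N, dimnames = list(manifest$probe_id,
                                                       ids))
  stratumIdx <- match(strata, strataLevels)
  for (s in seq_len(N)) {
    y <- rep(samples$baseline[s], n)
    wc <- waveCoefs[waveCoefs$sample_id == ids[s], , drop = FALSE]
    for (j in seq_len(nrow(wc))) {
      col <- paste0(wc$metric[j], "_w", wc$window[j])
      if (!col %in% colnames(cm))
        stop("waveCoefs reference window not in content: ", col)
      x <- cm[, col] - centers[col]
      y <- y + wc$beta[j] * x^wc$degree[j]
    }
    y <- y + strataOffsets[s, stratumIdx]
    y <- y - samples$A[s] * supBase *
      exp(-samples$rho[s] * pmin(probes$distance, config@dMax))
    y <- y + rnorm(n, 0, config@noiseSd)
    lrr[, s] <- y
  }
  cohort <- tufCohort(lrr, manifest, strata = strata, sampleInfo = samples)
  truth <- new("CohortTruth", elements = sim$elements, probes = probes,
    samples = samples, waveCoefs = waveCoefs,
    strataOffsets = strataOffsets, prtLinkage = 1, config = config)
  validObject(truth)
  list(cohort = cohort, truth = truth)
}

#' Fragment the template DNA in silico
#'
#' Sonication scatters Poisson breakpoints at rate `1/meanFragment` per
#' bp; digestion breaks at the enzyme's cut positions (deterministic). A
#' probe whose link to its nearest element is severed by any break has
#' its distance set to `Inf` — the suppression term then vanishes for
#' that probe. Sonication also attenuates the PRT-side linkage factor by
#' `exp(-prtDistance / meanFragment)`, the Poisson probability that no
#' break falls between the test amplicon and its anchoring element;
#' `separatePrt = TRUE` marks a digest known (e.g. from [adviseDigest()])
#' to cut between them, zeroing the linkage.
#'
#' @param truth a [CohortTruth-class].
#' @param mode `"sonication"` or `"digestion"`.
#' @param meanFragment mean fragment size in bp (sonication).
#' @param enzyme a [RestrictionEnzyme-class] (digestion).
#' @param sequence genome sequence (digestion).
#' @param separatePrt logical; digestion severs the PRT-side link.
#' @param seed random seed for sonication breakpoints.
#' @return the updated [CohortTruth-class].
#' @export
applyFragmentation <- function(truth,
    mode = c("sonication", "digestion"), meanFragment = NULL,
    enzyme = NULL, sequence = NULL, separatePrt = FALSE, seed = NULL) {
  mode <- match.arg(mode)
  L <- truth@config@genomeLength
  if (mode == "sonication") {
    if (is.null(meanFragment) || meanFragment <= 0)
      stop("meanFragment must be > 0")
    if (!is.null(seed)) set.seed(seed)
    k <- rpois(1L, L / meanFragment)
    breaks <- sort(sample.int(L - 1L, min(k, L - 1L)) + 1L)
    truth@prtLinkage <- truth@prtLinkage *
      exp(-truth@config@prtDistance / meanFragment)
  } else {
    if (is.null(enzyme) || is.null(sequence))
      stop("digestion needs an enzyme and the genome sequence")
    breaks <- findRestrictionSites(sequence, enzyme)
    if (separatePrt) truth@prtLinkage <- 0
  }
  if (length(breaks)) {
    p <- truth@probes
    fin <- which(is.finite(p$distance))
    if (length(fin)) {
      # a break at c starts a new fragment at base c
      fragOf <- function(x) findInterval(x, breaks)
      sep <- fragOf(p$pos[fin]) != fragOf(p$nearest_boundary[fin])
      p$distance[fin[sep]] <- Inf
      truth@probes <- p
    }
  }
  truth
}

#' Simulate per-sample PRT test:reference ratios
#'
#' The expected readout is
#' `rEq * (1 - min(A_s, 1) * exp(-rho_s * dPrt) * prtLinkage)` plus
#' Gaussian readout noise, clipped at zero. With no suppression (or after
#' physical separation, `dPrt = Inf` or linkage 0) every sample sits on
#' the equal-efficiency line `rEq`.
#'
#' @param truth a [CohortTruth-class].
#' @param dPrt distance (bp) from the test amplicon to its anchoring
#'   element; `Inf` means physically separated.
#' @param assayId label for the output rows.
#' @param seed random seed for readout noise.
#' @return data.frame (sample_id, assay_id, ratio).
#' @export
simulatePrtReadout <- function(truth, dPrt = truth@config@prtDistance,
                               assayId = "sim2n13", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- truth@config
  s <- truth@samples
  supp <- if (is.finite(dPrt))
    pmin(s$A, 1) * exp(-s$rho * dPrt) * truth@prtLinkage
  else rep(0, nrow(s))
  ratio <- cfg@rEq * (1 - supp) +
    rnorm(nrow(s), 0, cfg@prtNoiseSd)
  data.frame(sample_id = s$sample_id, assay_id = assayId,
             ratio = pmax(ratio, 0), stringsAsFactors = FALSE)
}

#' Read / write a simulation configuration as YAML
#'
#' Keys mirror the [SimulationConfig-class] fields; `waveCoefs` is a list
#' of records.
#'
#' @param path file path.
#' @export
readSimulationConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$waveCoefs))
    y$waveCoefs <- do.call(rbind,
      lapply(y$waveCoefs, as.data.frame, stringsAsFactors = FALSE))
  for (f in c("classMix", "nickRate", "suppressionA"))
    if (!is.null(y[[f]])) y[[f]] <- unlist(y[[f]])
  do.call(simulationConfig, y)
}

#' @rdname readSimulationConfig
#' @param config a [SimulationConfig-class].
#' @export
writeSimulationConfig <- function(config, path) {
  slots <- slotNames(config)
  y <- lapply(setNames(slots, slots), function(s) slot(config, s))
  y$classMix <- as.list(y$classMix)
  y$nickRate <- as.list(y$nickRate)
  y$suppressionA <- as.list(y$suppressionA)
  y$waveCoefs <- lapply(seq_len(nrow(config@waveCoefs)), function(i)
    as.list(config@waveCoefs[i, ]))
  yaml::write_yaml(y, path)
  invisible(path)
}
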