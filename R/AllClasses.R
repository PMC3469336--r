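## Central S4 classes. Intervals are 1-based fully-closed everywhere
## user-facing; BED I/O converts to 0-based half-open (see io.R).

#' WindowContentMatrix: multi-scale GC/CpG content per probe
#'
#' One row per probe of a manifest, one column per (metric, window size)
#' pair, holding the fraction of G+C bases (metric `"GC"`) or of CpG
#' dinucleotide slots occupied by CG (metric `"CpG"`) in a window centered
#' on the probe position. Values lie in `[0, 1]`; `NA` marks windows with
#' no unambiguous sequence. Columns are named `<metric>_w<window>`.
#'
#' @slot content numeric matrix, probes x (metrics * windows).
#' @slot windows integer vector of window sizes (bp).
#' @slot metrics character vector, subset of `c("GC", "CpG")`.
#' @export
setClass("WindowContentMatrix",
  representation(content = "matrix", windows = "integer",
                 metrics = "character"))

setValidity("WindowContentMatrix", function(object) {
  msg <- character()
  v <- object@content
  if (!is.numeric(v)) msg <- c(msg, "content must be numeric")
  if (length(v) && any(v < 0 | v > 1, na.rm = TRUE))
    msg <- c(msg, "content values must lie in [0, 1]")
  if (ncol(v) != length(object@windows) * length(object@metrics))
    msg <- c(msg, "ncol(content) must equal length(windows) * length(metrics)")
  if (!all(object@metrics %in% c("GC", "CpG")))
    msg <- c(msg, "metrics must be a subset of c('GC', 'CpG')")
  if (any(object@windows < 2))
    msg <- c(msg, "window sizes must be >= 2")
  if (length(msg)) msg else TRUE
})

#' TufCohort: a probes x samples LRR experiment
#'
#' Thin wrapper around [SummarizedExperiment::SummarizedExperiment] holding
#' a `"lrr"` assay (probes in rows, samples in columns), probe metadata
#' (`probe_id`, `chrom`, `pos`, chip `stratum`) in `rowData`, and sample
#' metadata in `colData`.
#'
#' @export
setClass("TufCohort", contains = "SummarizedExperiment")

setValidity("TufCohort", function(object) {
  msg <- character()
  if (!"lrr" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "must contain an assay named 'lrr'")
  else if (!all(is.finite(SummarizedExperiment::assay(object, "lrr"))))
    msg <- c(msg, "lrr values must be finite")
  rd <- SummarizedExperiment::rowData(object)
  need <- c("probe_id", "chrom", "pos", "stratum")
  if (!all(need %in% colnames(rd)))
    msg <- c(msg, paste("rowData must contain:", paste(need, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' SimulationConfig: study conditions for the synthetic TUF cohort
#'
#' Holds every free parameter of the mechanistic generator. The defaults
#' are the package's reference study conditions: a 1 Mb genome at 40%
#' background GC carrying three 1.5 kb extreme-GC (80%) elements, probes
#' every 200 bp (5000 probes), and a 54-sample cohort split 24/19/11 into
#' positive-wave, negative-wave (TUF-affected) and null classes. The
#' negative class models intact DNA: a low nick rate `rho` leaves long
#' stretches attached to anchoring elements, so suppression of amplitude
#' `A` (LRR units) decays slowly with distance, and its PRT ratios fall
#' well below the equal-efficiency line `rEq = 1.43`.
#'
#' @slot genomeLength integer, contig length in bp.
#' @slot backgroundGc fraction, background GC content.
#' @slot nElements integer, number of planted extreme-GC elements.
#' @slot elementLength integer bp, planted element length.
#' @slot elementGc fraction, planted element GC content.
#' @slot probeSpacing integer bp between consecutive probes.
#' @slot windowSizes integer vector of content window sizes (bp).
#' @slot nSamples integer, cohort size.
#' @slot classMix named integer vector `c(positive, negative, null)`.
#' @slot nickRate named numeric, per-class nick rate (nicks/bp).
#' @slot suppressionA named numeric, per-class suppression amplitude (LRR).
#' @slot waveCoefs data.frame (class, metric, window, degree, beta) of
#'   planted wave coefficients on centered covariates.
#' @slot nStrata integer, number of within-chip strata (probe strips).
#' @slot strataSd numeric, SD of per-sample stratum offsets (LRR units).
#' @slot baselineSd numeric, SD of per-sample baseline intercepts.
#' @slot noiseSd numeric, probe-level Gaussian noise SD (LRR units).
#' @slot dMax numeric bp, maximum reach of the suppression effect.
#' @slot rEq numeric, equal-efficiency PRT test:reference ratio.
#' @slot prtDistance numeric bp, distance from the PRT test amplicon to its
#'   anchoring element (off-array assay geometry).
#' @slot prtNoiseSd numeric, PRT readout noise SD.
#' @slot seed integer, base random seed recorded in all outputs.
#' @export
setClass("SimulationConfig",
  representation(genomeLength = "integer", backgroundGc = "numeric",
    nElements = "integer", elementLength = "integer", elementGc = "numeric",
    probeSpacing = "integer", windowSizes = "integer", nSamples = "integer",
    classMix = "integer", nickRate = "numeric", suppressionA = "numeric",
    waveCoefs = "data.frame", nStrata = "integer", strataSd = "numeric",
    baselineSd = "numeric", noiseSd = "numeric", dMax = "numeric",
    rEq = "numeric", prtDistance = "numeric", prtNoiseSd = "numeric",
    seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@genomeLength < 1000L)
    msg <- c(msg, "genomeLength must be >= 1000 bp")
  if (object@backgroundGc <= 0 || object@backgroundGc >= 1)
    msg <- c(msg, "backgroundGc must lie in (0, 1)")
  cls <- c("positive", "negative", "null")
  if (!identical(sort(names(object@classMix)), sort(cls)))
    msg <- c(msg, "classMix must be named positive/negative/null")
  else if (sum(object@classMix) != object@nSamples)
    msg <- c(msg, "classMix must sum to nSamples")
  for (s in c("nickRate", "suppressionA")) {
    v <- slot(object, s)
    if (!all(cls %in% names(v)))
      msg <- c(msg, paste(s, "must be named positive/negative/null"))
    else if (any(v < 0)) msg <- c(msg, paste(s, "must be >= 0"))
  }
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@rEq <= 0) msg <- c(msg, "rEq must be > 0")
  wc <- object@waveCoefs
  need <- c("class", "metric", "window", "degree", "beta")
  if (nrow(wc) && !all(need %in% colnames(wc)))
    msg <- c(msg, paste("waveCoefs must contain:", paste(need, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' CohortTruth: ground truth emitted by the synthetic generator
#'
#' @slot elements [GenomicRanges::GRanges] of planted extreme-GC elements
#'   (metadata: `gc_fraction`, `length_bp`).
#' @slot probes data.frame (probe_id, chrom, pos, stratum, distance,
#'   nearest_boundary). `distance` is the gap (bp) from the probe to the
#'   proximal boundary of its nearest element, 0 inside one, `Inf` when no
#'   element lies within `dMax` or the probe has been physically separated
#'   from it (fragmentation).
#' @slot samples data.frame (sample_id, class, rho, A, baseline).
#' @slot waveCoefs data.frame (sample_id, metric, window, degree, beta).
#' @slot strataOffsets matrix samples x strata of per-sample offsets.
#' @slot prtLinkage numeric in `[0, 1]`: probability that the PRT test
#'   amplicon is still physically linked to its anchoring element
#'   (1 = untreated; lowered by sonication, 0 after separating digestion).
#' @slot config the [SimulationConfig] that generated the cohort.
#' @export
setClass("CohortTruth",
  representation(elements = "GRanges", probes = "data.frame",
    samples = "data.frame", waveCoefs = "data.frame",
    strataOffsets = "matrix", prtLinkage = "numeric",
    config = "SimulationConfig"))

setValidity("CohortTruth", function(object) {
  msg <- character()
  p <- object@probes
  need <- c("probe_id", "chrom", "pos", "stratum", "distance",
            "nearest_boundary")
  if (!all(need %in% colnames(p)))
    msg <- c(msg, paste("probes must contain:", paste(need, collapse = ", ")))
  else if (any(p$distance < 0, na.rm = TRUE))
    msg <- c(msg, "probe distances must be >= 0")
  if (!all(c("sample_id", "class", "rho", "A") %in% colnames(object@samples)))
    msg <- c(msg, "samples must contain sample_id, class, rho, A")
  if (object@prtLinkage < 0 || object@prtLinkage > 1)
    msg <- c(msg, "prtLinkage must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' CorrectionModel: one sample's fitted GC/CpG wave regression
#'
#' Produced by [fitWaveModel()]. `terms` has one row per design column
#' (intercept, stratum indicators, and one row per (metric, window, degree)
#' wave term) with the OLS estimate, its standard error and the Z score
#' estimate/SE. Aliased (rank-deficient) terms carry `NA` estimates and are
#' flagged. `variancePre` is the variance of the input LRR, `variancePost`
#' the variance of the residuals; their complement ratio is the proportion
#' of LRR variance explained by the wave model.
#'
#' @slot sample sample identifier.
#' @slot terms data.frame (term, metric, window, degree, estimate, se, z,
#'   aliased).
#' @slot coefficients named numeric vector (NA for aliased terms).
#' @slot centers named numeric vector of covariate centers used to build
#'   the polynomial design (needed to re-apply the model).
#' @slot degree integer polynomial degree.
#' @slot windows integer window sizes entering the design.
#' @slot metrics character metrics entering the design.
#' @slot strataLevels character levels of the stratum factor.
#' @slot variancePre,variancePost numeric LRR variance before/after.
#' @export
setClass("CorrectionModel",
  representation(sample = "character", terms = "data.frame",
    coefficients = "numeric", centers = "numeric", degree = "integer",
    windows = "integer", metrics = "character", strataLevels = "character",
    variancePre = "numeric", variancePost = "numeric"))

setValidity("CorrectionModel", function(object) {
  msg <- character()
  if (object@variancePost > object@variancePre + 1e-12)
    msg <- c(msg, "variancePost must not exceed variancePre")
  need <- c("term", "metric", "window", "degree", "estimate", "se", "z",
            "aliased")
  if (!all(need %in% colnames(object@terms)))
    msg <- c(msg, paste("terms must contain:", paste(need, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' RestrictionEnzyme: a named IUPAC recognition site with cut offset
#'
#' The cut position reported by [findRestrictionSites()] is
#' `match start + cutOffset`, i.e. the first base of the downstream
#' fragment. Matching is forward-strand only; the classical enzymes
#' shipped with the package are palindromic, for which forward-strand
#' matching finds every site.
#'
#' @slot name enzyme name.
#' @slot recognition IUPAC recognition sequence.
#' @slot cutOffset integer in `[0, nchar(recognition)]`.
#' @export
setClass("RestrictionEnzyme",
  representation(name = "character", recognition = "character",
    cutOffset = "integer"))

setValidity("RestrictionEnzyme", function(object) {
  msg <- character()
  rec <- toupper(object@recognition)
  if (!nzchar(rec)) msg <- c(msg, "recognition must be non-empty")
  iupac <- strsplit("ACGTRYSWKMBDHVN", "")[[1]]
  if (!all(strsplit(rec, "")[[1]] %in% iupac))
    msg <- c(msg, "recognition must use valid IUPAC codes")
  if (object@cutOffset < 0L || object@cutOffset > nchar(rec))
    msg <- c(msg, "cutOffset must lie in [0, nchar(recognition)]")
  if (length(msg)) msg else TRUE
})

#' @describeIn RestrictionEnzyme-class Constructor.
#' @param name,recognition,cutOffset see slots.
#' @export
restrictionEnzyme <- function(name, recognition, cutOffset) {
  new("RestrictionEnzyme", name = as.character(name),
      recognition = toupper(as.character(recognition)),
      cutOffset = as.integer(cutOffset))
}
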