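## Accessors and show methods.

#' @rdname WindowContentMatrix-class
#' @param object a \code{WindowContentMatrix}.
#' @export
setGeneric("contentMatrix", function(object) standardGeneric("contentMatrix"))

#' @rdname WindowContentMatrix-class
#' @export
setMethod("contentMatrix", "WindowContentMatrix", function(object)
  object@content)

#' @rdname WindowContentMatrix-class
#' @export
setGeneric("windowSizes", function(object) standardGeneric("windowSizes"))

#' @rdname WindowContentMatrix-class
#' @export
setMethod("windowSizes", "WindowContentMatrix", function(object)
  object@windows)

setMethod("show", "WindowContentMatrix", function(object) {
  cat("WindowContentMatrix:", nrow(object@content), "probes x",
      ncol(object@content), "terms\n")
  cat("  metrics:", paste(object@metrics, collapse = ", "), "\n")
  cat("  windows (bp):", paste(object@windows, collapse = ", "), "\n")
})

#' @rdname TufCohort-class
#' @param object a \code{TufCohort}.
#' @export
setGeneric("lrrMatrix", function(object) standardGeneric("lrrMatrix"))

#' @rdname TufCohort-class
#' @export
setMethod("lrrMatrix", "TufCohort", function(object)
  SummarizedExperiment::assay(object, "lrr"))

#' @rdname TufCohort-class
#' @export
setGeneric("probeStrata", function(object) standardGeneric("probeStrata"))

#' @rdname TufCohort-class
#' @export
setMethod("probeStrata", "TufCohort", function(object)
  factor(SummarizedExperiment::rowData(object)$stratum))

#' @rdname TufCohort-class
#' @export
setGeneric("probeManifest", function(object) standardGeneric("probeManifest"))

#' @rdname TufCohort-class
#' @export
setMethod("probeManifest", "TufCohort", function(object) {
  rd <- SummarizedExperiment::rowData(object)
  data.frame(probe_id = rd$probe_id, chrom = rd$chrom, pos = rd$pos,
             stringsAsFactors = FALSE)
})

setMethod("show", "TufCohort", function(object) {
  cat("TufCohort:", nrow(object), "probes x", ncol(object), "samples\n")
  callNextMethod()
})

#' @rdname CorrectionModel-class
#' @param object a \code{CorrectionModel}.
#' @export
setGeneric("modelTerms", function(object) standardGeneric("modelTerms"))

#' @rdname CorrectionModel-class
#' @export
setMethod("modelTerms", "CorrectionModel", function(object) object@terms)

#' @rdname CorrectionModel-class
#' @export
setGeneric("varianceExplained", function(object)
  standardGeneric("varianceExplained"))

#' @rdname CorrectionModel-class
#' @export
setMethod("varianceExplained", "CorrectionModel", function(object) {
  if (object@variancePre <= 0) return(0)
  1 - object@variancePost / object@variancePre
})

setMethod("show", "CorrectionModel", function(object) {
  cat("CorrectionModel for sample", object@sample, "\n")
  cat(sprintf("  %d terms (degree %d; windows: %s)\n", nrow(object@terms),
              object@degree, paste(object@windows, collapse = ", ")))
  cat(sprintf("  variance pre = %.4g, post = %.4g (%.1f%% explained)\n",
              object@variancePre, object@variancePost,
              100 * varianceExplained(object)))
  wave <- object@terms[!is.na(object@terms$metric), ]
  if (nrow(wave)) {
    top <- wave[order(-abs(wave$z)), ][1, ]
    cat(sprintf("  max |Z| wave term: %s (Z = %.1f)\n", top$term, top$z))
  }
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:\n")
  cat(sprintf("  genome: %d bp at %.0f%% GC, %d element(s) (%d bp, %.0f%% GC)\n",
              object@genomeLength, 100 * object@backgroundGc,
              object@nElements, object@elementLength,
              100 * object@elementGc))
  cat(sprintf("  probes: every %d bp; windows: %s\n", object@probeSpacing,
              paste(object@windowSizes, collapse = ", ")))
  cat(sprintf("  samples: %d (%s)\n", object@nSamples,
              paste(names(object@classMix), object@classMix, sep = "=",
                    collapse = ", ")))
  cat(sprintf("  noise SD %.3g, dMax %g bp, rEq %.2f, seed %d\n",
              object@noiseSd, object@dMax, object@rEq, object@seed))
})

setMethod("show", "CohortTruth", function(object) {
  cat("CohortTruth:", nrow(object@probes), "probes,",
      nrow(object@samples), "samples,", length(object@elements),
      "element(s)\n")
  cat(sprintf("  susceptible probes (finite distance): %d; PRT linkage %.2f\n",
              sum(is.finite(object@probes$distance)), object@prtLinkage))
})

setMethod("show", "RestrictionEnzyme", function(object) {
  cat(sprintf("RestrictionEnzyme %s: %s (cut after %d)\n", object@name,
              object@recognition, object@cutOffset))
})
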