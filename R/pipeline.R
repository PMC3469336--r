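## End-to-end orchestration: simulate -> content -> correct -> detect ->
## associate -> advise, from one SimulationConfig, with per-stage
## sub-seeds so any stage can be reproduced in isolation.

## Stage k runs under seed + 101 * k (documented derivation; keeps all
## seeds well below 2^31 for small base seeds).
.stageSeed <- function(seed, k) as.integer(seed + 101L * k)

#' Run the full synthetic TUF analysis pipeline
#'
#' Executes the stages in dependency order and writes every tabular
#' output as TSV (BED for intervals, FASTA for the genome) under
#' `outdir`. Identical config + seed give byte-identical outputs. With
#' fewer than 4 samples the association stage is skipped with a notice;
#' without detected elements the advisor stage is skipped.
#'
#' @param config a [SimulationConfig-class], or path to its YAML file.
#' @param outdir output directory (created if needed).
#' @param seed base seed (defaults to `config@seed`).
#' @param cn1Threshold LRR threshold for weak-signal calls.
#' @param zThreshold classification threshold for extreme-wave samples.
#' @return the run manifest: a list with the config snapshot path, seed,
#'   per-stage status and output paths (also written as
#'   `run_manifest.json`).
#' @export
runPipeline <- function(config, outdir, seed = NULL,
                        cn1Threshold = -0.3, zThreshold = 30) {
  if (is.character(config)) config <- readSimulationConfig(config)
  stopifnot(is(config, "SimulationConfig"))
  if (is.null(seed)) seed <- config@seed
  seed <- as.integer(seed)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  outputs <- list()
  stages <- data.frame(stage = character(0), status = character(0),
                       note = character(0), stringsAsFactors = FALSE)
  note <- function(stage, status, msg = "") {
    message(sprintf("[tufscan] %-9s %s %s", stage, status, msg))
    stages[nrow(stages) + 1L, ] <<- list(stage, status, msg)
  }
  fail <- function(stage, e) {
    writeLines(conditionMessage(e), file.path(outdir,
      paste0("failed_", stage)))
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  out <- function(name, path) { outputs[[name]] <<- path; path }

  cfgPath <- out("config", file.path(outdir, "config.yaml"))
  writeSimulationConfig(config, cfgPath)

  ## -- simulate ------------------------------------------------------
  sim <- tryCatch({
    s <- simulateGenome(config, seed = .stageSeed(seed, 1L))
    Biostrings::writeXStringSet(s$genome,
      out("genome", file.path(outdir, "genome.fa")))
    writeBed(s$elements, out("elements_true",
      file.path(outdir, "elements_true.bed")), score = "gc_fraction")
    writeProbeManifest(s$manifest, out("manifest",
      file.path(outdir, "manifest.tsv")))
    s
  }, error = function(e) fail("simulate", e))
  note("simulate", "ok", sprintf("%d bp, %d probes, %d element(s)",
    config@genomeLength, nrow(sim$manifest), length(sim$elements)))

  ## -- content -------------------------------------------------------
  content <- tryCatch({
    ct <- buildContentMatrix(sim$genome, sim$manifest,
                             windowSizes = config@windowSizes)
    .writeTsv(cbind(probe_id = sim$manifest$probe_id,
                    as.data.frame(contentMatrix(ct))),
      out("content", file.path(outdir, "content.tsv")),
      "tufscan GC/CpG window content")
    ct
  }, error = function(e) fail("content", e))
  note("content", "ok", sprintf("%d terms", ncol(contentMatrix(content))))

  ## -- correct -------------------------------------------------------
  corrected <- tryCatch({
    cs <- simulateCohort(config, sim, content,
                         seed = .stageSeed(seed, 2L))
    writeIntensityMatrix(cs$cohort, out("lrr_raw",
      file.path(outdir, "lrr_raw.tsv")))
    qn <- if (ncol(cs$cohort) >= 2L) quantileNormalize(cs$cohort)
          else cs$cohort
    models <- fitCohortModels(qn, content)
    varianceReport(models, out("variance_report",
      file.path(outdir, "variance_report.tsv")))
    cls <- classifyExtremeSamples(models, zThreshold = zThreshold)
    .writeTsv(cls, out("classification",
      file.path(outdir, "classification.tsv")),
      "tufscan extreme-sample classification")
    cc <- correctCohort(models, qn, content)
    writeIntensityMatrix(cc, out("lrr_corrected",
      file.path(outdir, "lrr_corrected.tsv")))
    list(sim = cs, models = models, classes = cls, corrected = cc)
  }, error = function(e) fail("correct", e))
  note("correct", "ok", sprintf("%d sample model(s)",
    length(corrected$models)))

  ## -- detect --------------------------------------------------------
  detected <- tryCatch({
    elements <- findGcElements(sim$genome[["chr1"]], chrom = "chr1")
    writeBed(elements, out("elements_detected",
      file.path(outdir, "elements_detected.bed")), score = "gc_fraction")
    ann <- annotateSusceptibility(sim$manifest, elements,
                                  dMax = config@dMax)
    .writeTsv(ann[, c("probe_id", "distance", "susceptible")],
      out("susceptibility", file.path(outdir, "susceptibility.tsv")),
      "tufscan probe susceptibility")
    affected <- corrected$classes$sample[
      corrected$classes$label == "negative"]
    raw <- lrrMatrix(corrected$sim$cohort)
    calls <- inferCopyNumber(raw, cn1Threshold)
    regions <- if (length(affected) >= 2L)
      detectWeakRegions(calls, sim$manifest, affectedSamples = affected)
    else GenomicRanges::GRanges()
    if (length(regions))
      writeBed(regions, out("weak_regions",
        file.path(outdir, "weak_regions.bed")), score = "support")
    rates <- do.call(rbind, lapply(affected, function(s) {
      est <- try(estimateNickRate(
        probeSuppression(raw[, s], ann$distance), ann$distance),
        silent = TRUE)
      if (inherits(est, "try-error"))
        return(data.frame(sample = s, A = NA_real_, rho = NA_real_,
                          converged = FALSE))
      data.frame(sample = s, A = est$A, rho = est$rho,
                 converged = est$converged)
    }))
    if (!is.null(rates))
      .writeTsv(rates, out("nick_rates",
        file.path(outdir, "nick_rates.tsv")), "tufscan nick-rate fits")
    list(elements = elements, regions = regions, ann = ann)
  }, error = function(e) fail("detect", e))
  note("detect", "ok", sprintf("%d element(s), %d weak region(s)",
    length(detected$elements), length(detected$regions)))

  ## -- associate -----------------------------------------------------
  if (config@nSamples >= 4L) {
    tryCatch({
      readout <- simulatePrtReadout(corrected$sim$truth,
        seed = .stageSeed(seed, 5L))
      readout$replicate <- 1L
      writePrtReadouts(readout[, c("sample_id", "assay_id", "replicate",
                                   "ratio")],
        out("prt_readouts", file.path(outdir, "prt_readouts.tsv")))
      table2Report(corrected$models, readout, path = out("association",
        file.path(outdir, "association.tsv")))
    }, error = function(e) fail("associate", e))
    note("associate", "ok")
  } else {
    note("associate", "skipped", "fewer than 4 samples")
  }

  ## -- advise --------------------------------------------------------
  if (length(detected$elements)) {
    tryCatch({
      el <- detected$elements[1L]
      ts <- max(1L, GenomicRanges::start(el) - 1400L)
      target <- genomicInterval("chr1", ts, ts + 399L, "demo_target")
      enzymes <- readEnzymeTable(system.file("extdata", "enzymes.tsv",
                                             package = "tufscan"))
      neg <- config@suppressionA["negative"]
      verdicts <- adviseDigest(target, detected$elements, enzymes,
        sim$genome, A = neg, rho = config@nickRate[["negative"]],
        rEq = config@rEq, dMax = config@dMax)
      ranked <- rankTreatments(verdicts, sonicationMeanFragment = 500,
        A = neg, rho = config@nickRate[["negative"]], rEq = config@rEq)
      .writeTsv(ranked, out("advice", file.path(outdir, "advice.tsv")),
                "tufscan fragmentation advice")
    }, error = function(e) fail("advise", e))
    note("advise", "ok")
  } else {
    note("advise", "skipped", "no elements detected")
  }

  manifest <- list(seed = seed, config = cfgPath,
                   outputs = outputs, stages = stages)
  jsonlite::write_json(manifest, file.path(outdir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
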