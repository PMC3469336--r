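## TSV / BED / FASTA / YAML I/O. Tabular outputs are plain TSVs with
## '#'-prefixed provenance header lines; BED is 0-based half-open on disk
## and converted losslessly to the package's 1-based fully-closed GRanges.

.writeTsv <- function(df, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance))
    writeLines(paste0("# ", provenance), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.readTsv <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read / write a probe manifest TSV
#'
#' Columns: `probe_id`, `chrom`, `pos` (1-based), sorted by (chrom, pos).
#'
#' @param path file path.
#' @return `readProbeManifest`: a validated manifest data.frame.
#' @export
readProbeManifest <- function(path) validateManifest(.readTsv(path))

#' @rdname readProbeManifest
#' @param manifest a manifest data.frame.
#' @export
writeProbeManifest <- function(manifest, path) {
  .writeTsv(validateManifest(manifest), path, "tufscan probe manifest")
}

#' Construct a TufCohort from its parts
#'
#' @param lrr numeric matrix, probes x samples (finite values).
#' @param manifest data.frame with `probe_id`, `chrom`, `pos` matching the
#'   rows of `lrr`.
#' @param strata per-probe chip-stratum labels (recycled if length 1).
#' @param sampleInfo optional data.frame of per-sample columns.
#' @return a [TufCohort-class].
#' @export
tufCohort <- function(lrr, manifest, strata = "s1", sampleInfo = NULL) {
  manifest <- validateManifest(manifest)
  if (nrow(lrr) != nrow(manifest))
    stop("lrr rows must match manifest rows")
  strata <- rep_len(as.character(strata), nrow(manifest))
  rd <- S4Vectors::DataFrame(probe_id = manifest$probe_id,
    chrom = manifest$chrom, pos = manifest$pos, stratum = strata)
  rownames(lrr) <- manifest$probe_id
  cd <- if (is.null(sampleInfo))
    S4Vectors::DataFrame(sample_id = colnames(lrr))
  else S4Vectors::DataFrame(sampleInfo)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(lrr = lrr), rowData = rd, colData = cd)
  new("TufCohort", se)
}

#' Read / write a probes x samples LRR matrix TSV
#'
#' On disk: columns `probe_id`, `chrom`, `pos`, `stratum`, then one column
#' per sample.
#'
#' @param path file path.
#' @return `readIntensityMatrix`: a [TufCohort-class].
#' @export
readIntensityMatrix <- function(path) {
  df <- .readTsv(path)
  meta <- c("probe_id", "chrom", "pos", "stratum")
  if (!all(meta %in% colnames(df)))
    stop("intensity TSV needs columns: ", paste(meta, collapse = ", "))
  lrr <- as.matrix(df[, setdiff(colnames(df), meta), drop = FALSE])
  tufCohort(lrr, df[meta[1:3]], strata = df$stratum)
}

#' @rdname readIntensityMatrix
#' @param cohort a [TufCohort-class].
#' @export
writeIntensityMatrix <- function(cohort, path) {
  df <- cbind(probeManifest(cohort),
              stratum = as.character(probeStrata(cohort)),
              as.data.frame(lrrMatrix(cohort)))
  .writeTsv(df, path, "tufscan LRR intensity matrix")
}

#' Write / read element or region intervals as BED
#'
#' BED stores 0-based half-open coordinates; conversion to and from the
#' package's 1-based fully-closed [GenomicRanges::GRanges] is lossless.
#' A numeric metadata column named by `score` is carried in the BED score
#' field.
#'
#' @param gr a [GenomicRanges::GRanges].
#' @param path file path.
#' @param score name of a numeric metadata column to store as BED score.
#' @export
writeBed <- function(gr, path, score = NULL) {
  out <- gr
  if (is.null(names(out)))
    names(out) <- paste0("region_", seq_along(out))
  if (!is.null(score) && score %in% colnames(S4Vectors::mcols(out)))
    out$score <- as.numeric(S4Vectors::mcols(out)[[score]])
  rtracklayer::export(out, path, format = "BED")
  invisible(path)
}

#' @rdname writeBed
#' @return `readBed`: a GRanges in 1-based fully-closed coordinates.
#' @export
readBed <- function(path) {
  rtracklayer::import(path, format = "BED")
}

#' Read / write a restriction-enzyme table
#'
#' TSV columns: `name`, `recognition` (IUPAC), `cut_offset`.
#'
#' @param path file path.
#' @return `readEnzymeTable`: a list of [RestrictionEnzyme-class] objects.
#' @export
readEnzymeTable <- function(path) {
  df <- .readTsv(path)
  need <- c("name", "recognition", "cut_offset")
  if (!all(need %in% colnames(df)))
    stop("enzyme TSV needs columns: ", paste(need, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i)
    restrictionEnzyme(df$name[i], df$recognition[i], df$cut_offset[i]))
}

#' @rdname readEnzymeTable
#' @param enzymes list of [RestrictionEnzyme-class] objects.
#' @export
writeEnzymeTable <- function(enzymes, path) {
  df <- data.frame(name = vapply(enzymes, slot, "", "name"),
    recognition = vapply(enzymes, slot, "", "recognition"),
    cut_offset = vapply(enzymes, function(e) e@cutOffset, 0L))
  .writeTsv(df, path, "tufscan restriction enzymes")
}

#' Read PRT assay definitions
#'
#' Expects the Table-1-style layout shipped at
#' `system.file("extdata", "prt_assays.tsv", package = "tufscan")`:
#' one row per amplicon with columns `id`, `role` (test / reference /
#' probe), `chrom`, `start`, `end`, `length_bp`, `type` (TUF / Non-TUF)
#' and primer sequences.
#'
#' @param path file path; defaults to the shipped table.
#' @return a data.frame of amplicon records.
#' @export
readPrtAssays <- function(path = system.file("extdata", "prt_assays.tsv",
                                             package = "tufscan")) {
  df <- .readTsv(path)
  need <- c("id", "role", "chrom", "start", "end", "length_bp", "type")
  if (!all(need %in% colnames(df)))
    stop("PRT assay TSV needs columns: ", paste(need, collapse = ", "))
  df
}

#' Read / write PRT readouts
#'
#' TSV columns: `sample_id`, `assay_id`, `replicate`, `ratio`.
#'
#' @param path file path.
#' @export
readPrtReadouts <- function(path) {
  df <- .readTsv(path)
  need <- c("sample_id", "assay_id", "replicate", "ratio")
  if (!all(need %in% colnames(df)))
    stop("PRT readout TSV needs columns: ", paste(need, collapse = ", "))
  if (any(df$ratio < 0)) stop("ratios must be >= 0")
  df
}

#' @rdname readPrtReadouts
#' @param readouts data.frame of readouts.
#' @export
writePrtReadouts <- function(readouts, path) {
  .writeTsv(readouts, path, "tufscan PRT readouts")
}
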