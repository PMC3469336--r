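## Sequence and interval plumbing: coordinate arithmetic, multi-scale
## GC/CpG window content, extreme-GC element discovery, restriction sites.

#' Construct a validated 1-based fully-closed genomic interval
#'
#' All user-facing coordinates in tufscan are 1-based and fully closed
#' (both endpoints included), the convention under which
#' `length = end - start + 1`. BED files are converted on I/O
#' (see [writeBed()] / [readBed()]).
#'
#' @param chrom chromosome name (non-empty).
#' @param start,end 1-based inclusive positions, `end >= start >= 1`.
#' @param label optional name.
#' @return a [GenomicRanges::GRanges] of length `length(start)`.
#' @export
genomicInterval <- function(chrom, start, end, label = NULL) {
  if (any(!nzchar(chrom))) stop("chrom must be non-empty")
  if (any(start < 1)) stop("start must be >= 1")
  if (any(end < start)) stop("end must be >= start")
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  if (!is.null(label)) names(gr) <- label
  gr
}

#' Length of a 1-based fully-closed interval
#'
#' @param x a [GenomicRanges::GRanges], or a data.frame with `start` and
#'   `end` columns in the fully-closed convention.
#' @return integer vector of lengths in bp (`end - start + 1`).
#' @examples
#' intervalLength(genomicInterval("chr2", 241151005, 241151733)) # 729
#' @export
intervalLength <- function(x) {
  if (is(x, "GRanges")) return(GenomicRanges::width(x))
  if (is.data.frame(x)) {
    if (!all(c("start", "end") %in% colnames(x)))
      stop("data.frame input needs 'start' and 'end' columns")
    if (any(x$start < 1) || any(x$end < x$start))
      stop("invalid interval: need 1 <= start <= end")
    return(as.integer(x$end - x$start + 1))
  }
  stop("x must be a GRanges or a data.frame")
}

## Coerce any supported sequence input to a plain character string.
.asSeqString <- function(sequence) {
  if (is(sequence, "DNAStringSet")) {
    if (length(sequence) != 1L)
      stop("expected a single sequence; subset the DNAStringSet first")
    sequence <- sequence[[1L]]
  }
  if (is(sequence, "DNAString")) sequence <- as.character(sequence)
  if (!is.character(sequence) || length(sequence) != 1L)
    stop("sequence must be a single DNAString/character string")
  toupper(sequence)
}

## Per-position indicator profiles with prepended-zero cumsums, so any
## window count is two lookups. Ambiguous bases count in neither
## numerator nor denominator.
.seqProfiles <- function(sequence) {
  s <- .asSeqString(sequence)
  r <- charToRaw(s)
  L <- length(r)
  isG <- r == charToRaw("G")
  isC <- r == charToRaw("C")
  unamb <- isG | isC | r == charToRaw("A") | r == charToRaw("T")
  gc <- isG | isC
  cg <- if (L > 1L) isC[-L] & isG[-1L] else logical(0)
  list(L = L,
       csGC = c(0, cumsum(gc)),
       csU = c(0, cumsum(unamb)),
       csCG = c(0, cumsum(cg)),
       gcMask = gc)
}

## Window content for vectors of centers against precomputed profiles.
.windowContentAt <- function(prof, centers, windowSize, metric) {
  L <- prof$L
  h <- floor(windowSize / 2)
  if (any(centers < 1L | centers > L))
    stop("window center outside sequence (centers must lie in [1, ",
         L, "])")
  a <- pmax(1L, centers - h)
  b <- pmin(L, centers + h)
  eff <- prof$csU[b + 1L] - prof$csU[a]
  if (metric == "GC") {
    num <- prof$csGC[b + 1L] - prof$csGC[a]
    out <- ifelse(eff > 0, num / eff, NA_real_)
  } else {
    hi <- pmax(a, b) # dinucleotide slots span a..(b-1)
    num <- ifelse(b > a, prof$csCG[b] - prof$csCG[a], 0)
    out <- ifelse(eff > 1, num / (eff - 1), NA_real_)
  }
  out
}

#' GC or CpG fraction of a window centered on a genomic position
#'
#' The window spans `center - floor(w/2) .. center + floor(w/2)` and is
#' clipped to the available sequence at contig ends; the effective
#' (clipped, unambiguous) length is used as the denominator. The GC
#' fraction is `(#G + #C) / effective length`; the CpG fraction is the
#' number of CG dinucleotides divided by the number of dinucleotide slots
#' (`effective length - 1`). Ambiguous bases (N and other IUPAC codes)
#' are excluded from numerator and denominator; a window with no
#' unambiguous sequence yields `NA`.
#'
#' @param sequence a DNAString, single-sequence DNAStringSet or character.
#' @param center 1-based position(s) within the sequence.
#' @param windowSize window size in bp (`>= 2`).
#' @param metric `"GC"` or `"CpG"`.
#' @return numeric fraction(s) in `[0, 1]`, `NA` where undefined.
#' @export
windowContent <- function(sequence, center, windowSize,
                          metric = c("GC", "CpG")) {
  metric <- match.arg(metric)
  if (windowSize < 2) stop("windowSize must be >= 2")
  prof <- .seqProfiles(sequence)
  .windowContentAt(prof, as.integer(center), windowSize, metric)
}

#' Multi-scale GC/CpG content matrix for a probe manifest
#'
#' For each probe of the manifest and each window size, computes the GC
#' and CpG fraction of the window centered on the probe position (see
#' [windowContent()] for edge and ambiguity conventions). The default
#' window list spans 50 bp to 1 Mb.
#'
#' @param fasta a named [Biostrings::DNAStringSet] or path to a FASTA file.
#' @param manifest data.frame with columns `probe_id`, `chrom`, `pos`,
#'   sorted by (chrom, pos) with unique probe ids.
#' @param windowSizes integer vector of window sizes in bp.
#' @return a [WindowContentMatrix].
#' @export
buildContentMatrix <- function(fasta, manifest,
    windowSizes = c(50L, 100L, 500L, 1000L, 10000L, 50000L, 100000L,
                    250000L, 1000000L)) {
  seqs <- .asGenome(fasta)
  manifest <- validateManifest(manifest)
  windowSizes <- as.integer(windowSizes)
  metrics <- c("GC", "CpG")
  nterm <- length(windowSizes) * length(metrics)
  out <- matrix(NA_real_, nrow = nrow(manifest), ncol = nterm,
                dimnames = list(manifest$probe_id,
                  paste0(rep(metrics, each = length(windowSizes)), "_w",
                         rep(windowSizes, times = length(metrics)))))
  for (chr in unique(manifest$chrom)) {
    idx <- which(manifest$chrom == chr)
    if (!chr %in% names(seqs))
      stop("chromosome '", chr, "' (probe ", manifest$probe_id[idx[1L]],
           ") not present in the FASTA")
    prof <- .seqProfiles(seqs[[chr]])
    centers <- as.integer(manifest$pos[idx])
    for (m in metrics) for (w in windowSizes)
      out[idx, paste0(m, "_w", w)] <- .windowContentAt(prof, centers, w, m)
  }
  new("WindowContentMatrix", content = out, windows = windowSizes,
      metrics = metrics)
}

.asGenome <- function(fasta) {
  if (is.character(fasta) && length(fasta) == 1L && file.exists(fasta))
    fasta <- Biostrings::readDNAStringSet(fasta)
  if (is(fasta, "DNAStringSet")) {
    names(fasta) <- sub("\\s.*$", "", names(fasta))
    return(fasta)
  }
  stop("fasta must be a DNAStringSet or a path to a FASTA file")
}

#' Validate a probe manifest
#'
#' @param manifest data.frame with `probe_id`, `chrom`, `pos`.
#' @return the manifest, with basic invariants enforced.
#' @export
validateManifest <- function(manifest) {
  need <- c("probe_id", "chrom", "pos")
  if (!all(need %in% colnames(manifest)))
    stop("manifest needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(manifest$probe_id))
    stop("probe ids must be unique")
  ord <- order(manifest$chrom, manifest$pos)
  if (!identical(ord, seq_len(nrow(manifest))))
    stop("manifest must be sorted by (chrom, pos)")
  manifest
}

#' Discover extreme-GC sequence elements
#'
#' Slides windows of width `minLength` every `step` bp, keeps windows with
#' GC fraction `>= minGc`, merges qualifying windows (and merged runs
#' separated by gaps smaller than `step`), then refines boundaries by
#' trimming terminal non-GC bases and greedily extending over adjacent
#' G/C bases. Elements shorter than `minLength` after refinement are
#' dropped. The defaults (500 bp at 70% GC) are calibrated so that a
#' ~1 kb element of ~73% GC on a 40% GC background — the archetypal
#' anchoring element observed upstream of a poorly amplifying test
#' amplicon — is recovered with boundaries within one step.
#'
#' @param sequence a DNAString / single-sequence DNAStringSet / character.
#' @param minLength minimum element length in bp.
#' @param minGc minimum GC fraction in `(0, 1]`.
#' @param step window stride in bp.
#' @param chrom chromosome name for the output ranges (defaults to the
#'   sequence name, or `"chr1"`).
#' @return a [GenomicRanges::GRanges] of non-overlapping elements, sorted,
#'   with metadata columns `gc_fraction` and `length_bp`.
#' @export
findGcElements <- function(sequence, minLength = 500L, minGc = 0.70,
                           step = 50L, chrom = NULL) {
  if (minGc <= 0 || minGc > 1) stop("minGc must lie in (0, 1]")
  if (is.null(chrom))
    chrom <- if (is(sequence, "DNAStringSet") && !is.null(names(sequence)))
      names(sequence)[1L] else "chr1"
  prof <- .seqProfiles(sequence)
  L <- prof$L
  if (L < minLength) stop("sequence shorter than minLength")
  starts <- seq.int(1L, L - minLength + 1L, by = step)
  ends <- starts + minLength - 1L
  eff <- prof$csU[ends + 1L] - prof$csU[starts]
  gc <- ifelse(eff > 0, (prof$csGC[ends + 1L] - prof$csGC[starts]) / eff,
               NA_real_)
  keep <- which(!is.na(gc) & gc >= minGc)
  if (!length(keep)) return(.emptyElements(chrom))
  cand <- IRanges::reduce(IRanges::IRanges(starts[keep], ends[keep]),
                          min.gapwidth = step)
  s <- IRanges::start(cand); e <- IRanges::end(cand)
  mask <- prof$gcMask
  for (i in seq_along(s)) {
    while (s[i] <= e[i] && !mask[s[i]]) s[i] <- s[i] + 1L
    while (e[i] >= s[i] && !mask[e[i]]) e[i] <- e[i] - 1L
    while (s[i] > 1L && mask[s[i] - 1L]) s[i] <- s[i] - 1L
    while (e[i] < L && mask[e[i] + 1L]) e[i] <- e[i] + 1L
  }
  w <- e - s + 1L
  ok <- w >= minLength
  if (!any(ok)) return(.emptyElements(chrom))
  s <- s[ok]; e <- e[ok]
  effR <- prof$csU[e + 1L] - prof$csU[s]
  gcR <- (prof$csGC[e + 1L] - prof$csGC[s]) / effR
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(s, e),
                               gc_fraction = gcR, length_bp = e - s + 1L)
  sort(gr)
}

.emptyElements <- function(chrom) {
  gr <- GenomicRanges::GRanges()
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(gc_fraction = numeric(0),
                                               length_bp = integer(0))
  gr
}

#' Map restriction sites on the forward strand
#'
#' Finds every (possibly overlapping) forward-strand match of the
#' enzyme's IUPAC recognition sequence and reports cut positions as
#' `match start + cutOffset` — the first base of the downstream fragment.
#' The enzymes shipped with the package are palindromic, so
#' forward-strand matching locates every genomic site.
#'
#' @param sequence a DNAString / single-sequence DNAStringSet / character.
#' @param enzyme a [RestrictionEnzyme-class] object.
#' @return sorted integer vector of cut positions (possibly empty).
#' @export
findRestrictionSites <- function(sequence, enzyme) {
  stopifnot(is(enzyme, "RestrictionEnzyme"))
  validObject(enzyme)
  subject <- Biostrings::DNAString(.asSeqString(sequence))
  m <- Biostrings::matchPattern(enzyme@recognition, subject, fixed = FALSE)
  sort(Biostrings::start(m) + enzyme@cutOffset)
}

#' GC fraction of explicit amplicon intervals
#'
#' Utility for summarizing amplicon GC content (e.g. mean GC of PRT test
#' versus reference amplicons, given a reference genome FASTA).
#'
#' @param fasta a named [Biostrings::DNAStringSet] or FASTA path.
#' @param intervals data.frame with `chrom`, `start`, `end` (1-based,
#'   fully closed).
#' @return numeric vector of per-interval GC fractions.
#' @export
ampliconGc <- function(fasta, intervals) {
  seqs <- .asGenome(fasta)
  vapply(seq_len(nrow(intervals)), function(i) {
    chr <- intervals$chrom[i]
    if (!chr %in% names(seqs))
      stop("chromosome '", chr, "' not present in the FASTA")
    prof <- .seqProfiles(Biostrings::subseq(seqs[[chr]],
      start = intervals$start[i], end = intervals$end[i]))
    eff <- prof$csU[prof$L + 1L]
    if (eff == 0) return(NA_real_)
    prof$csGC[prof$L + 1L] / eff
  }, numeric(1))
}
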