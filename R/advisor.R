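## Fragmentation advisor: which treatments physically separate a target
## amplicon from its anchoring extreme-GC element, and what test:reference
## ratio the suppression model predicts afterwards. Amplification is
## problematic only while the target shares a DNA fragment with the
## element; a digest that cuts between them restores the ratio to the
## equal-efficiency maximum rEq, while a cut inside the target destroys
## the assay outright (the amplicon itself is cleaved).

.gapDistance <- function(aStart, aEnd, bStart, bEnd) {
  if (bStart > aEnd) bStart - aEnd
  else if (aStart > bEnd) aStart - bEnd
  else 0
}

#' Evaluate restriction digests for separating a target from its element
#'
#' For each enzyme: computes forward-strand cut positions on the target's
#' chromosome, flags the assay destroyed when any cut falls inside the
#' target, otherwise reports the target separated when at least one cut
#' lies strictly between the target's proximal boundary and the nearest
#' element's proximal boundary. The predicted post-treatment ratio is
#' `rEq` when separated and `rEq * (1 - min(A, 1) * exp(-rho * d))`
#' otherwise, with `d` the target-element gap. Separation is evaluated on
#' linear chromosome coordinates against the nearest element only.
#'
#' @param target a single [GenomicRanges::GRanges] interval (the test
#'   amplicon).
#' @param elements [GenomicRanges::GRanges] of extreme-GC elements.
#' @param enzymes list of [RestrictionEnzyme-class] objects.
#' @param sequence genome sequence holding the target's chromosome
#'   (named [Biostrings::DNAStringSet], single sequence, or character).
#' @param A,rho suppression amplitude and nick rate of the sample.
#' @param rEq equal-efficiency ratio.
#' @param dMax context window for counting nearby cuts (tie-break in
#'   [rankTreatments()]).
#' @return data.frame (enzyme, status, separated, n_cuts_inside,
#'   nearest_cut_between, distance, predicted_ratio). `status` is one of
#'   `"separated"`, `"linked"`, `"assay_destroyed"`, `"inseparable"`
#'   (target overlaps an element) or `"no_element"`.
#' @export
adviseDigest <- function(target, elements, enzymes, sequence,
                         A = 0.8, rho = 2e-4, rEq = 1.43, dMax = 50000) {
  stopifnot(is(target, "GRanges"), length(target) == 1L)
  chr <- as.character(GenomicRanges::seqnames(target))
  if (is(sequence, "DNAStringSet") && length(sequence) > 1L) {
    if (!chr %in% names(sequence))
      stop("target chromosome '", chr, "' not in sequence")
    sequence <- sequence[chr]
  }
  ts <- GenomicRanges::start(target); te <- GenomicRanges::end(target)
  onChr <- elements[as.character(GenomicRanges::seqnames(elements)) == chr]
  overlap <- length(onChr) &&
    any(GenomicRanges::start(onChr) <= te & GenomicRanges::end(onChr) >= ts)
  nearest <- NULL
  if (length(onChr) && !overlap) {
    gaps <- vapply(seq_along(onChr), function(j)
      .gapDistance(ts, te, GenomicRanges::start(onChr)[j],
                   GenomicRanges::end(onChr)[j]), 0)
    nearest <- onChr[which.min(gaps)]
  }
  rows <- lapply(enzymes, function(enz) {
    cuts <- findRestrictionSites(sequence, enz)
    inside <- cuts[cuts > ts & cuts <= te]
    nearCuts <- sum(cuts >= ts - dMax & cuts <= te + dMax)
    base <- data.frame(enzyme = enz@name, status = NA_character_,
      separated = FALSE, n_cuts_inside = length(inside),
      n_cuts_context = nearCuts, nearest_cut_between = NA_real_,
      distance = NA_real_, predicted_ratio = NA_real_,
      stringsAsFactors = FALSE)
    if (overlap) { base$status <- "inseparable"; return(base) }
    if (length(inside)) { base$status <- "assay_destroyed"; return(base) }
    if (is.null(nearest)) {
      base$status <- "no_element"
      base$predicted_ratio <- rEq
      return(base)
    }
    es <- GenomicRanges::start(nearest); ee <- GenomicRanges::end(nearest)
    d <- .gapDistance(ts, te, es, ee)
    base$distance <- d
    if (ee < ts) { # element left of target
      between <- cuts[cuts > ee & cuts <= ts]
    } else {       # element right of target
      between <- cuts[cuts > te & cuts <= es]
    }
    if (length(between)) {
      base$status <- "separated"
      base$separated <- TRUE
      prox <- if (ee < ts) ts else te
      base$nearest_cut_between <- between[which.min(abs(between - prox))]
      base$predicted_ratio <- rEq
    } else {
      base$status <- "linked"
      base$predicted_ratio <- rEq * (1 - min(A, 1) * exp(-rho * d))
    }
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank fragmentation treatments by predicted amplification restoration
#'
#' Orders digest verdicts (and, optionally, a sonication analogue) by
#' predicted test:reference ratio, descending. The sonication row's
#' expected ratio applies the Poisson no-break linkage probability
#' `exp(-d / meanFragment)` to the suppression term. Destroyed /
#' inseparable assays sink to the bottom; ties break by fewer cuts in
#' the `dMax` context, then by input order (deterministic).
#'
#' @param verdicts output of [adviseDigest()].
#' @param sonicationMeanFragment optional mean fragment size (bp) to add
#'   a sonication analogue row.
#' @param A,rho,rEq suppression model parameters (match the verdicts).
#' @return the verdict table with a `treatment` column, ordered by
#'   decreasing predicted ratio, plus a `rank` column.
#' @export
rankTreatments <- function(verdicts, sonicationMeanFragment = NULL,
                           A = 0.8, rho = 2e-4, rEq = 1.43) {
  if (!nrow(verdicts)) stop("need at least one verdict")
  out <- cbind(treatment = paste0("digest_", verdicts$enzyme), verdicts,
               stringsAsFactors = FALSE)
  if (!is.null(sonicationMeanFragment)) {
    d <- suppressWarnings(min(verdicts$distance, na.rm = TRUE))
    if (!is.finite(d)) d <- NA_real_
    ratio <- if (is.na(d)) rEq else
      rEq * (1 - min(A, 1) * exp(-rho * d) * exp(-d / sonicationMeanFragment))
    son <- data.frame(treatment = "sonication",
      enzyme = NA_character_, status = "sonicated", separated = NA,
      n_cuts_inside = 0L, n_cuts_context = 0L,
      nearest_cut_between = NA_real_, distance = d,
      predicted_ratio = ratio, stringsAsFactors = FALSE)
    out <- rbind(out, son)
  }
  sortKey <- ifelse(is.na(out$predicted_ratio), -Inf, out$predicted_ratio)
  ord <- order(-sortKey, out$n_cuts_context, seq_len(nrow(out)))
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
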