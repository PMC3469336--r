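## Weak-signal-region detection, probe susceptibility annotation, and
## nick-rate estimation from the suppression-versus-distance decay.

#' Threshold LRR values into signal-strength copy-number classes
#'
#' A one-threshold classifier mirroring the two discrete intensity rows
#' seen in weak-signal plots: probes at or below `cn1Threshold` read as
#' apparent copy number 1 (weak signal), the rest as 2.
#'
#' @param lrr numeric vector or probes x samples matrix of LRR values.
#' @param cn1Threshold LRR at or below which a probe is called CN 1.
#' @return integer vector/matrix of calls in `{1, 2}`.
#' @export
inferCopyNumber <- function(lrr, cn1Threshold = -0.3) {
  if (!all(is.finite(lrr))) stop("lrr must be finite")
  out <- ifelse(lrr <= cn1Threshold, 1L, 2L)
  if (is.matrix(lrr)) dimnames(out) <- dimnames(lrr)
  out
}

#' Detect weak-signal regions shared across affected samples
#'
#' Scans each chromosome for maximal runs of consecutive probes at which
#' the fraction of affected samples calling copy number 1 is at least
#' `minSampleFraction`, keeping runs of at least `minRun` probes. Region
#' boundaries are the first and last probe positions of the run. The
#' result is invariant to sample order.
#'
#' @param calls probes x samples integer matrix of CN calls (from
#'   [inferCopyNumber()]); columns restricted to affected samples by
#'   `affectedSamples`.
#' @param manifest probe manifest matching the call rows.
#' @param affectedSamples optional character vector of column names.
#' @param minRun minimum run length in probes.
#' @param minSampleFraction minimum supporting sample fraction.
#' @return [GenomicRanges::GRanges] with `n_probes` and `support`
#'   metadata (mean supporting fraction over the run).
#' @export
detectWeakRegions <- function(calls, manifest, affectedSamples = NULL,
                              minRun = 5L, minSampleFraction = 0.5) {
  manifest <- validateManifest(manifest)
  if (!is.matrix(calls)) calls <- matrix(calls, ncol = 1L)
  if (nrow(calls) != nrow(manifest))
    stop("calls rows must match the manifest")
  if (!is.null(affectedSamples)) {
    missing <- setdiff(affectedSamples, colnames(calls))
    if (length(missing))
      stop("affected samples not in calls: ",
           paste(missing, collapse = ", "))
    calls <- calls[, affectedSamples, drop = FALSE]
  }
  if (ncol(calls) == 0L) {
    warning("no affected samples; returning no regions")
    return(GenomicRanges::GRanges())
  }
  frac <- rowMeans(calls == 1L)
  hits <- frac >= minSampleFraction
  regions <- list()
  for (chr in unique(manifest$chrom)) {
    idx <- which(manifest$chrom == chr)
    r <- rle(hits[idx])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values & r$lengths >= minRun)
    for (j in keep) {
      probes <- idx[starts[j]:ends[j]]
      regions[[length(regions) + 1L]] <- GenomicRanges::GRanges(chr,
        IRanges::IRanges(manifest$pos[probes[1L]],
                         manifest$pos[probes[length(probes)]]),
        n_probes = length(probes), support = mean(frac[probes]))
    }
  }
  if (!length(regions)) return(GenomicRanges::GRanges())
  sort(do.call(c, regions))
}

#' Annotate each probe with its distance to the nearest element
#'
#' Distance is the gap in bp between the probe position and the proximal
#' boundary of the nearest element on the same chromosome (0 inside an
#' element), the scale on which the nick-mediated suppression decays.
#' Probes with no element within `dMax` get the `Inf` sentinel.
#'
#' @param manifest probe manifest data.frame.
#' @param elements [GenomicRanges::GRanges] of elements.
#' @param dMax susceptibility range in bp.
#' @return data.frame (probe_id, distance, susceptible,
#'   nearest_boundary). `nearest_boundary` is the coordinate of the
#'   proximal element boundary (NA when none).
#' @export
annotateSusceptibility <- function(manifest, elements, dMax = 50000) {
  manifest <- validateManifest(manifest)
  n <- nrow(manifest)
  distance <- rep(Inf, n)
  boundary <- rep(NA_real_, n)
  if (length(elements)) {
    echr <- as.character(GenomicRanges::seqnames(elements))
    es <- GenomicRanges::start(elements)
    ee <- GenomicRanges::end(elements)
    for (j in seq_along(es)) {
      idx <- which(manifest$chrom == echr[j])
      if (!length(idx)) next
      p <- manifest$pos[idx]
      d <- ifelse(p < es[j], es[j] - p, ifelse(p > ee[j], p - ee[j], 0))
      b <- ifelse(p < es[j], es[j], ifelse(p > ee[j], ee[j], p))
      upd <- d < distance[idx]
      distance[idx[upd]] <- d[upd]
      boundary[idx[upd]] <- b[upd]
    }
  }
  far <- distance > dMax
  distance[far] <- Inf
  boundary[far] <- NA_real_
  data.frame(probe_id = manifest$probe_id, distance = distance,
             susceptible = is.finite(distance),
             nearest_boundary = boundary, stringsAsFactors = FALSE)
}

#' Estimate suppression amplitude and nick rate from distance decay
#'
#' Fits `delta = A * exp(-rho * d)` to the observed per-probe
#' suppression `delta` (baseline-minus-observed LRR, positive where
#' signal is lost) against distance-to-element `d`. Distances are
#' grouped into equal-count bins (default 10, fewer when fewer distinct
#' distances exist) and bin-mean suppression is fitted against bin-mean
#' distance by Levenberg-Marquardt least squares, initialized from a
#' log-linear fit on the positive bins.
#'
#' @param delta numeric vector of per-probe suppression values.
#' @param d numeric vector of distances (bp); `Inf` rows are dropped.
#' @param nbins number of distance bins.
#' @return list with `A`, `rho`, `seA`, `seRho`, `converged`, and the
#'   binned data (`bins`). When all suppressions are ~0, `A = 0` and
#'   `rho = NA` (flagged by `converged = FALSE`).
#' @export
estimateNickRate <- function(delta, d, nbins = 10L) {
  keep <- is.finite(d) & is.finite(delta)
  delta <- delta[keep]; d <- d[keep]
  if (length(d) < 20L)
    stop("need at least 20 susceptible probes (finite distance)")
  if (length(unique(d)) < 2L)
    stop("need at least 2 distinct distances")
  nbins <- min(nbins, length(unique(d)))
  if (length(unique(d)) <= nbins) {
    grp <- match(d, sort(unique(d)))
  } else {
    br <- unique(quantile(d, probs = seq(0, 1, length.out = nbins + 1L)))
    grp <- cut(d, breaks = br, include.lowest = TRUE, labels = FALSE)
  }
  bd <- tapply(d, grp, mean)
  by <- tapply(delta, grp, mean)
  bins <- data.frame(d = as.numeric(bd), delta = as.numeric(by),
                     n = as.numeric(table(grp)))
  if (max(bins$delta) < 1e-8)
    return(list(A = 0, rho = NA_real_, seA = NA_real_, seRho = NA_real_,
                converged = FALSE, bins = bins))
  pos <- bins[bins$delta > 0, , drop = FALSE]
  if (nrow(pos) >= 2L) {
    ll <- lm(log(delta) ~ d, data = pos)
    A0 <- unname(exp(coef(ll)[1L]))
    rho0 <- unname(max(-coef(ll)[2L], 1e-12))
  } else {
    A0 <- max(bins$delta)
    rho0 <- 1 / max(mean(bins$d), 1)
  }
  fit <- try(minpack.lm::nlsLM(delta ~ A * exp(-rho * d), data = bins,
    start = list(A = A0, rho = rho0), lower = c(0, 0),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error"))
    stop("exponential-decay fit failed to converge; binned data:\n",
         paste(utils::capture.output(print(bins)), collapse = "\n"))
  est <- coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  list(A = unname(est["A"]), rho = unname(est["rho"]),
       seA = unname(se["A"]), seRho = unname(se["rho"]),
       converged = TRUE, bins = bins)
}

#' Per-probe suppression relative to the unsusceptible baseline
#'
#' Convenience for [estimateNickRate()]: suppression is the median LRR
#' of unsusceptible probes (distance `Inf`) minus each probe's LRR, so
#' signal loss is positive.
#'
#' @param lrr one sample's per-probe LRR values.
#' @param distance per-probe distances from [annotateSusceptibility()].
#' @return numeric vector of suppression values.
#' @export
probeSuppression <- function(lrr, distance) {
  if (length(lrr) != length(distance))
    stop("lrr and distance lengths differ")
  base <- median(lrr[!is.finite(distance)])
  if (!is.finite(base))
    stop("no unsusceptible probes to define the baseline")
  base - lrr
}
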