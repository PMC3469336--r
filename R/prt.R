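## PRT ratio computation and the association between per-sample wave
## statistics and PRT performance, reported in the Table-2-style layout
## (rows = window sizes; Pearson and Spearman p-values for GC and CpG).

#' Test:reference PRT product ratio
#'
#' @param testPeakHeight,refPeakHeight positive peak heights (gel
#'   densitometry units).
#' @return numeric ratio(s) `test / ref`.
#' @export
prtRatio <- function(testPeakHeight, refPeakHeight) {
  if (any(testPeakHeight <= 0) || any(refPeakHeight <= 0))
    stop("peak heights must be > 0")
  testPeakHeight / refPeakHeight
}

#' Summarize replicate PRT ratios
#'
#' Mean with the maximum and minimum as the error-bar convention.
#'
#' @param ratios numeric vector of replicate ratios.
#' @return named numeric `c(mean, min, max)`.
#' @export
summarizeReplicates <- function(ratios) {
  if (!length(ratios)) stop("no replicates")
  c(mean = mean(ratios), min = min(ratios), max = max(ratios))
}

## All permutations of 1..n (n! rows); used for exact Spearman p-values.
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

.spearmanRho <- function(x, y) {
  cor(rank(x), rank(y))
}

#' Association between a per-sample statistic and PRT ratios
#'
#' Pearson: two-sided t-approximation p-value for the product-moment
#' correlation. Spearman: rank correlation with the t-approximation,
#' replaced by exact enumeration of all n! rank permutations when
#' `n <= exactMax`. Permutation: Monte-Carlo two-sided p for the Pearson
#' correlation under random pairing.
#'
#' @param x,y paired numeric vectors (`n >= 4`, non-constant for the
#'   correlation methods).
#' @param method `"pearson"`, `"spearman"` or `"permutation"`.
#' @param nPerm Monte-Carlo permutation count.
#' @param seed seed for the Monte-Carlo permutations.
#' @param exactMax largest n for exact Spearman enumeration.
#' @return the p-value.
#' @export
testAssociation <- function(x, y,
    method = c("pearson", "spearman", "permutation"),
    nPerm = 10000L, seed = NULL, exactMax = 8L) {
  method <- match.arg(method)
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("need at least 4 paired observations")
  if (sd(x) == 0 || sd(y) == 0)
    stop("constant input; correlation undefined")
  if (method == "pearson")
    return(cor.test(x, y)$p.value)
  if (method == "spearman") {
    rho <- .spearmanRho(x, y)
    if (n <= exactMax) {
      perms <- .permutations(n)
      ry <- rank(y)
      rhos <- apply(perms, 1L, function(p) cor(rank(x), ry[p]))
      return(mean(abs(rhos) >= abs(rho) - 1e-12))
    }
    if (abs(rho) >= 1) return(0)
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    return(2 * pt(-abs(tstat), df = n - 2))
  }
  if (!is.null(seed)) set.seed(seed)
  obs <- abs(cor(x, y))
  hits <- sum(vapply(seq_len(nPerm), function(i)
    abs(cor(x, sample(y))) >= obs - 1e-12, logical(1)))
  (1 + hits) / (nPerm + 1)
}

#' Table-2-style association report
#'
#' For every (metric, window) cell, takes each sample's wave-regression
#' statistic (that term's Z score by default, or the signed proportion
#' of variance explained) and tests its association with the per-sample
#' PRT ratio by Pearson and Spearman correlation. Rows are ordered from
#' the largest to the smallest window.
#'
#' @param models named list of [CorrectionModel-class] objects.
#' @param readouts data.frame with `sample_id` and `ratio` (replicates,
#'   if present, are averaged per sample).
#' @param windows window sizes to report (default: the models' windows).
#' @param metrics metrics to report.
#' @param degree which polynomial degree's term supplies the statistic.
#' @param statistic `"z"` or `"signed_r2"` (proportion of variance
#'   explained, signed by the selected term's coefficient).
#' @param path optional TSV output path.
#' @return data.frame (window, gc_correlation_p, gc_spearman_p,
#'   cpg_correlation_p, cpg_spearman_p).
#' @export
table2Report <- function(models, readouts, windows = NULL,
    metrics = c("GC", "CpG"), degree = 1L,
    statistic = c("z", "signed_r2"), path = NULL) {
  statistic <- match.arg(statistic)
  ratios <- tapply(readouts$ratio, readouts$sample_id, mean)
  ids <- vapply(models, slot, "", "sample")
  missing <- setdiff(ids, names(ratios))
  if (length(missing))
    stop("no PRT readout for sample(s): ", paste(missing, collapse = ", "))
  ratio <- as.numeric(ratios[ids])
  if (is.null(windows)) windows <- models[[1L]]@windows
  windows <- sort(as.integer(windows), decreasing = TRUE)
  stat <- function(m, metric, w) {
    tt <- m@terms
    row <- tt[!is.na(tt$metric) & tt$metric == metric &
              tt$window == w & tt$degree == degree, , drop = FALSE]
    if (!nrow(row) || row$aliased[1L]) return(NA_real_)
    if (statistic == "z") row$z[1L]
    else sign(row$estimate[1L]) * varianceExplained(m)
  }
  out <- data.frame(window = windows)
  for (metric in metrics) {
    pear <- spear <- rep(NA_real_, length(windows))
    for (i in seq_along(windows)) {
      v <- vapply(models, stat, 0, metric, windows[i])
      pear[i] <- testAssociation(v, ratio, "pearson")
      spear[i] <- testAssociation(v, ratio, "spearman")
    }
    pre <- if (metric == "GC") "gc" else "cpg"
    out[[paste0(pre, "_correlation_p")]] <- pear
    out[[paste0(pre, "_spearman_p")]] <- spear
  }
  if (!is.null(path)) .writeTsv(out, path, "tufscan association report")
  out
}

#' @rdname table2Report
#' @export
readAssociationReport <- function(path) .readTsv(path)
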