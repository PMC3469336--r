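## Per-sample multi-window polynomial GC/CpG wave regression of the LRR,
## with within-chip rescaling (stratum) terms:
##
##   LRR_i = b0 + sum_k gamma_k * 1[stratum(i) = k]
##         + sum_m sum_w sum_p beta[m,w,p] * (x[m,w,i] - center[m,w])^p
##         + e_i
##
## estimated by OLS separately for every sample, because the wave
## amplitude and sign are sample properties (DNA intactness and input
## concentration). Covariates are centered before polynomial expansion to
## limit collinearity between degrees; rank-deficient designs drop
## aliased terms with a warning.

#' Quantile-normalize an LRR matrix across samples
#'
#' Every sample (column) is mapped onto the reference distribution formed
#' by the mean of the sorted columns; ties receive the average of the
#' reference values they span. Column distributions are identical
#' afterwards.
#'
#' @param x a probes x samples numeric matrix, or a [TufCohort-class]
#'   (whose `lrr` assay is replaced).
#' @return an object of the same class as `x`.
#' @export
setGeneric("quantileNormalize", function(x) standardGeneric("quantileNormalize"))

#' @rdname quantileNormalize
#' @export
setMethod("quantileNormalize", "matrix", function(x) {
  if (ncol(x) < 2L) stop("need at least 2 samples")
  if (anyNA(x))
    stop("missing values present; impute upstream before normalization")
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
})

#' @rdname quantileNormalize
#' @export
setMethod("quantileNormalize", "TufCohort", function(x) {
  SummarizedExperiment::assay(x, "lrr") <-
    quantileNormalize(lrrMatrix(x))
  x
})

## Build the regression design. `centers` NULL => center at the sample's
## own covariate means (fitting); supplying stored centers reproduces a
## fitted design (correction).
.waveDesign <- function(content, strata = NULL, degree = 2L,
                        centers = NULL, strataLevels = NULL) {
  if (is(content, "WindowContentMatrix")) {
    cm <- contentMatrix(content)
    metrics <- content@metrics
    windows <- content@windows
  } else {
    cm <- as.matrix(content)
    parts <- strsplit(colnames(cm), "_w")
    metrics <- unique(vapply(parts, `[`, "", 1L))
    windows <- unique(as.integer(vapply(parts, `[`, "", 2L)))
  }
  if (anyNA(cm))
    stop("content matrix contains NA; drop or impute those probes first")
  n <- nrow(cm)
  degree <- as.integer(degree)
  if (degree < 1L) stop("degree must be >= 1")
  if (is.null(centers)) centers <- colMeans(cm)
  if (is.null(strata)) strata <- factor(rep("s1", n))
  strata <- as.factor(strata)
  if (is.null(strataLevels)) strataLevels <- levels(droplevels(strata))
  else if (!all(levels(droplevels(strata)) %in% strataLevels))
    stop("stratum labels not seen when the model was fitted: ",
         paste(setdiff(levels(droplevels(strata)), strataLevels),
               collapse = ", "))
  cols <- list(`(Intercept)` = rep(1, n))
  info <- data.frame(term = "(Intercept)", metric = NA_character_,
                     window = NA_integer_, degree = NA_integer_)
  for (lev in strataLevels[-1L]) {
    cols[[paste0("stratum", lev)]] <- as.numeric(strata == lev)
    info <- rbind(info, data.frame(term = paste0("stratum", lev),
      metric = NA_character_, window = NA_integer_, degree = NA_integer_))
  }
  for (m in metrics) for (w in windows) {
    cname <- paste0(m, "_w", w)
    x <- cm[, cname] - centers[cname]
    for (p in seq_len(degree)) {
      tname <- paste0(cname, "_p", p)
      cols[[tname]] <- x^p
      info <- rbind(info, data.frame(term = tname, metric = m,
        window = as.integer(w), degree = p))
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  list(X = X, centers = centers, strataLevels = strataLevels,
       info = info, metrics = metrics, windows = as.integer(windows),
       degree = degree)
}

#' Fit the per-sample GC/CpG wave regression
#'
#' Ordinary least squares of one sample's LRR values on centered
#' polynomial GC/CpG terms for every content window, plus within-chip
#' stratum indicator offsets and an intercept. Each term's Z score is
#' its coefficient divided by its standard error; a sample whose largest
#' GC-window |Z| exceeds ~30 is an extreme-wave sample (see
#' [classifyExtremeSamples()]).
#'
#' @param lrr numeric vector of one sample's per-probe LRR values.
#' @param content a [WindowContentMatrix] (rows matching `lrr`).
#' @param strata per-probe chip-stratum labels (or NULL for none).
#' @param degree polynomial degree (default 2).
#' @param sample sample identifier stored in the model.
#' @return a [CorrectionModel-class].
#' @export
fitWaveModel <- function(lrr, content, strata = NULL, degree = 2L,
                         sample = "sample") {
  lrr <- as.numeric(lrr)
  if (!all(is.finite(lrr))) stop("lrr must be finite")
  d <- .waveDesign(content, strata, degree)
  X <- d$X
  n <- length(lrr)
  if (n != nrow(X)) stop("lrr length must match content rows")
  k <- ncol(X)
  if (n <= k + 1L)
    stop("too few probes (", n, ") for ", k, " model terms")
  if (n < 10L * k)
    warning("fewer than 10 probes per model term (", n, " for ", k,
            "); estimates may be unstable")
  fit <- lm(lrr ~ X - 1)
  cf <- coef(fit)
  names(cf) <- sub("^X", "", names(cf))
  aliased <- is.na(cf)
  if (any(aliased))
    warning("dropping aliased (rank-deficient) terms: ",
            paste(names(cf)[aliased], collapse = ", "))
  sm <- summary(fit)$coefficients
  rownames(sm) <- sub("^X", "", rownames(sm))
  terms <- d$info
  terms$estimate <- cf[terms$term]
  terms$se <- sm[, "Std. Error"][terms$term]
  terms$z <- terms$estimate / terms$se
  terms$aliased <- aliased[terms$term]
  rownames(terms) <- NULL
  res <- residuals(fit)
  mdl <- new("CorrectionModel", sample = as.character(sample),
    terms = terms, coefficients = cf, centers = d$centers,
    degree = d$degree, windows = d$windows, metrics = d$metrics,
    strataLevels = d$strataLevels,
    variancePre = var(lrr), variancePost = var(res))
  validObject(mdl)
  mdl
}

#' Fit wave models for every sample of a cohort
#'
#' @param cohort a [TufCohort-class].
#' @param content a [WindowContentMatrix].
#' @param degree polynomial degree.
#' @return named list of [CorrectionModel-class] objects.
#' @export
fitCohortModels <- function(cohort, content, degree = 2L) {
  lrr <- lrrMatrix(cohort)
  strata <- probeStrata(cohort)
  setNames(lapply(colnames(lrr), function(s)
    fitWaveModel(lrr[, s], content, strata, degree, sample = s)),
    colnames(lrr))
}

#' Re-compute corrected LRR values from a fitted wave model
#'
#' Residuals of the wave regression, re-centered to the sample's
#' pre-correction mean so the corrected values stay on the LRR scale.
#' On the data the model was fitted to, `var(corrected) <= var(input)`.
#'
#' @param model a [CorrectionModel-class].
#' @param lrr numeric vector of LRR values.
#' @param content a [WindowContentMatrix] compatible with the model.
#' @param strata per-probe stratum labels (or NULL).
#' @return numeric vector of corrected LRR values.
#' @export
correctLrr <- function(model, lrr, content, strata = NULL) {
  d <- .waveDesign(content, strata, model@degree,
                   centers = model@centers,
                   strataLevels = model@strataLevels)
  if (!identical(colnames(d$X), names(model@coefficients)))
    stop("design mismatch: content/strata differ from the fitted model")
  beta <- model@coefficients
  beta[is.na(beta)] <- 0
  resid <- as.numeric(lrr - d$X %*% beta)
  resid - mean(resid) + mean(lrr)
}

#' @rdname correctLrr
#' @param models named list of models (one per cohort sample).
#' @param cohort a [TufCohort-class].
#' @return `correctCohort`: the cohort with a corrected `lrr` assay.
#' @export
correctCohort <- function(models, cohort, content) {
  lrr <- lrrMatrix(cohort)
  strata <- probeStrata(cohort)
  for (s in colnames(lrr))
    lrr[, s] <- correctLrr(models[[s]], lrr[, s], content, strata)
  SummarizedExperiment::assay(cohort, "lrr") <- lrr
  cohort
}

#' Pre- versus post-correction LRR variance per sample
#'
#' One row per sample: the LRR variance before and after wave
#' correction, their ratio, and the proportion of variance explained —
#' the scatter-ready summary of how much of each sample's intensity
#' variance the GC/CpG waves account for.
#'
#' @param models named list of [CorrectionModel-class] objects.
#' @param path optional TSV output path.
#' @return data.frame (sample, variance_pre, variance_post,
#'   variance_ratio, prop_explained).
#' @export
varianceReport <- function(models, path = NULL) {
  df <- data.frame(
    sample = vapply(models, slot, "", "sample"),
    variance_pre = vapply(models, slot, 0, "variancePre"),
    variance_post = vapply(models, slot, 0, "variancePost"),
    row.names = NULL, stringsAsFactors = FALSE)
  df$variance_ratio <- df$variance_post / df$variance_pre
  df$prop_explained <- 1 - df$variance_ratio
  if (!is.null(path)) .writeTsv(df, path, "tufscan variance report")
  df
}

#' Classify samples as extreme-wave positive / negative / null
#'
#' The per-sample statistic is the largest-|Z| GC window term (degree 1
#' by default, so the sign carries the wave direction): a sample is
#' `positive` if that Z exceeds `zThreshold`, `negative` below
#' `-zThreshold`, otherwise `null`. The selected term and Z are recorded.
#'
#' @param models named list of [CorrectionModel-class] objects.
#' @param zThreshold classification threshold (default 30).
#' @param metric which metric's terms enter the selector.
#' @param degrees which polynomial degrees enter the selector.
#' @return data.frame (sample, label, term, z).
#' @export
classifyExtremeSamples <- function(models, zThreshold = 30,
                                   metric = "GC", degrees = 1L) {
  rows <- lapply(models, function(m) {
    tt <- m@terms
    tt <- tt[!is.na(tt$metric) & tt$metric == metric &
             tt$degree %in% degrees & !tt$aliased, , drop = FALSE]
    if (!nrow(tt))
      return(data.frame(sample = m@sample, label = "null",
                        term = NA_character_, z = NA_real_))
    i <- which.max(abs(tt$z))
    z <- tt$z[i]
    label <- if (z > zThreshold) "positive"
             else if (z < -zThreshold) "negative" else "null"
    data.frame(sample = m@sample, label = label, term = tt$term[i], z = z)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
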