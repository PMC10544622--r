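#' Onset latency by baseline-band crossing
#'
#' The onset latency is the time of the first sample at/after `cutoffMs`
#' whose deviation from the baseline mean exceeds `thresholdSds` baseline
#' standard deviations; baseline mean and SD are computed on the final
#' `baselineMs` of the window (where no signal is expected).  Returns `NA`
#' if the signal never leaves the baseline band.  With a zero baseline SD
#' the threshold degenerates to the first nonzero deviation from the
#' baseline mean.
#'
#' @param samples numeric vector, one window (any length covering at least
#'   `baselineMs`).
#' @param samplingRate sampling rate in Hz.
#' @param cutoffMs search start time in ms (0 for artifact-free segments).
#' @param baselineMs length of the terminal baseline segment in ms.
#' @param thresholdSds threshold in baseline SDs.
#' @return onset time in ms relative to the start of `samples`, or `NA`.
#' @examples
#' x <- numeric(2000); x[700:800] <- 1
#' onsetLatency(x, cutoffMs = 17.5)
#' @export
onsetLatency <- function(samples, samplingRate = 20000, cutoffMs = 17.5,
                         baselineMs = 20, thresholdSds = 2) {
    dtMs <- 1000 / samplingRate
    n <- length(samples)
    nBase <- round(baselineMs / dtMs)
    if (n < nBase) stop("trace shorter than the baseline segment")
    base <- samples[(n - nBase + 1):n]
    mu <- mean(base)
    sdev <- stats::sd(base)
    from <- round(cutoffMs / dtMs) + 1
    if (from > n) stop("cutoffMs lies outside the window")
    dev <- abs(samples[from:n] - mu)
    hit <- which(dev > thresholdSds * sdev)
    if (!length(hit)) return(NA_real_)
    (from - 1 + hit[1] - 1) * dtMs
}

#' End of signal: onset latency of the time-reversed trace
#'
#' The end of the signal is defined through the onset latency of the
#' time-reversed trace, mapped back to forward time: the last time the
#' signal exceeds the band set by the reversed trace's terminal baseline.
#' Returns `NA` when no crossing exists.
#'
#' @inheritParams onsetLatency
#' @return end-of-signal time in ms relative to the start of `samples`, or
#'   `NA`.
#' @export
endOfSignal <- function(samples, samplingRate = 20000, baselineMs = 20,
                        thresholdSds = 2) {
    rev_onset <- onsetLatency(rev(samples), samplingRate, cutoffMs = 0,
                              baselineMs = baselineMs,
                              thresholdSds = thresholdSds)
    if (is.na(rev_onset)) return(NA_real_)
    (length(samples) - 1) * 1000 / samplingRate - rev_onset
}

#' Peak-to-peak amplitude
#'
#' Absolute difference between the maximum and the minimum of the signal.
#'
#' @param samples numeric vector.
#' @return `max(samples) - min(samples)` (always >= 0).
#' @examples
#' peakAmplitude(c(-0.3, 0.1, 0.6))
#' @export
peakAmplitude <- function(samples) {
    if (!length(samples)) stop("empty trace")
    max(samples) - min(samples)
}

#' Rectified area under the curve
#'
#' Trapezoidal integral of the rectified signal, in signal units times ms.
#'
#' @inheritParams onsetLatency
#' @return the AUC (>= 0).
#' @export
traceAuc <- function(samples, samplingRate = 20000) {
    if (length(samples) < 2) stop("trace too short")
    a <- abs(samples)
    dtMs <- 1000 / samplingRate
    sum((a[-1] + a[-length(a)]) / 2) * dtMs
}

#' Extract the 7-dimensional feature representation of a cohort
#'
#' For every trace of a preselected cohort computes: onset latency, peak
#' latency (latency of the first detected peak), end of signal (onset
#' latency of the time-reversed trace mapped back to forward time), maximum,
#' minimum, rectified AUC, and number of detected peaks.  Latencies are
#' reported stimulus-relative (ms from the start of the original window;
#' the preselected segment starts at the artifact cutoff).  Undefined onset
#' latencies are imputed with the segment start and undefined ends of signal
#' with the window end; imputations are counted in the `imputed` attribute.
#'
#' @param cohort a preselected [MEPCohort-class].
#' @param prominenceSds peak-prominence threshold in trace SDs.
#' @return a data.frame with the 7 feature columns `onset_latency_ms`,
#'   `peak_latency_ms`, `end_of_signal_ms`, `maximum`, `minimum`, `auc`,
#'   `n_peaks`, plus `muscle`, `patient_id`, `trace_id`.
#' @examples
#' cfg <- generatorConfig(nPatients = 2, tracesPerPatient = c(APB = 8))
#' pre <- preselectCohort(generateCohort(cfg))
#' head(extractFeatures(normalizePatients(pre$accepted)))
#' @export
extractFeatures <- function(cohort, prominenceSds = 2) {
    stopifnot(methods::is(cohort, "MEPCohort"))
    if (!isPreselected(cohort))
        stop("features are extracted from preselected traces")
    sig <- signalMatrix(cohort)
    fs <- samplingRate(cohort)
    offset <- S4Vectors::metadata(cohort)$cutoff_ms
    if (is.null(offset)) offset <- 17.5
    endMs <- offset + (nrow(sig) - 1) * 1000 / fs
    cd <- SummarizedExperiment::colData(cohort)
    stored <- all(c("n_peaks", "peak_latency_ms") %in% colnames(cd))
    nImputed <- 0L
    one <- function(j) {
        x <- sig[, j]
        if (stored) {            # preselection record (full-window peaks)
            pkLat <- cd$peak_latency_ms[j]
            npk <- cd$n_peaks[j]
        } else {
            pk <- detectPeaks(x, samplingRate = fs, cutoffMs = 0,
                              prominenceSds = prominenceSds)
            pkLat <- if (nrow(pk)) offset + pk$time_ms[1] else NA_real_
            npk <- nrow(pk)
        }
        onset <- onsetLatency(x, fs, cutoffMs = 0)
        eos <- endOfSignal(x, fs)
        if (is.na(onset)) { onset <- 0; nImputed <<- nImputed + 1L }
        if (is.na(eos)) { eos <- endMs - offset; nImputed <<- nImputed + 1L }
        c(onset_latency_ms = offset + onset,
          peak_latency_ms = if (is.na(pkLat)) offset + onset else pkLat,
          end_of_signal_ms = offset + eos,
          maximum = max(x), minimum = min(x),
          auc = traceAuc(x, fs), n_peaks = npk)
    }
    ft <- as.data.frame(t(vapply(seq_len(ncol(sig)), one, numeric(7))))
    ft$muscle <- as.character(muscle(cohort))
    ft$patient_id <- patientId(cohort)
    ft$trace_id <- traceId(cohort)
    rownames(ft) <- NULL
    attr(ft, "imputed") <- nImputed
    ft
}

#' Names of the 7 engineered features
#' @return character vector of the feature column names, in order.
#' @export
featureNames <- function() {
    c("onset_latency_ms", "peak_latency_ms", "end_of_signal_ms",
      "maximum", "minimum", "auc", "n_peaks")
}

#' Fit a PCA compression model
#'
#' Mean-centred principal component analysis retaining the smallest number
#' of components whose cumulative explained variance reaches `varTarget`.
#' Fit on training rows only; apply to held-out data with [applyPca()].
#'
#' @param x numeric matrix, rows = samples (traces), columns = dimensions.
#' @param varTarget explained-variance target (default 0.95).
#' @return an [MEPPca-class] model.
#' @examples
#' m <- fitPca(matrix(rnorm(200), 20, 10))
#' m@nComponents
#' @export
fitPca <- function(x, varTarget = 0.95) {
    x <- as.matrix(x)
    if (nrow(x) < 2) stop("need at least 2 rows to fit a PCA")
    pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
    v <- pc$sdev^2
    if (sum(v) == 0)
        return(methods::new("MEPPca",
                            rotation = matrix(0, ncol(x), 0),
                            center = pc$center, varExplained = numeric(0),
                            nComponents = 0L, varTarget = varTarget))
    ve <- v / sum(v)
    k <- which(cumsum(ve) >= varTarget - 1e-12)[1]
    methods::new("MEPPca", rotation = pc$rotation[, seq_len(k), drop = FALSE],
                 center = pc$center, varExplained = ve,
                 nComponents = as.integer(k), varTarget = varTarget)
}

#' @param model an [MEPPca-class] model from [fitPca()].
#' @rdname fitPca
#' @export
applyPca <- function(model, x) {
    stopifnot(methods::is(model, "MEPPca"))
    if (model@nComponents == 0L)
        stop("PCA model has zero components (zero-variance fit data)")
    x <- as.matrix(x)
    if (ncol(x) != length(model@center))
        stop("dimension mismatch between model and data")
    sweep(x, 2, model@center) %*% model@rotation
}
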