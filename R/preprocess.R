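#' Detect peaks on the rectified signal after the artifact cutoff
#'
#' Peaks are local maxima of the rectified (absolute-value) signal at or
#' after `cutoffMs`, with topographic prominence exceeding `prominenceSds`
#' times the standard deviation of the rectified post-cutoff segment.  Both
#' polarities therefore count, and the stimulation-artifact train before the
#' cutoff does not influence the threshold (local maxima are found on the
#' whole rectified trace, so a peak exactly at the cutoff sample is still
#' eligible, but only peaks at/after the cutoff are reported).  For a
#' constant post-cutoff segment (SD 0) no peaks are returned.  Plateau
#' maxima are assigned to the leftmost sample of the plateau.
#'
#' @param samples numeric vector, one recording window.
#' @param samplingRate sampling rate in Hz.
#' @param cutoffMs artifact cutoff in ms (peaks only at/after this time).
#' @param prominenceSds prominence threshold in units of the segment SD.
#' @return a data.frame with columns `index` (0-based, on the input trace),
#'   `time_ms`, `height` (rectified) and `prominence`, ordered by time.
#' @examples
#' x <- numeric(2000); x[701] <- 1  # single pulse at 35 ms
#' detectPeaks(x)
#' @export
detectPeaks <- function(samples, samplingRate = 20000, cutoffMs = 17.5,
                        prominenceSds = 2) {
    stopifnot(is.numeric(samples), length(samples) > 2)
    if (cutoffMs < 0 || cutoffMs * samplingRate / 1000 >= length(samples))
        stop("cutoffMs must lie inside the window")
    dtMs <- 1000 / samplingRate
    cut <- round(cutoffMs / dtMs)
    rect <- abs(samples)
    sdSeg <- stats::sd(rect[(cut + 1):length(samples)])
    empty <- data.frame(index = integer(), time_ms = numeric(),
                        height = numeric(), prominence = numeric())
    if (!is.finite(sdSeg) || sdSeg == 0) return(empty)
    pk <- .findPeaksC(rect)
    keep <- pk$index >= cut & pk$prominence > prominenceSds * sdSeg
    if (!any(keep)) return(empty)
    idx <- pk$index[keep]
    data.frame(index = idx, time_ms = idx * dtMs,
               height = pk$height[keep], prominence = pk$prominence[keep])
}

#' Preselect a single recording window
#'
#' Applies the MEP gate: a window is assumed to contain an MEP if at least
#' one and no more than `maxPeaks` peaks are detected (see [detectPeaks()]).
#' Accepted windows are cut to the post-cutoff segment (the first
#' `cutoffMs` worth of samples -- the stimulation-artifact train -- is
#' removed, leaving 1650 samples under the defaults).
#'
#' @inheritParams detectPeaks
#' @param maxPeaks largest admissible peak count.
#' @param expectedLength required input length (2000 under the defaults);
#'   set to `NULL` to skip the check.
#' @return a list: `accepted` (logical), `samples` (post-cutoff segment if
#'   accepted, else `NULL`), `peaks` (the [detectPeaks()] table), `nPeaks`,
#'   and `reason` (`NA`, `"no_peaks"` or `"too_many_peaks"`).
#' @examples
#' x <- numeric(2000); x[701] <- 1
#' preselectTrace(x)$accepted
#' @export
preselectTrace <- function(samples, samplingRate = 20000, cutoffMs = 17.5,
                           prominenceSds = 2, maxPeaks = 10,
                           expectedLength = 2000) {
    if (!is.null(expectedLength) && length(samples) != expectedLength)
        stop("expected a window of ", expectedLength, " samples, got ",
             length(samples))
    pk <- detectPeaks(samples, samplingRate, cutoffMs, prominenceSds)
    np <- nrow(pk)
    accepted <- np >= 1 && np <= maxPeaks
    cut <- round(cutoffMs * samplingRate / 1000)
    list(accepted = accepted,
         samples = if (accepted) samples[(cut + 1):length(samples)],
         peaks = pk, nPeaks = np,
         reason = if (accepted) NA_character_
                  else if (np == 0) "no_peaks" else "too_many_peaks")
}

#' Preselect a cohort
#'
#' Runs [preselectTrace()] over every window of a raw cohort.  Accepted
#' traces are returned as a new, shorter-window [MEPCohort-class] (the
#' artifact segment removed; 1650 samples under the defaults) whose colData
#' additionally records `n_peaks` and `peak_latency_ms` (first detected
#' peak, stimulus-relative).  Rejected traces are listed with their reason.
#'
#' @param cohort a raw [MEPCohort-class].
#' @inheritParams preselectTrace
#' @return a list with `accepted` (an [MEPCohort-class]) and `rejections`
#'   (data.frame: `trace_id`, `muscle`, `patient_id`, `reason`).
#' @examples
#' cfg <- generatorConfig(nPatients = 2, tracesPerPatient = c(EXT = 5))
#' pre <- preselectCohort(generateCohort(cfg))
#' ncol(pre$accepted); nrow(pre$rejections)
#' @export
preselectCohort <- function(cohort, cutoffMs = 17.5, prominenceSds = 2,
                            maxPeaks = 10) {
    stopifnot(methods::is(cohort, "MEPCohort"))
    if (isPreselected(cohort)) stop("cohort is already preselected")
    fs <- samplingRate(cohort)
    nIn <- round(windowMs(cohort) * fs / 1000)
    sig <- signalMatrix(cohort)
    if (nrow(sig) != nIn)
        stop("signal matrix does not match the declared window geometry")
    cut <- round(cutoffMs * fs / 1000)
    res <- lapply(seq_len(ncol(sig)), function(j)
        preselectTrace(sig[, j], fs, cutoffMs, prominenceSds, maxPeaks,
                       expectedLength = nIn))
    acc <- vapply(res, `[[`, logical(1), "accepted")
    cd <- SummarizedExperiment::colData(cohort)
    rejections <- data.frame(
        trace_id = cd$trace_id[!acc],
        muscle = as.character(cd$muscle[!acc]),
        patient_id = cd$patient_id[!acc],
        reason = vapply(res[!acc], `[[`, character(1), "reason"))
    keep <- which(acc)
    out <- MEPCohort(sig[(cut + 1):nIn, keep, drop = FALSE],
                     muscle = as.character(cd$muscle[keep]),
                     patientId = cd$patient_id[keep],
                     traceId = cd$trace_id[keep],
                     truthHasMep = cd$truth_has_mep[keep],
                     samplingRate = fs,
                     windowMs = windowMs(cohort) - cutoffMs,
                     preselected = TRUE,
                     config = S4Vectors::metadata(cohort)$config)
    SummarizedExperiment::colData(out)$n_peaks <-
        vapply(res[keep], `[[`, numeric(1), "nPeaks")
    SummarizedExperiment::colData(out)$peak_latency_ms <-
        vapply(res[keep], function(r) r$peaks$time_ms[1], numeric(1))
    S4Vectors::metadata(out)$cutoff_ms <- cutoffMs
    list(accepted = out, rejections = rejections)
}

#' Normalize traces by each patient's largest rectified peak
#'
#' Divides every sample of every accepted trace by that patient's
#' normalization denominator: the maximum absolute sample value over all of
#' the patient's accepted traces (across muscles).  After normalization, the
#' largest rectified sample of each patient equals exactly 1.
#'
#' @param cohort a preselected [MEPCohort-class].
#' @return the normalized [MEPCohort-class].
#' @examples
#' cfg <- generatorConfig(nPatients = 2, tracesPerPatient = c(APB = 10))
#' pre <- preselectCohort(generateCohort(cfg))
#' norm <- normalizePatients(pre$accepted)
#' max(abs(signalMatrix(norm)))
#' @export
normalizePatients <- function(cohort) {
    stopifnot(methods::is(cohort, "MEPCohort"))
    if (!isPreselected(cohort))
        stop("normalization operates on preselected traces only")
    if (isNormalized(cohort)) return(cohort)
    sig <- signalMatrix(cohort)
    pid <- patientId(cohort)
    denominators <- numeric(0)
    for (p in unique(pid)) {
        cols <- which(pid == p)
        d <- max(abs(sig[, cols, drop = FALSE]))
        if (d == 0)
            stop("degenerate patient ", p, ": all-zero accepted traces")
        sig[, cols] <- sig[, cols, drop = FALSE] / d
        denominators[p] <- d
    }
    SummarizedExperiment::assay(cohort, "signal") <- sig
    S4Vectors::metadata(cohort)$normalized <- TRUE
    S4Vectors::metadata(cohort)$normalization_denominators <- denominators
    cohort
}
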