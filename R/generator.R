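#' Default per-muscle generator parameters
#'
#' One row per muscle with the waveform, latency, amplitude, blank-rate and
#' per-patient trace-count settings of the synthetic cohort generator.
#' Columns:
#' \describe{
#'   \item{ampMean, ampSd}{mean/SD of the raw (pre-normalization)
#'     peak-to-peak amplitude distribution, a moment-matched lognormal.
#'     Values are calibrated by large-n simulation so that the
#'     post-preselection, per-patient-normalized amplitude means reproduce
#'     the reference cohort summary (EXT 0.09, APB 0.34, TA 0.20,
#'     AH 0.11).}
#'   \item{ampCapSds}{saturation point of the amplitude distribution, in
#'     log-SDs above the log-mean (draws beyond it are clipped); sets the
#'     per-patient normalization denominator and hence the overall
#'     normalized-amplitude level.}
#'   \item{latTargetMs}{the target mean of the first-peak latency after
#'     preselection (17.53 / 20.01 / 24.69 / 31.03 ms).}
#'   \item{latMu, latSd, latMaxMs}{parameters of the underlying normal onset
#'     latency, truncated to `[17.5, latMaxMs]` ms; `latMu` is calibrated so
#'     the post-truncation mean of the measured first-peak latency equals
#'     `latTargetMs`.}
#'   \item{burstFreqHz, burstTauMs}{oscillation frequency and exponential
#'     decay constant of the damped-cosine burst waveform.}
#'   \item{burstP1, burstP2, burstP3}{probabilities of 1, 2 or 3 burst
#'     complexes per non-blank trace (sets the detected peak-count
#'     distribution; medians 1/2/2/2).}
#'   \item{gapMeanMs}{mean spacing between successive burst complexes.}
#'   \item{blankRate}{probability that a window contains no MEP; higher in
#'     the lower extremity, producing the class imbalance.}
#'   \item{tracesPerPatient}{windows generated per patient and muscle
#'     (echoing per-patient recording counts of 112/137/134/112).}
#' }
#'
#' @return a data.frame with one row per muscle.
#' @examples
#' muscleDefaults()
#' @export
muscleDefaults <- function() {
    data.frame(
        muscle = c("EXT", "APB", "TA", "AH"),
        ampMean = c(0.08298, 0.40072, 0.23524, 0.10665),
        ampSd = c(0.11058, 0.42430, 0.29400, 0.22307),
        ampCapSds = rep(1.91329, 4),
        latTargetMs = c(17.53, 20.01, 24.69, 31.03),
        latMu = c(14.8385, 19.1320, 24.3997, 31.0948),
        latSd = c(0.30, 2.20, 4.00, 6.50),
        latMaxMs = c(40, 55, 65, 75),
        burstFreqHz = c(350, 300, 250, 220),
        burstTauMs = c(0.45, 1.2, 1.4, 1.35),
        burstP1 = c(0.85, 0.60, 0.60, 0.60),
        burstP2 = c(0.15, 0.30, 0.30, 0.30),
        burstP3 = c(0.00, 0.10, 0.10, 0.10),
        gapMeanMs = c(5, 6, 6, 7),
        blankRate = c(0.02, 0.28263, 0.69277, 0.71327),
        tracesPerPatient = c(112, 137, 134, 112),
        stringsAsFactors = FALSE
    )
}

#' Construct a generator configuration
#'
#' Builds a validated [GeneratorConfig-class]. With no arguments this yields
#' the default study conditions: 36 patients, 100 ms / 2000-sample windows at
#' 20 kHz, a train of five alternating-sign stimulation-artifact pulses
#' before 17.5 ms, and the calibrated per-muscle settings of
#' [muscleDefaults()].
#'
#' @param samplingRate sampling rate in Hz.
#' @param windowMs window length in ms.
#' @param nPatients number of synthetic patients.
#' @param muscles per-muscle parameter table (defaults to
#'   [muscleDefaults()]).
#' @param tracesPerPatient optional named vector overriding per-muscle trace
#'   counts; muscles not named are dropped from the cohort (e.g.
#'   `c(EXT = 2)` generates EXT traces only).
#' @param blankRate optional named vector overriding per-muscle blank rates.
#' @param artifactPulses,artifactStartMs,artifactSpacingMs,artifactAmplitude
#'   stimulation-artifact train settings; all pulses must lie before 17.5 ms.
#' @param noiseSd baseline noise SD (raw units).
#' @param patientScaleSdLog log-SD of the per-patient lognormal gain.
#' @param seed integer seed; together with the config it fully determines a
#'   cohort.
#' @return a [GeneratorConfig-class] object.
#' @examples
#' generatorConfig(nPatients = 4, tracesPerPatient = c(EXT = 5, TA = 5))
#' @export
generatorConfig <- function(samplingRate = 20000, windowMs = 100,
                            nPatients = 36, muscles = muscleDefaults(),
                            tracesPerPatient = NULL, blankRate = NULL,
                            artifactPulses = 5, artifactStartMs = 2,
                            artifactSpacingMs = 2, artifactAmplitude = 3,
                            noiseSd = 0.001, patientScaleSdLog = 0.4,
                            seed = 1L) {
    if (samplingRate <= 0) stop("samplingRate must be positive")
    if (!is.null(tracesPerPatient)) {
        keep <- checkMuscle(names(tracesPerPatient))
        muscles <- muscles[match(keep, muscles$muscle), , drop = FALSE]
        muscles$tracesPerPatient <- as.numeric(tracesPerPatient)
    }
    if (!is.null(blankRate)) {
        nm <- checkMuscle(names(blankRate))
        muscles$blankRate[match(nm, muscles$muscle)] <- as.numeric(blankRate)
    }
    methods::new("GeneratorConfig", samplingRate = samplingRate,
                 windowMs = windowMs, nPatients = nPatients,
                 muscles = muscles, artifactPulses = artifactPulses,
                 artifactStartMs = artifactStartMs,
                 artifactSpacingMs = artifactSpacingMs,
                 artifactAmplitude = artifactAmplitude, noiseSd = noiseSd,
                 patientScaleSdLog = patientScaleSdLog,
                 seed = as.numeric(seed))
}

#' Derive a stage-specific seed from a global seed
#'
#' Expands one global seed into reproducible per-stage seeds so pipeline
#' stages can be rerun in isolation: `(seed * 97 + hash(stage)) mod (2^31-1)`
#' where `hash` sums the UTF-8 code points of the stage name.
#'
#' @param seed integer global seed.
#' @param stage character stage label.
#' @return an integer seed.
#' @examples
#' deriveSeed(1, "generate")
#' @export
deriveSeed <- function(seed, stage) {
    h <- sum(utf8ToInt(as.character(stage)))
    as.integer((as.numeric(seed) * 97 + h) %% 2147483647)
}

## Truncated-normal sampler, numerically stable for deep lower truncation
## (works in the upper tail so pnorm/qnorm never saturate at 1).
rtruncnorm <- function(n, mean, sd, lower, upper) {
    if (sd == 0) return(rep(pmin(pmax(mean, lower), upper), n))
    a <- (lower - mean) / sd
    b <- (upper - mean) / sd
    pa <- stats::pnorm(a, lower.tail = FALSE)
    pb <- stats::pnorm(b, lower.tail = FALSE)
    u <- stats::runif(n, pb, pa)
    mean + sd * stats::qnorm(u, lower.tail = FALSE)
}

## Damped-cosine burst starting (at its first peak) at sample index i0.
burstWave <- function(n, i0, freqHz, tauMs, dtMs) {
    u <- (seq_len(n) - 1 - i0) * dtMs
    w <- numeric(n)
    on <- u >= 0
    w[on] <- exp(-u[on] / tauMs) * cospi(2 * freqHz * u[on] / 1000)
    w
}

#' Generate one synthetic MEP recording window
#'
#' Produces a single 100 ms window: a train of alternating-sign stimulation
#' artifact pulses entirely before 17.5 ms, smoothed Gaussian baseline noise
#' everywhere, and -- unless the window is blank -- a complex of 1-3
#' damped-cosine bursts whose first peak lies at the drawn onset latency
#' (truncated below at 17.5 ms) and whose overall peak-to-peak size equals
#' the drawn amplitude times `patientGain`.
#'
#' Uses the current RNG state; callers seed it (see [generateCohort()]).
#'
#' @param muscle a muscle code present in `config@muscles`.
#' @param patientGain multiplicative per-patient gain.
#' @param config a [GeneratorConfig-class].
#' @param blank,latencyMs,amplitude,nBursts optional overrides of the random
#'   draws (used for inspection and testing).
#' @return a list with `samples` (numeric vector, one window), `hasMep`,
#'   `latencyMs` and `amplitude` (`NA` for blanks).
#' @examples
#' cfg <- generatorConfig()
#' set.seed(1)
#' tr <- generateTrace("APB", 1, cfg)
#' length(tr$samples)
#' @export
generateTrace <- function(muscle, patientGain = 1, config = generatorConfig(),
                          blank = NULL, latencyMs = NULL, amplitude = NULL,
                          nBursts = NULL) {
    muscle <- checkMuscle(muscle)
    if (length(muscle) != 1) stop("one muscle at a time")
    p <- config@muscles[match(muscle, config@muscles$muscle), ]
    if (nrow(p) != 1 || is.na(p$muscle))
        stop("muscle ", muscle, " not present in the generator config")
    fs <- config@samplingRate
    dtMs <- 1000 / fs
    n <- round(config@windowMs * fs / 1000)

    ## stimulation artifact train: narrow triangular alternating-sign spikes
    s <- numeric(n)
    for (k in seq_len(config@artifactPulses)) {
        ik <- round((config@artifactStartMs +
                     (k - 1) * config@artifactSpacingMs) / dtMs)
        sgn <- (-1)^(k - 1)
        span <- ik + (-1:1)
        ok <- span >= 0 & span < n
        s[span[ok] + 1] <- s[span[ok] + 1] +
            sgn * config@artifactAmplitude * c(0.5, 1, 0.5)[ok]
    }

    if (is.null(blank)) blank <- stats::runif(1) < p$blankRate
    lat <- NA_real_
    amp <- NA_real_
    if (!blank) {
        lat <- if (is.null(latencyMs))
            rtruncnorm(1, p$latMu, p$latSd, 17.5, p$latMaxMs) else latencyMs
        amp <- if (is.null(amplitude)) {
            ## lognormal moment-matched to (ampMean, ampSd), winsorized at
            ## ampCapSds log-SDs above the log-mean (amplitude saturation;
            ## stabilizes the per-patient normalization denominator)
            s2 <- log(1 + (p$ampSd / p$ampMean)^2)
            ml <- log(p$ampMean) - s2 / 2
            min(stats::rlnorm(1, ml, sqrt(s2)),
                exp(ml + p$ampCapSds * sqrt(s2)))
        } else amplitude
        nb <- if (is.null(nBursts))
            sample.int(3, 1, prob = c(p$burstP1, p$burstP2, p$burstP3))
        else nBursts
        complexWave <- numeric(n)
        L <- lat
        for (b in seq_len(nb)) {
            i0 <- round(L / dtMs)
            frac <- if (b == 1) 1 else stats::runif(1, 0.35, 0.7)
            complexWave <- complexWave +
                frac * burstWave(n, i0, p$burstFreqHz, p$burstTauMs, dtMs)
            L <- L + p$gapMeanMs * stats::runif(1, 0.7, 1.3)
        }
        ptp <- max(complexWave) - min(complexWave)
        if (ptp > 0) s <- s + complexWave * (amp / ptp)
    }

    if (config@noiseSd > 0) {
        raw <- stats::rnorm(n)
        sm <- (c(raw[1], raw[-n]) + raw + c(raw[-1], raw[n])) / 3
        s <- s + sm * config@noiseSd * sqrt(3)
    }

    list(samples = s * patientGain, hasMep = !blank, latencyMs = lat,
         amplitude = amp)
}

#' Generate a synthetic MEP cohort
#'
#' Deterministically expands a [GeneratorConfig-class] (including its seed)
#' into a full cohort: for each of `nPatients` patients a lognormal gain is
#' drawn, then `tracesPerPatient` windows are generated per muscle.
#'
#' @param config a [GeneratorConfig-class].
#' @param patientOffset integer added to patient numbers (useful when
#'   pooling several independently generated cohorts).
#' @return an [MEPCohort-class] with per-trace `muscle`, `patient_id` and
#'   ground-truth `truth_has_mep` labels.
#' @examples
#' cohort <- generateCohort(generatorConfig(nPatients = 2,
#'     tracesPerPatient = c(EXT = 3, AH = 2), seed = 7))
#' table(muscle(cohort))
#' @export
generateCohort <- function(config = generatorConfig(), patientOffset = 0) {
    if (config@nPatients < 2)
        stop("nPatients must be at least 2 (patient-wise split impossible)")
    set.seed(as.integer(config@seed %% 2147483647))
    fs <- config@samplingRate
    n <- round(config@windowMs * fs / 1000)
    m <- config@muscles
    perPatient <- sum(m$tracesPerPatient)
    total <- config@nPatients * perPatient
    sig <- matrix(0, nrow = n, ncol = total)
    musc <- character(total)
    pid <- character(total)
    tid <- character(total)
    hasMep <- logical(total)
    col <- 0L
    for (ptNum in seq_len(config@nPatients)) {
        gain <- stats::rlnorm(1, 0, config@patientScaleSdLog)
        ptLabel <- sprintf("P%03d", ptNum + patientOffset)
        for (mi in seq_len(nrow(m))) {
            for (r in seq_len(m$tracesPerPatient[mi])) {
                tr <- generateTrace(m$muscle[mi], gain, config)
                col <- col + 1L
                sig[, col] <- tr$samples
                musc[col] <- m$muscle[mi]
                pid[col] <- ptLabel
                tid[col] <- sprintf("%s_%s_%04d", ptLabel, m$muscle[mi], r)
                hasMep[col] <- tr$hasMep
            }
        }
    }
    MEPCohort(sig, muscle = musc, patientId = pid, traceId = tid,
              truthHasMep = hasMep, samplingRate = fs,
              windowMs = config@windowMs, config = config)
}

#' Summarize per-muscle MEP properties of a cohort
#'
#' Computes, per muscle, the mean/SD of the peak-to-peak amplitude, the
#' first-peak latency (ms, stimulus-relative), the rectified area under the
#' curve (units x ms), plus the median/SD of the detected peak count and the
#' trace count -- the summary layout used for cohort calibration.  Muscles
#' with no traces are reported with `n = 0` and `NA` statistics.
#'
#' @param cohort an [MEPCohort-class]; typically preselected and normalized.
#' @param prominenceSds peak-prominence threshold in trace SDs.
#' @return a data.frame with one row per muscle.
#' @examples
#' cfg <- generatorConfig(nPatients = 3, tracesPerPatient = c(APB = 30))
#' pre <- preselectCohort(generateCohort(cfg))
#' summarizeCohort(normalizePatients(pre$accepted))
#' @export
summarizeCohort <- function(cohort, prominenceSds = 2) {
    if (!methods::is(cohort, "MEPCohort") || ncol(cohort) == 0)
        stop("non-empty MEPCohort required")
    sig <- signalMatrix(cohort)
    fs <- samplingRate(cohort)
    offset <- if (isPreselected(cohort)) 17.5 else 0
    cutoff <- if (isPreselected(cohort)) 0 else 17.5
    cd <- SummarizedExperiment::colData(cohort)
    stored <- all(c("n_peaks", "peak_latency_ms") %in% colnames(cd))
    stats_one <- function(j) {
        x <- sig[, j]
        if (stored) {
            lat <- cd$peak_latency_ms[j]
            npk <- cd$n_peaks[j]
        } else {
            # fallback for cohorts without a preselection record; peaks on
            # the available window only (the pre-cutoff context is gone)
            pk <- detectPeaks(x, samplingRate = fs, cutoffMs = cutoff,
                              prominenceSds = prominenceSds)
            lat <- if (nrow(pk)) offset + pk$time_ms[1] else NA_real_
            npk <- nrow(pk)
        }
        c(amp = max(x) - min(x), lat = lat, npk = npk,
          auc = traceAuc(x, samplingRate = fs))
    }
    st <- t(vapply(seq_len(ncol(sig)), stats_one, numeric(4)))
    out <- lapply(muscleCodes(), function(mc) {
        sel <- muscle(cohort) == mc
        if (!any(sel))
            return(data.frame(muscle = mc, n = 0L, amp_mean = NA, amp_sd = NA,
                              peak_latency_mean = NA, peak_latency_sd = NA,
                              n_peaks_median = NA, n_peaks_sd = NA,
                              auc_mean = NA, auc_sd = NA))
        v <- st[sel, , drop = FALSE]
        sd0 <- function(z) {            # single observation: SD reported as 0
            z <- z[!is.na(z)]
            if (length(z) < 2) 0 else stats::sd(z)
        }
        data.frame(muscle = mc, n = sum(sel),
                   amp_mean = mean(v[, "amp"]), amp_sd = sd0(v[, "amp"]),
                   peak_latency_mean = mean(v[, "lat"], na.rm = TRUE),
                   peak_latency_sd = sd0(v[, "lat"]),
                   n_peaks_median = stats::median(v[, "npk"]),
                   n_peaks_sd = sd0(v[, "npk"]),
                   auc_mean = mean(v[, "auc"]), auc_sd = sd0(v[, "auc"]))
    })
    do.call(rbind, out)
}
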