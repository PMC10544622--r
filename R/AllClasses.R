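#' @import methods
#' @importFrom Rcpp evalCpp
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors metadata DataFrame
#' @importFrom stats predict
#' @useDynLib mepmuscle, .registration = TRUE
NULL

#' Muscle codes and extremity mapping
#'
#' The four routinely monitored muscles: extensor digitorum (EXT) and
#' abductor pollicis brevis (APB) on the upper extremity, tibialis anterior
#' (TA) and abductor hallucis (AH) on the lower extremity.
#'
#' @return `muscleCodes()` returns the four muscle codes in canonical order;
#'   `extremityOf()` maps muscle codes to `"UPPER"`/`"LOWER"`.
#' @examples
#' muscleCodes()
#' extremityOf(c("APB", "AH"))
#' @export
muscleCodes <- function() c("EXT", "APB", "TA", "AH")

#' @param muscle character vector of muscle codes.
#' @rdname muscleCodes
#' @export
extremityOf <- function(muscle) {
    muscle <- checkMuscle(muscle)
    ifelse(muscle %in% c("EXT", "APB"), "UPPER", "LOWER")
}

checkMuscle <- function(muscle) {
    muscle <- as.character(muscle)
    bad <- setdiff(unique(muscle), muscleCodes())
    if (length(bad))
        stop("unknown muscle code(s): ", paste(bad, collapse = ", "))
    muscle
}

#' MEPCohort: a cohort of fixed-length MEP recording windows
#'
#' An S4 container extending
#' [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' holding one assay `"signal"` (rows = time samples, columns = traces) plus
#' per-trace column metadata: `trace_id`, `patient_id`, `muscle`, and (for
#' synthetic cohorts) the ground-truth flag `truth_has_mep`.  Cohort-level
#' metadata records the sampling rate (Hz), the window length (ms) and the
#' processing state (`preselected`, `normalized`).
#'
#' @export
setClass("MEPCohort", contains = "SummarizedExperiment")

setValidity("MEPCohort", function(object) {
    msg <- character()
    md <- S4Vectors::metadata(object)
    cd <- SummarizedExperiment::colData(object)
    if (!"signal" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'signal' is required")
    need <- c("trace_id", "patient_id", "muscle")
    miss <- setdiff(need, colnames(cd))
    if (length(miss))
        msg <- c(msg, paste("missing colData column(s):",
                            paste(miss, collapse = ", ")))
    if (is.null(md$sampling_rate) || md$sampling_rate <= 0)
        msg <- c(msg, "metadata$sampling_rate must be a positive number")
    if (is.null(md$window_ms) || md$window_ms <= 0)
        msg <- c(msg, "metadata$window_ms must be a positive number")
    if ("muscle" %in% colnames(cd)) {
        bad <- setdiff(unique(as.character(cd$muscle)), muscleCodes())
        if (length(bad))
            msg <- c(msg, paste("unknown muscle code(s):",
                                paste(bad, collapse = ", ")))
    }
    if (length(msg)) msg else TRUE
})

#' Construct an MEPCohort
#'
#' @param signal numeric matrix, time samples in rows, traces in columns.
#' @param muscle character/factor vector of muscle codes, one per trace.
#' @param patientId vector of patient identifiers, one per trace.
#' @param traceId optional trace identifiers (defaults to `trace_1`, ...).
#' @param truthHasMep optional logical vector: synthetic ground truth for
#'   whether each window contains an MEP (`NA` for real recordings).
#' @param samplingRate sampling rate in Hz.
#' @param windowMs window length in milliseconds.
#' @param preselected,normalized processing-state flags.
#' @param config optional [GeneratorConfig-class] stored in the metadata.
#' @return an [MEPCohort-class] object.
#' @examples
#' sig <- matrix(rnorm(2000 * 3), nrow = 2000)
#' MEPCohort(sig, muscle = c("EXT", "APB", "TA"), patientId = c(1, 1, 2))
#' @export
MEPCohort <- function(signal, muscle, patientId, traceId = NULL,
                      truthHasMep = NULL, samplingRate = 20000,
                      windowMs = 100, preselected = FALSE,
                      normalized = FALSE, config = NULL) {
    signal <- as.matrix(signal)
    if (!all(is.finite(signal)))
        stop("signal matrix must contain finite values only")
    n <- ncol(signal)
    if (is.null(traceId)) traceId <- paste0("trace_", seq_len(n))
    if (is.null(truthHasMep)) truthHasMep <- rep(NA, n)
    cd <- S4Vectors::DataFrame(
        trace_id = as.character(traceId),
        patient_id = as.character(patientId),
        muscle = factor(checkMuscle(muscle), levels = muscleCodes()),
        truth_has_mep = as.logical(truthHasMep)
    )
    colnames(signal) <- cd$trace_id
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(signal = signal), colData = cd,
        metadata = list(sampling_rate = samplingRate, window_ms = windowMs,
                        preselected = preselected, normalized = normalized,
                        config = config))
    methods::new("MEPCohort", se)
}

#' GeneratorConfig: parameters of the synthetic MEP cohort generator
#'
#' Holds the full parameterization of a synthetic cohort: window geometry,
#' patient count, per-muscle waveform/latency/amplitude/blank-rate settings
#' (see [muscleDefaults()]), stimulation-artifact train, baseline noise and
#' the per-patient gain distribution.  A config plus its seed fully
#' determines a cohort.
#'
#' @slot samplingRate sampling rate in Hz (default 20000).
#' @slot windowMs window length in ms (default 100; 2000 samples).
#' @slot nPatients number of synthetic patients (default 36).
#' @slot muscles data.frame of per-muscle parameters, see [muscleDefaults()].
#' @slot artifactPulses number of stimulation-artifact pulses (default 5).
#' @slot artifactStartMs onset of the first artifact pulse (ms).
#' @slot artifactSpacingMs spacing between artifact pulses (ms).
#' @slot artifactAmplitude artifact pulse amplitude (raw units; larger than
#'   the MEP scale).
#' @slot noiseSd baseline noise standard deviation (raw units).
#' @slot patientScaleSdLog log-sd of the per-patient lognormal gain.
#' @slot seed integer seed.
#' @export
setClass("GeneratorConfig",
    representation(samplingRate = "numeric", windowMs = "numeric",
                   nPatients = "numeric", muscles = "data.frame",
                   artifactPulses = "numeric", artifactStartMs = "numeric",
                   artifactSpacingMs = "numeric",
                   artifactAmplitude = "numeric", noiseSd = "numeric",
                   patientScaleSdLog = "numeric", seed = "numeric"))

setValidity("GeneratorConfig", function(object) {
    msg <- character()
    if (object@samplingRate <= 0)
        msg <- c(msg, "samplingRate must be positive")
    if (object@windowMs <= 0)
        msg <- c(msg, "windowMs must be positive")
    ns <- object@windowMs * object@samplingRate / 1000
    if (abs(ns - round(ns)) > 1e-8)
        msg <- c(msg, "windowMs * samplingRate must give a whole number of samples")
    m <- object@muscles
    need <- c("muscle", "ampMean", "ampSd", "ampCapSds", "latMu", "latSd",
              "latMaxMs",
              "burstFreqHz", "burstTauMs", "burstP1", "burstP2", "burstP3",
              "gapMeanMs", "blankRate", "tracesPerPatient")
    miss <- setdiff(need, colnames(m))
    if (length(miss))
        msg <- c(msg, paste("muscles table missing column(s):",
                            paste(miss, collapse = ", ")))
    else {
        bad <- setdiff(m$muscle, muscleCodes())
        if (length(bad))
            msg <- c(msg, paste("unknown muscle code(s):",
                                paste(bad, collapse = ", ")))
        if (any(m$ampSd < 0) || any(m$latSd < 0))
            msg <- c(msg, "all SDs must be >= 0")
        if (any(m$blankRate < 0 | m$blankRate > 1))
            msg <- c(msg, "blankRate must lie in [0, 1]")
        p <- m$burstP1 + m$burstP2 + m$burstP3
        if (any(abs(p - 1) > 1e-8))
            msg <- c(msg, "burst-count probabilities must sum to 1")
    }
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
    art_end <- object@artifactStartMs +
        (object@artifactPulses - 1) * object@artifactSpacingMs
    if (art_end >= 17.5)
        msg <- c(msg, "all artifact pulses must lie before 17.5 ms")
    if (length(msg)) msg else TRUE
})

#' MEPPca: a fitted PCA compression model
#'
#' Mean-centred principal-component projection retaining the smallest number
#' of components whose cumulative explained variance reaches the target
#' fraction (default 0.95).
#'
#' @slot rotation loadings matrix (features x retained components).
#' @slot center training-data mean vector.
#' @slot varExplained per-component explained-variance fractions (all
#'   components of the fit, not only retained ones).
#' @slot nComponents number of retained components.
#' @slot varTarget the explained-variance target used at fit time.
#' @export
setClass("MEPPca",
    representation(rotation = "matrix", center = "numeric",
                   varExplained = "numeric", nComponents = "integer",
                   varTarget = "numeric"))

setValidity("MEPPca", function(object) {
    k <- object@nComponents
    if (k > 0 && sum(object@varExplained[seq_len(k)]) < object@varTarget - 1e-8)
        return("retained components do not reach the explained-variance target")
    TRUE
})

#' EvaluationReport: scores for one (algorithm, paradigm, representation) cell
#'
#' @slot algorithm one of `"RF"`, `"kNN"`, `"LogReg"`.
#' @slot paradigm one of `"FOUR_MUSCLE"`, `"EXT_vs_APB"`, `"EXT_vs_TA"`.
#' @slot representation one of `"RAW"`, `"PCA"`, `"FE"`.
#' @slot accuracy,f1Macro,rocAuc fractions in [0, 1].
#' @slot confusion confusion matrix of counts (rows = true class).
#' @slot tuned list of tuned hyperparameter values.
#' @slot aucScheme the multiclass ROC AUC convention used
#'   (`"macro one-vs-rest"`).
#' @export
setClass("EvaluationReport",
    representation(algorithm = "character", paradigm = "character",
                   representation = "character", accuracy = "numeric",
                   f1Macro = "numeric", rocAuc = "numeric",
                   confusion = "matrix", tuned = "list",
                   aucScheme = "character"))

setValidity("EvaluationReport", function(object) {
    msg <- character()
    v <- c(object@accuracy, object@f1Macro, object@rocAuc)
    if (any(!is.na(v) & (v < 0 | v > 1)))
        msg <- c(msg, "scores must lie in [0, 1]")
    cm <- object@confusion
    if (nrow(cm) != ncol(cm))
        msg <- c(msg, "confusion matrix must be square")
    if (sum(cm) > 0 &&
        !isTRUE(all.equal(object@accuracy, sum(diag(cm)) / sum(cm))))
        msg <- c(msg, "accuracy must equal trace/total of the confusion matrix")
    if (length(msg)) msg else TRUE
})
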