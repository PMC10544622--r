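#' @rdname MEPCohort-accessors
#' @export
setGeneric("muscle", function(x) standardGeneric("muscle"))

#' @rdname MEPCohort-accessors
#' @export
setGeneric("patientId", function(x) standardGeneric("patientId"))

#' @rdname MEPCohort-accessors
#' @export
setGeneric("traceId", function(x) standardGeneric("traceId"))

#' @rdname MEPCohort-accessors
#' @export
setGeneric("truthHasMep", function(x) standardGeneric("truthHasMep"))

#' @rdname MEPCohort-accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname MEPCohort-accessors
#' @export
setGeneric("windowMs", function(x) standardGeneric("windowMs"))

#' @rdname MEPCohort-accessors
#' @export
setGeneric("signalMatrix", function(x) standardGeneric("signalMatrix"))

#' @rdname MEPCohort-accessors
#' @export
setGeneric("isPreselected", function(x) standardGeneric("isPreselected"))

#' @rdname MEPCohort-accessors
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))

#' Accessors for MEPCohort objects
#'
#' @param x an [MEPCohort-class] object.
#' @return `muscle()` the per-trace muscle factor; `patientId()`/`traceId()`
#'   character vectors; `truthHasMep()` the synthetic ground-truth flags
#'   (`NA` for real data); `samplingRate()` Hz; `windowMs()` the window
#'   length in ms; `signalMatrix()` the time-by-trace signal matrix;
#'   `isPreselected()`/`isNormalized()` processing-state flags.
#' @examples
#' cohort <- generateCohort(generatorConfig(nPatients = 2,
#'     tracesPerPatient = c(EXT = 3)))
#' muscle(cohort)
#' dim(signalMatrix(cohort))
#' @name MEPCohort-accessors
NULL

#' @rdname MEPCohort-accessors
#' @export
setMethod("muscle", "MEPCohort", function(x)
    SummarizedExperiment::colData(x)$muscle)

#' @rdname MEPCohort-accessors
#' @export
setMethod("patientId", "MEPCohort", function(x)
    SummarizedExperiment::colData(x)$patient_id)

#' @rdname MEPCohort-accessors
#' @export
setMethod("traceId", "MEPCohort", function(x)
    SummarizedExperiment::colData(x)$trace_id)

#' @rdname MEPCohort-accessors
#' @export
setMethod("truthHasMep", "MEPCohort", function(x)
    SummarizedExperiment::colData(x)$truth_has_mep)

#' @rdname MEPCohort-accessors
#' @export
setMethod("samplingRate", "MEPCohort", function(x)
    S4Vectors::metadata(x)$sampling_rate)

#' @rdname MEPCohort-accessors
#' @export
setMethod("windowMs", "MEPCohort", function(x)
    S4Vectors::metadata(x)$window_ms)

#' @rdname MEPCohort-accessors
#' @export
setMethod("signalMatrix", "MEPCohort", function(x)
    SummarizedExperiment::assay(x, "signal"))

#' @rdname MEPCohort-accessors
#' @export
setMethod("isPreselected", "MEPCohort", function(x)
    isTRUE(S4Vectors::metadata(x)$preselected))

#' @rdname MEPCohort-accessors
#' @export
setMethod("isNormalized", "MEPCohort", function(x)
    isTRUE(S4Vectors::metadata(x)$normalized))

setMethod("show", "MEPCohort", function(object) {
    cat(sprintf("MEPCohort: %d traces x %d samples (%g ms @ %g kHz)\n",
                ncol(object), nrow(object), windowMs(object),
                samplingRate(object) / 1000))
    cat(sprintf("  patients: %d | preselected: %s | normalized: %s\n",
                length(unique(patientId(object))), isPreselected(object),
                isNormalized(object)))
    tab <- table(muscle(object))
    cat("  muscles: ",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = " "),
        "\n", sep = "")
})

setMethod("show", "MEPPca", function(object) {
    k <- object@nComponents
    cat(sprintf("MEPPca: %d retained components (target %.2f, reached %.4f)\n",
                k, object@varTarget,
                if (k) sum(object@varExplained[seq_len(k)]) else 0))
})

setMethod("show", "EvaluationReport", function(object) {
    cat(sprintf("EvaluationReport [%s | %s | %s]\n", object@algorithm,
                object@paradigm, object@representation))
    cat(sprintf("  accuracy %.3f | macro F1 %.3f | ROC AUC %.3f (%s)\n",
                object@accuracy, object@f1Macro, object@rocAuc,
                object@aucScheme))
    print(object@confusion)
})
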