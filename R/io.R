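## Minimal EDF (European Data Format, 16-bit) writer/reader.
## Layout convention for cohort archives: one channel per (patient, muscle)
## pair; each data record holds one recording window per channel; channels
## with fewer windows than the longest one are zero-padded and the manifest
## records which (channel, record) slots are real traces.

edfField <- function(x, width) {
    s <- substr(format(x, trim = TRUE), 1, width)
    formatC(s, width = width, flag = "-")
}

writeEdf <- function(path, channels, labels, recordDurationSec) {
    stopifnot(length(channels) == length(labels))
    ns <- length(channels)
    spr <- unique(vapply(channels, nrow, integer(1)))
    if (length(spr) != 1)
        stop("non-uniform samples per record across channels")
    nRec <- max(vapply(channels, ncol, integer(1)))
    physMax <- vapply(channels, function(m) max(abs(m), 1e-12), numeric(1))
    con <- file(path, "wb")
    on.exit(close(con))
    hdr <- paste0(
        edfField("0", 8), edfField("synthetic cohort", 80),
        edfField("mepmuscle archive", 80),
        edfField("01.01.26", 8), edfField("00.00.00", 8),
        edfField(256 * (1 + ns), 8), edfField("", 44),
        edfField(nRec, 8), edfField(format(recordDurationSec), 8),
        edfField(ns, 4),
        paste(edfField(labels, 16), collapse = ""),
        paste(rep(edfField("", 80), ns), collapse = ""),
        paste(rep(edfField("au", 8), ns), collapse = ""),
        paste(edfField(sprintf("%.6g", -physMax), 8), collapse = ""),
        paste(edfField(sprintf("%.6g", physMax), 8), collapse = ""),
        paste(rep(edfField(-32767, 8), ns), collapse = ""),
        paste(rep(edfField(32767, 8), ns), collapse = ""),
        paste(rep(edfField("", 80), ns), collapse = ""),
        paste(rep(edfField(spr, 8), ns), collapse = ""),
        paste(rep(edfField("", 32), ns), collapse = ""))
    writeChar(hdr, con, eos = NULL)
    for (r in seq_len(nRec)) {
        for (s in seq_len(ns)) {
            x <- if (r <= ncol(channels[[s]])) channels[[s]][, r]
                 else numeric(spr)
            dig <- as.integer(round(x / physMax[s] * 32767))
            writeBin(pmin(pmax(dig, -32767L), 32767L), con, size = 2,
                     endian = "little")
        }
    }
    invisible(path)
}

readEdf <- function(path) {
    con <- file(path, "rb")
    on.exit(close(con))
    rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
    rd(8); rd(80); rd(80); rd(8); rd(8)
    rd(8); rd(44)
    nRec <- as.integer(rd(8))
    recDur <- as.numeric(rd(8))
    ns <- as.integer(rd(4))
    labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
    for (i in seq_len(ns)) rd(80)
    for (i in seq_len(ns)) rd(8)
    physMin <- as.numeric(vapply(seq_len(ns), function(i) rd(8),
                                 character(1)))
    physMax <- as.numeric(vapply(seq_len(ns), function(i) rd(8),
                                 character(1)))
    digMin <- as.numeric(vapply(seq_len(ns), function(i) rd(8),
                                character(1)))
    digMax <- as.numeric(vapply(seq_len(ns), function(i) rd(8),
                                character(1)))
    for (i in seq_len(ns)) rd(80)
    spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), character(1)))
    for (i in seq_len(ns)) rd(32)
    channels <- lapply(seq_len(ns), function(s)
        matrix(0, nrow = spr[s], ncol = nRec))
    for (r in seq_len(nRec)) {
        for (s in seq_len(ns)) {
            dig <- readBin(con, "integer", n = spr[s], size = 2,
                           endian = "little")
            channels[[s]][, r] <- physMin[s] + (dig - digMin[s]) *
                (physMax[s] - physMin[s]) / (digMax[s] - digMin[s])
        }
    }
    list(channels = channels, labels = labels, recordDurationSec = recDur,
         samplesPerRecord = spr, nRecords = nRec)
}

#' Export a cohort as an EDF archive with a manifest
#'
#' Writes `signals.edf` (one channel per (patient, muscle) pair, one
#' recording window per data record) and `manifest.tsv` (trace_id,
#' patient_id, muscle, truth flag, channel/record offsets) into `path`.
#' Sampling rate and window length are encoded in the EDF header (samples
#' per record and record duration).
#'
#' @param cohort a non-empty [MEPCohort-class].
#' @param path directory to create/use.
#' @return `path`, invisibly.
#' @examples
#' cfg <- generatorConfig(nPatients = 2, tracesPerPatient = c(EXT = 3))
#' d <- file.path(tempdir(), "arch")
#' exportCohort(generateCohort(cfg), d)
#' list.files(d)
#' @export
exportCohort <- function(cohort, path) {
    stopifnot(methods::is(cohort, "MEPCohort"))
    if (ncol(cohort) == 0) stop("cannot export an empty cohort")
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    if (!dir.exists(path)) stop("unwritable path: ", path)
    key <- paste(patientId(cohort), muscle(cohort), sep = "|")
    chanKeys <- unique(key)
    sig <- signalMatrix(cohort)
    channels <- lapply(chanKeys, function(k)
        sig[, key == k, drop = FALSE])
    manifest <- data.frame(trace_id = traceId(cohort),
                           patient_id = patientId(cohort),
                           muscle = as.character(muscle(cohort)),
                           truth_has_mep = truthHasMep(cohort),
                           channel = match(key, chanKeys),
                           record = stats::ave(seq_along(key), key,
                                               FUN = seq_along))
    writeEdf(file.path(path, "signals.edf"), channels,
             labels = chanKeys,
             recordDurationSec = windowMs(cohort) / 1000)
    utils::write.table(manifest, file.path(path, "manifest.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Import a cohort from an EDF archive
#'
#' Reads an archive written by [exportCohort()].  The window length in
#' samples is taken from the EDF header (samples per record), so archives
#' at sampling rates other than 20 kHz are accepted with the window length
#' recomputed from the record duration.  Manifest rows pointing past the
#' end of their channel are skipped with a warning; unknown muscle labels
#' are an error.
#'
#' @param path archive directory.
#' @return an [MEPCohort-class].
#' @export
importCohort <- function(path) {
    manifestPath <- file.path(path, "manifest.tsv")
    if (!file.exists(manifestPath)) stop("missing manifest: ", manifestPath)
    manifest <- utils::read.delim(manifestPath, stringsAsFactors = FALSE)
    edf <- readEdf(file.path(path, "signals.edf"))
    checkMuscle(manifest$muscle)
    spr <- edf$samplesPerRecord[1]
    ok <- manifest$channel >= 1 & manifest$channel <= length(edf$channels) &
        manifest$record >= 1 & manifest$record <= edf$nRecords
    if (any(!ok)) {
        warning(sum(!ok), " manifest row(s) point outside the signal store",
                "; skipped: ",
                paste(utils::head(manifest$trace_id[!ok], 5), collapse = ", "))
        manifest <- manifest[ok, , drop = FALSE]
    }
    sig <- vapply(seq_len(nrow(manifest)), function(i)
        edf$channels[[manifest$channel[i]]][, manifest$record[i]],
        numeric(spr))
    MEPCohort(sig, muscle = manifest$muscle,
              patientId = manifest$patient_id,
              traceId = manifest$trace_id,
              truthHasMep = manifest$truth_has_mep,
              samplingRate = spr / edf$recordDurationSec,
              windowMs = edf$recordDurationSec * 1000)
}

#' Write / read a feature table
#'
#' Lossless (at full double precision) delimited-text round trip of the
#' 7-feature representation plus labels.  On read, a header missing any
#' feature column is an error naming the column.
#'
#' @param features a data.frame from [extractFeatures()].
#' @param path file path (tab-separated text).
#' @return `writeFeatureTable()`: `path`, invisibly;
#'   `readFeatureTable()`: the data.frame.
#' @examples
#' cfg <- generatorConfig(nPatients = 2, tracesPerPatient = c(APB = 6))
#' ft <- extractFeatures(preselectCohort(generateCohort(cfg))$accepted)
#' p <- tempfile(fileext = ".tsv")
#' writeFeatureTable(ft, p)
#' head(readFeatureTable(p))
#' @export
writeFeatureTable <- function(features, path) {
    need <- c(featureNames(), "muscle", "patient_id", "trace_id")
    miss <- setdiff(need, colnames(features))
    if (length(miss))
        stop("feature table missing column(s): ",
             paste(miss, collapse = ", "))
    out <- features[, need]
    for (cl in featureNames())
        out[[cl]] <- sprintf("%.17g", out[[cl]])
    utils::write.table(out, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
    ft <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
    miss <- setdiff(featureNames(), colnames(ft))
    if (length(miss))
        stop("feature table missing column(s): ",
             paste(miss, collapse = ", "))
    for (cl in featureNames()) ft[[cl]] <- as.numeric(ft[[cl]])
    ft
}
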