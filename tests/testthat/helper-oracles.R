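# Independent brute-force oracles used to cross-check package operations.

# All local maxima (leftmost of plateau) of x by direct enumeration, with
# prominences computed literally from the definition: scan each side for the
# nearest strictly higher sample; the side base is the minimum in between.
oracleFindPeaks <- function(x) {
    n <- length(x)
    out <- data.frame(index = integer(), prominence = numeric())
    i <- 2
    while (i <= n - 1) {
        if (x[i] > x[i - 1]) {
            j <- i
            while (j < n && x[j + 1] == x[i]) j <- j + 1
            if (j < n && x[j + 1] < x[i]) {
                lmin <- x[i]
                for (l in (i - 1):1) {
                    if (x[l] > x[i]) break
                    lmin <- min(lmin, x[l])
                }
                rmin <- x[i]
                for (r2 in (j + 1):n) {
                    if (x[r2] > x[i]) break
                    rmin <- min(rmin, x[r2])
                }
                out <- rbind(out, data.frame(index = i - 1,
                                             prominence = x[i] -
                                                 max(lmin, rmin)))
            }
            i <- j + 1
        } else i <- i + 1
    }
    out
}

# Gate decision by brute force for a short trace.
oracleGate <- function(samples, samplingRate, cutoffMs, prominenceSds = 2,
                       maxPeaks = 10) {
    cut <- round(cutoffMs * samplingRate / 1000)
    rect <- abs(samples)
    sdSeg <- stats::sd(rect[(cut + 1):length(samples)])
    if (!is.finite(sdSeg) || sdSeg == 0) return(FALSE)
    pk <- oracleFindPeaks(rect)
    np <- sum(pk$index >= cut & pk$prominence > prominenceSds * sdSeg)
    np >= 1 && np <= maxPeaks
}

# Macro F1 by literal per-class formula evaluation.
oracleF1 <- function(preds, labels) {
    cls <- sort(unique(labels))
    vals <- numeric(0)
    for (cl in cls) {
        tp <- 0; fp <- 0; fn <- 0
        for (i in seq_along(labels)) {
            if (preds[i] == cl && labels[i] == cl) tp <- tp + 1
            if (preds[i] == cl && labels[i] != cl) fp <- fp + 1
            if (preds[i] != cl && labels[i] == cl) fn <- fn + 1
        }
        vals <- c(vals, if (2 * tp + fp + fn == 0) 0
                  else 2 * tp / (2 * tp + fp + fn))
    }
    mean(vals)
}

# Binary AUC by all-pairs concordance, ties counted half.
oracleAucBinary <- function(score, pos) {
    ip <- which(pos); im <- which(!pos)
    tot <- 0
    for (i in ip) for (j in im)
        tot <- tot + (score[i] > score[j]) + 0.5 * (score[i] == score[j])
    tot / (length(ip) * length(im))
}

# Macro one-vs-rest AUC from a score matrix.
oracleAucMacro <- function(scores, labels) {
    cls <- sort(unique(labels))
    mean(vapply(cls, function(cl)
        oracleAucBinary(scores[, cl], labels == cl), numeric(1)))
}

# Tiny preselected cohort built directly (bypasses the generator).
makePreselectedCohort <- function(traces, muscle, patientId,
                                  samplingRate = 20000) {
    sig <- do.call(cbind, traces)
    MEPCohort(sig, muscle = muscle, patientId = patientId,
              samplingRate = samplingRate,
              windowMs = nrow(sig) * 1000 / samplingRate,
              preselected = TRUE)
}
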