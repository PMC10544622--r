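#' Classification accuracy
#'
#' Number of correct classifications divided by the total number of samples.
#'
#' @param preds predicted class labels.
#' @param labels true class labels (same length).
#' @return a fraction in [0, 1].
#' @examples
#' accuracyScore(c("A", "B", "A", "B"), c("A", "A", "B", "B"))
#' @export
accuracyScore <- function(preds, labels) {
    if (!length(labels) || length(preds) != length(labels))
        stop("preds and labels must be non-empty and of equal length")
    mean(as.character(preds) == as.character(labels))
}

#' Macro-averaged F1 score
#'
#' Per-class F1 from one-vs-rest true positives, false positives and false
#' negatives, `F1 = 2TP / (2TP + FP + FN)`, averaged with equal weight over
#' the classes present in `labels`.  A class with `TP = FP = FN = 0`
#' contributes an F1 of 0 (zero-division convention).
#'
#' @inheritParams accuracyScore
#' @return a fraction in [0, 1].
#' @examples
#' f1Macro(c("A", "B", "A", "B"), c("A", "A", "B", "B"))
#' @export
f1Macro <- function(preds, labels) {
    if (!length(labels) || length(preds) != length(labels))
        stop("preds and labels must be non-empty and of equal length")
    preds <- as.character(preds)
    labels <- as.character(labels)
    classes <- sort(unique(labels))
    f1 <- vapply(classes, function(cl) {
        tp <- sum(preds == cl & labels == cl)
        fp <- sum(preds == cl & labels != cl)
        fn <- sum(preds != cl & labels == cl)
        if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    }, numeric(1))
    mean(f1)
}

#' ROC AUC (rank-based, macro one-vs-rest for multiclass)
#'
#' For each class present in the labels, the binary one-vs-rest AUC is
#' computed from the per-class score column by the rank (Mann-Whitney)
#' formula, with tied scores counted half; multiclass AUC is the unweighted
#' mean over classes (macro one-vs-rest).  A one-vs-rest split where only
#' one side is present is skipped with a warning.
#'
#' @param scores numeric matrix of per-class scores (rows sum to 1), with
#'   one named column per class; or, for the binary case, a vector of
#'   positive-class scores.
#' @param labels true class labels; for the vector form, a logical or
#'   two-level vector where `TRUE`/the second level is the positive class.
#' @param positive for the vector form, the positive label.
#' @return a fraction in [0, 1].
#' @examples
#' rocAuc(c(0.9, 0.8, 0.7, 0.1), c(TRUE, FALSE, TRUE, FALSE),
#'        positive = TRUE)
#' @export
rocAuc <- function(scores, labels, positive = NULL) {
    labels <- as.character(labels)
    if (is.null(dim(scores))) {
        if (is.null(positive)) stop("vector scores need a 'positive' label")
        return(binaryAuc(scores, labels == as.character(positive)))
    }
    scores <- as.matrix(scores)
    if (length(labels) != nrow(scores))
        stop("labels must match the score matrix rows")
    classes <- sort(unique(labels))
    if (length(classes) < 2) stop("need at least 2 classes present")
    aucs <- vapply(classes, function(cl) {
        if (!cl %in% colnames(scores)) {
            warning("no score column for class ", cl, "; skipped")
            return(NA_real_)
        }
        pos <- labels == cl
        if (all(pos) || !any(pos)) {
            warning("one-vs-rest split for class ", cl,
                    " has a single class; skipped")
            return(NA_real_)
        }
        binaryAuc(scores[, cl], pos)
    }, numeric(1))
    mean(aucs, na.rm = TRUE)
}

binaryAuc <- function(score, pos) {
    n1 <- sum(pos)
    n0 <- sum(!pos)
    if (n1 == 0 || n0 == 0) stop("both classes must be present")
    r <- rank(score, ties.method = "average")
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion matrix (counts or row-normalized)
#'
#' Rows are true classes, columns predicted classes.  With
#' `normalizeRows = TRUE` each row is divided by its sum and rounded to
#' `roundDigits` digits; zero-count rows are emitted as all-zero with a
#' warning.
#'
#' @inheritParams accuracyScore
#' @param classes class set defining the matrix order (default: classes
#'   observed in labels or predictions).
#' @param normalizeRows normalize rows to fractions?
#' @param roundDigits rounding for normalized rows.
#' @return a square numeric matrix.
#' @examples
#' confusionCounts(c("A", "B", "B"), c("A", "A", "B"),
#'                 normalizeRows = TRUE)
#' @export
confusionCounts <- function(preds, labels, classes = NULL,
                            normalizeRows = FALSE, roundDigits = 2) {
    if (length(preds) != length(labels))
        stop("preds and labels must have equal length")
    preds <- as.character(preds)
    labels <- as.character(labels)
    if (is.null(classes)) classes <- sort(unique(c(labels, preds)))
    cm <- table(factor(labels, levels = classes),
                factor(preds, levels = classes))
    cm <- matrix(as.numeric(cm), nrow = length(classes),
                 dimnames = list(true = classes, predicted = classes))
    if (normalizeRows) {
        rs <- rowSums(cm)
        if (any(rs == 0))
            warning("zero-count row(s): ",
                    paste(classes[rs == 0], collapse = ", "))
        cm <- cm / ifelse(rs == 0, 1, rs)
        cm <- round(cm, roundDigits)
    }
    cm
}

#' Aggregate a muscle-level confusion matrix to extremities
#'
#' Sums the cells of a muscle-level confusion matrix across limbs
#' (EXT/APB = UPPER, TA/AH = LOWER), preserving the total count, and
#' reports the limb-level accuracy.
#'
#' @param confusion a muscle-level confusion matrix of counts with muscle
#'   codes as dimnames (rows = true).
#' @return a list with `confusion` (2x2 UPPER/LOWER counts) and `accuracy`.
#' @examples
#' cm <- confusionCounts(rep(muscleCodes(), 2), rep(muscleCodes(), 2))
#' extremityReport(cm)
#' @export
extremityReport <- function(confusion) {
    mus <- rownames(confusion)
    ext <- extremityOf(mus)
    lv <- c("UPPER", "LOWER")
    out <- matrix(0, 2, 2, dimnames = list(true = lv, predicted = lv))
    for (i in seq_along(mus))
        for (j in seq_along(mus))
            out[ext[i], ext[j]] <- out[ext[i], ext[j]] + confusion[i, j]
    list(confusion = out, accuracy = sum(diag(out)) / sum(out))
}

#' Build the full evaluation report for one experiment cell
#'
#' @param preds predicted labels on the test set.
#' @param labels true test labels.
#' @param scores per-class score matrix (rows sum to 1).
#' @param algorithm,paradigm,representation cell identity.
#' @param tuned list of tuned hyperparameters.
#' @return an [EvaluationReport-class].
#' @export
evaluationReport <- function(preds, labels, scores, algorithm = "NA",
                             paradigm = "NA", representation = "NA",
                             tuned = list()) {
    classes <- sort(unique(as.character(labels)))
    methods::new("EvaluationReport", algorithm = algorithm,
                 paradigm = paradigm, representation = representation,
                 accuracy = accuracyScore(preds, labels),
                 f1Macro = f1Macro(preds, labels),
                 rocAuc = rocAuc(scores, labels),
                 confusion = confusionCounts(preds, labels, classes),
                 tuned = tuned, aucScheme = "macro one-vs-rest")
}
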