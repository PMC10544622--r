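test_that("accuracy is exact rational arithmetic", {
    expect_equal(accuracyScore(c("A", "B"), c("A", "B")), 1)
    expect_equal(accuracyScore(c("A", "B", "A", "B"),
                               c("A", "A", "B", "B")), 0.5)
    expect_equal(accuracyScore(c("A", "A", "A", "A", "B"),
                               c("A", "A", "A", "A", "A")), 0.8)
    expect_error(accuracyScore(character(0), character(0)), "non-empty")
})

test_that("macro F1 follows the per-class one-vs-rest formula", {
    expect_equal(f1Macro(c("A", "B"), c("A", "B")), 1)
    # each class: TP=1, FP=1, FN=1 -> F1 = 2/4
    expect_equal(f1Macro(c("A", "B", "A", "B"), c("A", "A", "B", "B")), 0.5)
    expect_equal(f1Macro(c("B", "A"), c("A", "B")), 0)
})

test_that("ROC AUC follows the rank formula with ties counted half", {
    expect_equal(rocAuc(c(1, 1, 0, 0), c(TRUE, TRUE, FALSE, FALSE),
                        positive = TRUE), 1)
    expect_equal(rocAuc(rep(0.5, 6), rep(c(TRUE, FALSE), 3),
                        positive = TRUE), 0.5)
    # concordant pairs 3 of 4
    expect_equal(rocAuc(c(0.9, 0.8, 0.7, 0.1),
                        c("p", "n", "p", "n"), positive = "p"), 0.75)
})

test_that("metric implementations match brute-force oracles", {
    set.seed(41)
    classes <- c("EXT", "APB", "TA", "AH")
    for (i in 1:200) {
        n <- sample(8:30, 1)
        k <- sample(2:4, 1)
        cls <- classes[seq_len(k)]
        labels <- c(cls, sample(cls, n - k, replace = TRUE)) # all present
        preds <- sample(cls, n, replace = TRUE)
        sc <- matrix(runif(n * k), n, k, dimnames = list(NULL, cls))
        if (i %% 4 == 0) sc <- ceiling(sc * 4) / 4  # force score ties
        sc <- sc / rowSums(sc)
        expect_equal(f1Macro(preds, labels), oracleF1(preds, labels))
        expect_equal(rocAuc(sc, labels), oracleAucMacro(sc, labels))
        expect_equal(accuracyScore(preds, labels), mean(preds == labels))
    }
})

test_that("binary AUC agrees with an established implementation", {
    skip_if_not_installed("pROC")
    set.seed(43)
    for (i in 1:10) {
        y <- sample(c(0, 1), 40, replace = TRUE, prob = c(0.4, 0.6))
        if (length(unique(y)) < 2) next
        s <- runif(40)
        ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                              direction = "<")))
        expect_equal(rocAuc(s, y == 1, positive = TRUE), ref)
    }
})

test_that("confusion matrices count, normalize and aggregate correctly", {
    cm <- confusionCounts(c("A", "B", "B"), c("A", "A", "B"))
    expect_equal(cm["A", "A"], 1)
    expect_equal(cm["A", "B"], 1)
    expect_equal(cm["B", "B"], 1)
    expect_equal(sum(cm), 3)

    cmn <- confusionCounts(c("A", "B", "B"), c("A", "A", "B"),
                           normalizeRows = TRUE)
    expect_equal(unname(cmn["A", ]), c(0.5, 0.5))
    expect_equal(unname(cmn["B", ]), c(0, 1))

    # perfect predictions: identity after normalization
    p <- rep(c("A", "B", "C"), 4)
    expect_equal(unname(confusionCounts(p, p, normalizeRows = TRUE)),
                 diag(3))

    # zero-count row warning
    expect_warning(confusionCounts(c("A", "A"), c("A", "A"),
                                   classes = c("A", "B"),
                                   normalizeRows = TRUE), "zero-count")
})

test_that("limb aggregation preserves counts and accuracy structure", {
    set.seed(47)
    labels <- sample(muscleCodes(), 200, replace = TRUE)
    preds <- ifelse(runif(200) < 0.6, labels,
                    sample(muscleCodes(), 200, replace = TRUE))
    cm <- confusionCounts(preds, labels, classes = muscleCodes())
    limb <- extremityReport(cm)
    expect_equal(sum(limb$confusion), sum(cm))
    expect_equal(dim(limb$confusion), c(2, 2))
    # limb accuracy can only gain from within-limb confusions
    expect_gte(limb$accuracy, sum(diag(cm)) / sum(cm))

    # pure within-limb confusion: perfect limb accuracy
    lab2 <- c("EXT", "APB", "TA", "AH")
    prd2 <- c("APB", "EXT", "AH", "TA")
    limb2 <- extremityReport(confusionCounts(prd2, lab2,
                                             classes = muscleCodes()))
    expect_equal(limb2$accuracy, 1)
})

test_that("evaluation reports are internally consistent", {
    set.seed(53)
    labels <- sample(c("EXT", "TA"), 50, replace = TRUE)
    sc <- matrix(runif(100), 50, 2, dimnames = list(NULL, c("EXT", "TA")))
    sc <- sc / rowSums(sc)
    preds <- colnames(sc)[max.col(sc)]
    rep1 <- evaluationReport(preds, labels, sc, algorithm = "RF",
                             paradigm = "EXT_vs_TA",
                             representation = "RAW")
    expect_s4_class(rep1, "EvaluationReport")
    expect_equal(rep1@accuracy,
                 sum(diag(rep1@confusion)) / sum(rep1@confusion))
    expect_equal(rep1@aucScheme, "macro one-vs-rest")
    expect_output(show(rep1), "EXT_vs_TA")
})
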