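makeToyCohort <- function(seed = 61, nPatients = 6, perMuscle = 8) {
    cfg <- generatorConfig(
        nPatients = nPatients, seed = seed,
        tracesPerPatient = setNames(rep(perMuscle, 4), muscleCodes()),
        blankRate = c(EXT = .05, APB = .05, TA = .1, AH = .1))
    normalizePatients(preselectCohort(generateCohort(cfg))$accepted)
}

test_that("patient-wise splitting is disjoint and deterministic", {
    coh <- makeToyCohort()
    sp <- splitByPatient(coh, nTrain = 4, nTest = 2, seed = 5)
    expect_length(sp$trainPatients, 4)
    expect_length(sp$testPatients, 2)
    expect_length(intersect(sp$trainPatients, sp$testPatients), 0)
    expect_setequal(unique(patientId(sp$train)), sp$trainPatients)
    expect_setequal(unique(patientId(sp$test)), sp$testPatients)
    sp2 <- splitByPatient(coh, nTrain = 4, nTest = 2, seed = 5)
    expect_identical(sp$testPatients, sp2$testPatients)
    expect_error(splitByPatient(coh, nTrain = 5, nTest = 2), "equal")
})

test_that("SMOTE equalizes counts with convex-combination synthetics", {
    set.seed(67)
    x <- rbind(matrix(rnorm(40, 0), 20, 2),
               matrix(rnorm(16, 4), 8, 2))
    y <- rep(c("maj", "min"), c(20, 8))
    out <- smoteBalance(x, y, k = 3, seed = 2)
    expect_equal(unname(table(out$y)["min"]), 20)
    expect_equal(unname(table(out$y)["maj"]), 20)
    # original rows preserved, in order, ahead of synthetics
    expect_equal(out$x[1:28, ], unname(x))
    # every synthetic row lies on a segment between two same-class rows
    minRows <- x[y == "min", , drop = FALSE]
    for (i in 29:nrow(out$x)) {
        z <- out$x[i, ]
        expect_equal(out$y[i], "min")
        onSeg <- FALSE
        for (a in seq_len(nrow(minRows))) for (b in seq_len(nrow(minRows))) {
            d <- minRows[b, ] - minRows[a, ]
            za <- z - minRows[a, ]
            if (sum(d^2) == 0) next
            t <- sum(za * d) / sum(d^2)
            if (t >= -1e-9 && t <= 1 + 1e-9 &&
                sqrt(sum((za - t * d)^2)) < 1e-8) onSeg <- TRUE
        }
        expect_true(onSeg, label = paste("synthetic row", i))
    }
})

test_that("SMOTE edge cases follow the definition", {
    # already balanced: unchanged
    x <- matrix(rnorm(20), 10, 2)
    y <- rep(c("a", "b"), 5)
    out <- smoteBalance(x, y, seed = 1)
    expect_equal(out$x, unname(x))
    expect_equal(out$y, y)

    # two-point minority with k = 1: synthetics of the form (t, t)
    x2 <- rbind(matrix(rnorm(20, 10), 10, 2), c(0, 0), c(1, 1))
    y2 <- rep(c("maj", "min"), c(10, 2))
    out2 <- smoteBalance(x2, y2, k = 1, seed = 3)
    syn <- out2$x[out2$y == "min", , drop = FALSE][-(1:2), , drop = FALSE]
    expect_equal(syn[, 1], syn[, 2])
    expect_true(all(syn[, 1] >= 0 & syn[, 1] <= 1))

    expect_error(smoteBalance(rbind(x, c(0, 0)), c(y, "solo"), seed = 1),
                 "solo")
})

test_that("grid search tunes by stratified CV with first-in-grid ties", {
    set.seed(71)
    # two tight, well-separated clusters: small k beats huge k
    x <- rbind(matrix(rnorm(60, 0, 0.3), 30, 2),
               matrix(rnorm(60, 5, 0.3), 30, 2))
    y <- rep(c("a", "b"), each = 30)
    tuned <- tuneHyperparameters("kNN", x, y,
        grid = data.frame(k = c(3, 59), distance = "euclidean",
                          stringsAsFactors = FALSE),
        cvFolds = 5, seed = 1)
    expect_equal(tuned$best$k, 3)
    expect_true(tuned$best$k %in% c(3, 59))

    # single-point grid: that point selected
    t1 <- tuneHyperparameters("RF", x, y,
        grid = data.frame(num.trees = 50, max.depth = 0),
        cvFolds = 3, seed = 1)
    expect_equal(t1$best$num.trees, 50)

    # tuned RF values always come from the grid
    gridRF <- defaultGrids(reduced = TRUE)$RF
    t2 <- tuneHyperparameters("RF", x, y, grid = gridRF, cvFolds = 3,
                              seed = 2)
    expect_true(any(gridRF$num.trees == t2$best$num.trees &
                    gridRF$max.depth == t2$best$max.depth))
})

test_that("classifiers predict sanely in identifiable cases", {
    set.seed(73)
    x <- matrix(rnorm(40), 20, 2)
    y <- rep("only", 20)
    for (alg in c("RF", "kNN")) {
        params <- list(num.trees = 50, max.depth = 0, k = 3,
                       distance = "euclidean")
        out <- trainAndPredict(alg, params, x, y, matrix(rnorm(10), 5, 2),
                               seed = 1)
        expect_true(all(out$pred == "only"))
    }

    # kNN with k = 1 recalls a training point exactly
    x2 <- rbind(a = c(0, 0), b = c(5, 5), c = c(0, 5))
    y2 <- c("a", "b", "c")
    out2 <- trainAndPredict("kNN",
                            list(k = 1, distance = "euclidean"),
                            x2, y2, x2[2, , drop = FALSE], seed = 1)
    expect_equal(out2$pred, "b")
    expect_equal(unname(out2$scores[1, "b"]), 1)

    # manhattan distance is honoured
    out3 <- trainAndPredict("kNN", list(k = 1, distance = "manhattan"),
                            x2, y2, matrix(c(0.4, 0.2), 1, 2), seed = 1)
    expect_equal(out3$pred, "a")

    # score vectors sum to one for all three algorithms
    xb <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 3), 20, 2))
    yb <- rep(c("a", "b"), each = 20)
    for (alg in c("RF", "kNN", "LogReg")) {
        params <- list(num.trees = 50, max.depth = 0, k = 3,
                       distance = "euclidean", lambda = 0.01)
        outb <- trainAndPredict(alg, params, xb, yb,
                                matrix(rnorm(12), 6, 2), seed = 1)
        expect_equal(unname(rowSums(outb$scores)), rep(1, 6),
                     tolerance = 1e-6)
    }

    expect_error(trainAndPredict("kNN", list(k = 1, distance = "euclidean"),
                                 x2, y2, matrix(0, 1, 3)), "mismatch")
})

test_that("the experiment grid is leakage-free and correctly shaped", {
    coh <- makeToyCohort(seed = 79, nPatients = 6, perMuscle = 10)
    res <- runExperiment(coh, paradigms = c("FOUR_MUSCLE", "EXT_vs_APB"),
                         representations = c("PCA", "FE"),
                         algorithms = c("kNN", "LogReg"),
                         seed = 2, grids = defaultGrids(reduced = TRUE),
                         cvFolds = 2, nTrain = 4, nTest = 2)
    expect_length(res$reports, 2 * 2 * 2)
    expect_length(intersect(res$split$trainPatients,
                            res$split$testPatients), 0)

    # two-class paradigms contain no dropped-class test traces
    cm <- res$reports[["kNN.EXT_vs_APB.FE"]]@confusion
    expect_setequal(rownames(cm), c("APB", "EXT"))

    # PCA fitted on training rows only: its centre is the train mean
    sp <- splitByPatient(coh, nTrain = 4, nTest = 2,
                         seed = deriveSeed(2, "split"))
    pca <- fitPca(t(signalMatrix(sp$train)))
    expect_equal(pca@center, colMeans(t(signalMatrix(sp$train))))
    expect_gte(sum(pca@varExplained[seq_len(pca@nComponents)]), 0.95)

    # determinism of the full grid
    res2 <- runExperiment(coh, paradigms = "EXT_vs_APB",
                          representations = "FE", algorithms = "kNN",
                          seed = 2, grids = defaultGrids(reduced = TRUE),
                          cvFolds = 2, nTrain = 4, nTest = 2)
    expect_identical(res2$reports[["kNN.EXT_vs_APB.FE"]]@accuracy,
                     res$reports[["kNN.EXT_vs_APB.FE"]]@accuracy)
})
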