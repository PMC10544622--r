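#' Muscle-comparison paradigms
#'
#' The three classification paradigms: all four muscles simultaneously, the
#' within-upper-extremity pair (EXT vs APB), and the across-extremities pair
#' (EXT vs TA).
#'
#' @param code one of `"FOUR_MUSCLE"`, `"EXT_vs_APB"`, `"EXT_vs_TA"`.
#' @return `paradigmClasses()`: the class set of the paradigm;
#'   `paradigmCodes()`: all paradigm codes.
#' @examples
#' paradigmClasses("EXT_vs_TA")
#' @export
paradigmClasses <- function(code) {
    switch(match.arg(code, paradigmCodes()),
           FOUR_MUSCLE = c("EXT", "APB", "TA", "AH"),
           EXT_vs_APB = c("EXT", "APB"),
           EXT_vs_TA = c("EXT", "TA"))
}

#' @rdname paradigmClasses
#' @export
paradigmCodes <- function() c("FOUR_MUSCLE", "EXT_vs_APB", "EXT_vs_TA")

#' @rdname paradigmClasses
#' @export
representationCodes <- function() c("RAW", "PCA", "FE")

#' Patient-disjoint train/test split
#'
#' Assigns whole patients uniformly at random to the training or test side,
#' so that no patient contributes traces to both.
#'
#' @param cohort an [MEPCohort-class].
#' @param nTrain,nTest number of training/test patients; must sum to the
#'   number of distinct patients (defaults 28/8 for a 36-patient cohort).
#' @param seed integer seed for the assignment.
#' @return a list: `train` and `test` ([MEPCohort-class] subsets),
#'   `trainPatients`, `testPatients`, `seed`.
#' @examples
#' cfg <- generatorConfig(nPatients = 6, tracesPerPatient = c(EXT = 4))
#' sp <- splitByPatient(generateCohort(cfg), nTrain = 4, nTest = 2, seed = 1)
#' intersect(sp$trainPatients, sp$testPatients)
#' @export
splitByPatient <- function(cohort, nTrain = 28, nTest = 8, seed = 1) {
    stopifnot(methods::is(cohort, "MEPCohort"))
    patients <- unique(patientId(cohort))
    if (nTrain + nTest != length(patients))
        stop("nTrain + nTest (", nTrain + nTest,
             ") must equal the number of patients (", length(patients), ")")
    set.seed(as.integer(seed))
    testPatients <- sort(sample(patients, nTest))
    trainPatients <- sort(setdiff(patients, testPatients))
    list(train = cohort[, patientId(cohort) %in% trainPatients],
         test = cohort[, patientId(cohort) %in% testPatients],
         trainPatients = trainPatients, testPatients = testPatients,
         seed = seed)
}

#' SMOTE class balancing
#'
#' Synthetic minority oversampling: every class is brought up to the
#' majority-class count by adding synthetic rows, each a convex combination
#' `x + u (z - x)`, `u ~ U(0, 1)`, of a random minority row `x` and one of
#' its `k` nearest same-class neighbours `z` (Euclidean distance).  Original
#' rows are preserved, in order, ahead of the synthetic rows.
#'
#' @param x numeric matrix of training rows.
#' @param y class labels (one per row).
#' @param k number of same-class nearest neighbours to draw from.
#' @param seed integer seed.
#' @return a list with the balanced `x` and `y`.
#' @examples
#' out <- smoteBalance(matrix(rnorm(20), 10, 2),
#'                     rep(c("a", "b"), c(7, 3)), seed = 1)
#' table(out$y)
#' @export
smoteBalance <- function(x, y, k = 5, seed = 1) {
    x <- as.matrix(x)
    y <- as.character(y)
    stopifnot(nrow(x) == length(y), k >= 1)
    counts <- table(y)
    small <- names(counts)[counts < 2]
    if (length(small))
        stop("class(es) with fewer than 2 training samples: ",
             paste(small, collapse = ", "))
    target <- max(counts)
    set.seed(as.integer(seed))
    synX <- list()
    synY <- character(0)
    for (cl in names(counts)) {
        need <- target - counts[[cl]]
        if (need == 0) next
        rows <- which(y == cl)
        xc <- x[rows, , drop = FALSE]
        kEff <- min(k, nrow(xc) - 1)
        d <- as.matrix(stats::dist(xc))
        diag(d) <- Inf
        nn <- apply(d, 1, function(v) order(v)[seq_len(kEff)])
        nn <- matrix(nn, nrow = kEff)  # kEff x n_class
        base <- sample.int(nrow(xc), need, replace = TRUE)
        pick <- vapply(base, function(b) nn[sample.int(kEff, 1), b],
                       integer(1))
        u <- stats::runif(need)
        newRows <- xc[base, , drop = FALSE] +
            u * (xc[pick, , drop = FALSE] - xc[base, , drop = FALSE])
        synX[[cl]] <- newRows
        synY <- c(synY, rep(cl, need))
    }
    if (length(synX)) {
        x <- rbind(x, do.call(rbind, synX))
        y <- c(y, synY)
    }
    rownames(x) <- NULL
    list(x = x, y = y)
}

#' Default hyperparameter grids
#'
#' Substitute grids bracketing common implementation defaults: random forest
#' over number of trees and maximum depth (0 = unbounded), kNN over the
#' neighbour count and distance metric, and ridge-penalized logistic
#' regression over the penalty strength `lambda`.
#'
#' @param reduced use the small desk-scale grids (used by the bundled
#'   experiment runs) instead of the full ones.
#' @return a named list of data.frame grids for `"RF"`, `"kNN"`, `"LogReg"`.
#' @examples
#' defaultGrids()$kNN
#' @export
defaultGrids <- function(reduced = FALSE) {
    if (reduced)
        return(list(
            RF = expand.grid(num.trees = 200, max.depth = c(0, 15)),
            kNN = expand.grid(k = c(5, 21), distance = "euclidean",
                              stringsAsFactors = FALSE),
            LogReg = data.frame(lambda = c(0.1, 0.001))))
    list(RF = expand.grid(num.trees = c(100, 300, 500),
                          max.depth = c(0, 10, 20)),
         kNN = expand.grid(k = c(1, 3, 5, 11, 21),
                           distance = c("euclidean", "manhattan"),
                           stringsAsFactors = FALSE),
         LogReg = data.frame(lambda = c(1, 0.1, 0.01, 0.001, 1e-4)))
}

## Cross-side distances between test rows and training rows.
crossDist <- function(xTest, xTrain, method = "euclidean") {
    if (method == "euclidean") {
        cp <- tcrossprod(xTest, xTrain)
        d2 <- outer(rowSums(xTest^2), rowSums(xTrain^2), "+") - 2 * cp
        sqrt(pmax(d2, 0))
    } else if (method == "manhattan") {
        tt <- t(xTrain)
        t(apply(xTest, 1, function(r) colSums(abs(tt - r))))
    } else stop("unknown distance: ", method)
}

fitModel <- function(algorithm, x, y, params, seed = 1) {
    y <- factor(y)
    if (is.null(colnames(x)))
        colnames(x) <- paste0("V", seq_len(ncol(x)))
    switch(algorithm,
        RF = {
            depth <- params$max.depth
            list(kind = "RF", levels = levels(y), varnames = colnames(x),
                 fit = ranger::ranger(
                     x = x, y = y, probability = TRUE,
                     num.trees = params$num.trees,
                     max.depth = if (depth > 0) depth else NULL,
                     seed = as.integer(seed), num.threads = 1))
        },
        kNN = list(kind = "kNN", x = x, y = y, k = params$k,
                   distance = params$distance, levels = levels(y)),
        LogReg = {
            fam <- if (nlevels(y) > 2) "multinomial" else "binomial"
            ## fit along a short decreasing path ending at the target
            ## penalty (glmnet is unreliable with a single lambda), then
            ## predict at the target; convergence notes are logged, not fatal
            fit <- withCallingHandlers(
                glmnet::glmnet(x, y, family = fam, alpha = 0,
                               lambda = params$lambda * c(100, 10, 1),
                               standardize = TRUE, maxit = 2e5),
                warning = function(w) {
                    message("LogReg convergence note: ",
                            conditionMessage(w))
                    invokeRestart("muffleWarning")
                })
            list(kind = "LogReg", levels = levels(y), fit = fit,
                 lambda = params$lambda)
        },
        stop("unknown algorithm: ", algorithm))
}

predictModel <- function(model, x) {
    lv <- model$levels
    scores <- switch(model$kind,
        RF = {
            colnames(x) <- model$varnames
            pr <- stats::predict(model$fit, data = x,
                                 num.threads = 1)$predictions
            pr[, lv, drop = FALSE]
        },
        kNN = {
            d <- crossDist(x, model$x, model$distance)
            k <- min(model$k, ncol(d))
            votes <- vapply(seq_len(nrow(d)), function(i) {
                nb <- model$y[order(d[i, ])[seq_len(k)]]
                tabulate(nb, nbins = length(lv)) / k
            }, numeric(length(lv)))
            votes <- t(matrix(votes, nrow = length(lv)))
            colnames(votes) <- lv
            votes
        },
        LogReg = {
            pr <- stats::predict(model$fit, newx = x, type = "response",
                                 s = model$lambda)
            if (length(dim(pr)) == 3) {
                pr <- pr[, , 1]
                pr[, lv, drop = FALSE]
            } else {
                p2 <- as.numeric(pr)
                cbind(matrix(1 - p2, ncol = 1), p2,
                      deparse.level = 0) -> m
                colnames(m) <- lv
                m
            }
        })
    pred <- lv[max.col(scores, ties.method = "first")]
    list(pred = pred, scores = scores)
}

#' Grid-search hyperparameter tuning by stratified cross-validation
#'
#' Exhaustively scores every grid row by mean `cvFolds`-fold
#' cross-validated accuracy on the (balanced) training data, with folds
#' stratified by class.  Ties are broken by first-in-grid order.
#'
#' @param algorithm `"RF"`, `"kNN"` or `"LogReg"`.
#' @param x training matrix (rows = traces).
#' @param y training labels.
#' @param grid data.frame of candidate hyperparameter rows (default: the
#'   full grid of [defaultGrids()]).
#' @param cvFolds number of folds (default 10).
#' @param seed integer seed (folds and fit randomness).
#' @return a list: `best` (named list of tuned values), `cvAccuracy` of the
#'   winner, and `results` (the grid with a `cv_accuracy` column).
#' @examples
#' x <- matrix(rnorm(60), 30, 2); y <- rep(c("a", "b"), 15)
#' tuneHyperparameters("kNN", x, y,
#'     grid = data.frame(k = c(1, 3), distance = "euclidean"),
#'     cvFolds = 3)$best
#' @export
tuneHyperparameters <- function(algorithm, x, y,
                                grid = defaultGrids()[[algorithm]],
                                cvFolds = 10, seed = 1) {
    stopifnot(nrow(grid) >= 1, cvFolds >= 2)
    x <- as.matrix(x)
    y <- factor(y)
    set.seed(as.integer(seed))
    folds <- caret::createFolds(y, k = cvFolds)
    if (any(vapply(folds, function(i) nlevels(droplevels(y[-i])) <
                   nlevels(y), logical(1))))
        stop("stratification error: a CV fold is missing a class")
    acc <- vapply(seq_len(nrow(grid)), function(g) {
        params <- as.list(grid[g, , drop = FALSE])
        mean(vapply(folds, function(idx) {
            fit <- fitModel(algorithm, x[-idx, , drop = FALSE], y[-idx],
                            params, seed = seed)
            accuracyScore(predictModel(fit, x[idx, , drop = FALSE])$pred,
                          y[idx])
        }, numeric(1)))
    }, numeric(1))
    best <- which.max(acc)  # first-in-grid on ties
    list(best = as.list(grid[best, , drop = FALSE]),
         cvAccuracy = acc[best],
         results = cbind(grid, cv_accuracy = acc))
}

#' Train a tuned model and predict the test set
#'
#' @param algorithm `"RF"`, `"kNN"` or `"LogReg"`.
#' @param params named list of tuned hyperparameters (see
#'   [tuneHyperparameters()]).
#' @param xTrain,yTrain training matrix and labels (balanced).
#' @param xTest test matrix in the same representation (any PCA/FE mapping
#'   fitted on training rows only).
#' @param seed integer seed.
#' @return a list: `pred` (predicted labels) and `scores` (per-class score
#'   matrix, rows summing to 1: tree-vote fractions for RF, neighbour-vote
#'   fractions for kNN, model probabilities for LogReg).
#' @export
trainAndPredict <- function(algorithm, params, xTrain, yTrain, xTest,
                            seed = 1) {
    xTrain <- as.matrix(xTrain)
    xTest <- as.matrix(xTest)
    if (ncol(xTrain) != ncol(xTest))
        stop("train/test dimension mismatch")
    fit <- fitModel(algorithm, xTrain, yTrain, params, seed = seed)
    predictModel(fit, xTest)
}

#' Run the full 3 x 3 x 3 classification experiment
#'
#' From a preselected, per-patient-normalized cohort: performs one
#' patient-disjoint split, builds the three data representations (raw
#' post-cutoff traces; PCA fitted on training rows at 95% explained
#' variance; the 7 engineered features), derives the two-muscle paradigms
#' by dropping rows of the same split (never re-splitting), balances each
#' training set with SMOTE, tunes each algorithm by stratified
#' cross-validation, and evaluates on the held-out patients.
#'
#' @param cohort a preselected, normalized [MEPCohort-class].
#' @param paradigms,representations,algorithms subsets of the grid to run.
#' @param seed global seed; stage seeds are derived with [deriveSeed()].
#' @param grids hyperparameter grids as in [defaultGrids()].
#' @param cvFolds cross-validation folds for tuning.
#' @param nTrain,nTest patients per side of the split.
#' @param smoteK SMOTE neighbour count.
#' @param varTarget PCA explained-variance target.
#' @return a list with `reports` (list of [EvaluationReport-class], one per
#'   cell, named `algorithm.paradigm.representation`), `split` (patient
#'   assignment), `pcaDims` (retained PCA dimension), and `summary` (a
#'   data.frame of the scores of every cell).
#' @examples
#' \donttest{
#' cfg <- generatorConfig(nPatients = 6,
#'     tracesPerPatient = c(EXT = 12, APB = 12, TA = 12, AH = 12),
#'     blankRate = c(EXT = 0.1, APB = 0.1, TA = 0.2, AH = 0.2))
#' coh <- normalizePatients(preselectCohort(generateCohort(cfg))$accepted)
#' res <- runExperiment(coh, paradigms = "EXT_vs_TA",
#'     representations = "FE", algorithms = "kNN", nTrain = 4, nTest = 2,
#'     grids = defaultGrids(reduced = TRUE), cvFolds = 3)
#' res$summary
#' }
#' @export
runExperiment <- function(cohort, paradigms = paradigmCodes(),
                          representations = representationCodes(),
                          algorithms = c("RF", "kNN", "LogReg"),
                          seed = 1, grids = defaultGrids(),
                          cvFolds = 10, nTrain = 28, nTest = 8,
                          smoteK = 5, varTarget = 0.95) {
    stopifnot(methods::is(cohort, "MEPCohort"), isPreselected(cohort))
    split <- splitByPatient(cohort, nTrain, nTest,
                            seed = deriveSeed(seed, "split"))
    yTrainAll <- as.character(muscle(split$train))
    yTestAll <- as.character(muscle(split$test))

    rawTrain <- t(signalMatrix(split$train))
    rawTest <- t(signalMatrix(split$test))
    pca <- fitPca(rawTrain, varTarget = varTarget)
    pcaTrain <- applyPca(pca, rawTrain)
    pcaTest <- applyPca(pca, rawTest)
    feTrain <- as.matrix(extractFeatures(split$train)[, featureNames()])
    feTest <- as.matrix(extractFeatures(split$test)[, featureNames()])

    repData <- list(RAW = list(train = rawTrain, test = rawTest),
                    PCA = list(train = pcaTrain, test = pcaTest),
                    FE = list(train = feTrain, test = feTest))

    reports <- list()
    for (par in paradigms) {
        classes <- paradigmClasses(par)
        trKeep <- yTrainAll %in% classes
        teKeep <- yTestAll %in% classes
        for (rep in representations) {
            bal <- smoteBalance(repData[[rep]]$train[trKeep, , drop = FALSE],
                                yTrainAll[trKeep], k = smoteK,
                                seed = deriveSeed(seed,
                                                  paste("smote", par, rep)))
            xTest <- repData[[rep]]$test[teKeep, , drop = FALSE]
            yTest <- yTestAll[teKeep]
            for (alg in algorithms) {
                cellSeed <- deriveSeed(seed, paste(alg, par, rep))
                tuned <- tuneHyperparameters(alg, bal$x, bal$y,
                                             grid = grids[[alg]],
                                             cvFolds = cvFolds,
                                             seed = cellSeed)
                out <- trainAndPredict(alg, tuned$best, bal$x, bal$y,
                                       xTest, seed = cellSeed)
                reports[[paste(alg, par, rep, sep = ".")]] <-
                    evaluationReport(out$pred, yTest, out$scores,
                                     algorithm = alg, paradigm = par,
                                     representation = rep,
                                     tuned = tuned$best)
            }
        }
    }
    list(reports = reports, split = split[c("trainPatients", "testPatients")],
         pcaDims = pca@nComponents, summary = summaryTable(reports))
}

#' Tabulate a list of evaluation reports
#'
#' @param reports a list of [EvaluationReport-class] objects.
#' @return a data.frame with one row per cell (algorithm, paradigm,
#'   representation, accuracy, f1_macro, roc_auc).
#' @export
summaryTable <- function(reports) {
    do.call(rbind, lapply(unname(reports), function(r)
        data.frame(algorithm = r@algorithm, paradigm = r@paradigm,
                   representation = r@representation,
                   accuracy = r@accuracy, f1_macro = r@f1Macro,
                   roc_auc = r@rocAuc)))
}
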