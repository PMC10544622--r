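#' Build a run configuration
#'
#' A run configuration is a plain, fully serializable list driving
#' [runPipeline()]: generator settings, split sizes, grid choice, CV folds
#' and the global seed.  [readRunConfig()]/[writeRunConfig()] persist it as
#' YAML; a persisted configuration re-executes to identical outputs.
#'
#' @param nPatients,tracesPerPatient,blankRate,noiseSd generator settings
#'   (see [generatorConfig()]); `NULL` keeps the defaults.
#' @param nTrain,nTest patients per split side.
#' @param reducedGrids use the desk-scale grids of
#'   `defaultGrids(reduced = TRUE)`.
#' @param cvFolds cross-validation folds for tuning.
#' @param paradigms,representations,algorithms experiment grid subsets.
#' @param seed global seed; per-stage seeds are derived via [deriveSeed()].
#' @return a named list.
#' @examples
#' cfg <- runConfig(nPatients = 4, nTrain = 3, nTest = 1)
#' @export
runConfig <- function(nPatients = 36, tracesPerPatient = NULL,
                      blankRate = NULL, noiseSd = 0.001,
                      nTrain = 28, nTest = 8, reducedGrids = FALSE,
                      cvFolds = 10, paradigms = paradigmCodes(),
                      representations = representationCodes(),
                      algorithms = c("RF", "kNN", "LogReg"), seed = 1) {
    list(nPatients = nPatients, tracesPerPatient = tracesPerPatient,
         blankRate = blankRate, noiseSd = noiseSd, nTrain = nTrain,
         nTest = nTest, reducedGrids = reducedGrids, cvFolds = cvFolds,
         paradigms = paradigms, representations = representations,
         algorithms = algorithms, seed = seed)
}

#' @param path YAML file path.
#' @rdname runConfig
#' @export
readRunConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    base <- runConfig()
    unknown <- setdiff(names(cfg), names(base))
    if (length(unknown))
        stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    for (k in c("tracesPerPatient", "blankRate"))
        if (!is.null(cfg[[k]])) cfg[[k]] <- unlist(cfg[[k]])
    utils::modifyList(base, cfg)
}

#' @param config a run configuration list.
#' @rdname runConfig
#' @export
writeRunConfig <- function(config, path) {
    for (k in c("tracesPerPatient", "blankRate"))
        if (!is.null(config[[k]]))
            config[[k]] <- as.list(config[[k]])  # keep names in YAML
    yaml::write_yaml(config, path)
    invisible(path)
}

#' Run the whole pipeline: simulate, preselect, compress, train, evaluate
#'
#' Orchestrates the stages end to end from one configuration: synthetic
#' cohort generation, preselection and per-patient normalization, the
#' 3 x 3 x 3 experiment grid, and report writing.  All artifacts are
#' written under `outDir` together with the configuration (and its MD5
#' hash) and a per-stage count log, so a run is fully reproducible from
#' `(config, seed)`.
#'
#' @param config a list from [runConfig()] or [readRunConfig()].
#' @param outDir output directory (created if needed); `NULL` writes
#'   nothing.
#' @param verbose print per-stage progress.
#' @return a list: `cohort` sizes, `rejections`, `summary` (per-cell
#'   scores), `reports`, `pcaDims`, `configHash`.
#' @examples
#' \donttest{
#' cfg <- runConfig(nPatients = 4,
#'     tracesPerPatient = c(EXT = 10, APB = 10, TA = 10, AH = 10),
#'     blankRate = c(EXT = .1, APB = .1, TA = .2, AH = .2),
#'     nTrain = 3, nTest = 1, reducedGrids = TRUE, cvFolds = 2,
#'     paradigms = "EXT_vs_TA", representations = "FE",
#'     algorithms = "kNN")
#' res <- runPipeline(cfg, outDir = NULL)
#' res$summary
#' }
#' @export
runPipeline <- function(config = runConfig(), outDir = NULL,
                        verbose = TRUE) {
    say <- function(...) if (verbose) message(...)
    gen <- generatorConfig(nPatients = config$nPatients,
                           tracesPerPatient = config$tracesPerPatient,
                           blankRate = config$blankRate,
                           noiseSd = config$noiseSd,
                           seed = deriveSeed(config$seed, "generate"))
    say("simulate: ", gen@nPatients, " patients")
    cohort <- generateCohort(gen)
    say("  generated ", ncol(cohort), " traces")
    pre <- preselectCohort(cohort)
    say("preselect: accepted ", ncol(pre$accepted), ", rejected ",
        nrow(pre$rejections))
    norm <- normalizePatients(pre$accepted)
    say("train/evaluate: ", length(config$algorithms), " x ",
        length(config$paradigms), " x ", length(config$representations),
        " cells")
    res <- runExperiment(norm, paradigms = config$paradigms,
                         representations = config$representations,
                         algorithms = config$algorithms,
                         seed = config$seed,
                         grids = defaultGrids(reduced =
                                                  config$reducedGrids),
                         cvFolds = config$cvFolds,
                         nTrain = config$nTrain, nTest = config$nTest)
    configHash <- NA_character_
    if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        cfgPath <- file.path(outDir, "config.yaml")
        writeRunConfig(config, cfgPath)
        configHash <- unname(tools::md5sum(cfgPath))
        utils::write.table(pre$rejections,
                           file.path(outDir, "rejections.tsv"),
                           sep = "\t", row.names = FALSE, quote = FALSE)
        writeFeatureTable(extractFeatures(norm),
                          file.path(outDir, "features.tsv"))
        summ <- res$summary
        summ$config_hash <- configHash
        summ$seed <- config$seed
        utils::write.table(summ, file.path(outDir, "summary.tsv"),
                           sep = "\t", row.names = FALSE, quote = FALSE)
        tuned <- do.call(rbind, lapply(names(res$reports), function(nm)
            data.frame(cell = nm, parameter = names(res$reports[[nm]]@tuned),
                       value = vapply(res$reports[[nm]]@tuned, format,
                                      character(1)))))
        utils::write.table(tuned, file.path(outDir, "tuned.tsv"),
                           sep = "\t", row.names = FALSE, quote = FALSE)
        counts <- data.frame(
            stage = c("generated", "accepted", "rejected", "train_patients",
                      "test_patients"),
            count = c(ncol(cohort), ncol(pre$accepted),
                      nrow(pre$rejections),
                      length(res$split$trainPatients),
                      length(res$split$testPatients)))
        utils::write.table(counts, file.path(outDir, "counts.tsv"),
                           sep = "\t", row.names = FALSE, quote = FALSE)
    }
    list(nGenerated = ncol(cohort), nAccepted = ncol(pre$accepted),
         rejections = pre$rejections, summary = res$summary,
         reports = res$reports, pcaDims = res$pcaDims,
         split = res$split, configHash = configHash)
}
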