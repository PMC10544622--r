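test_that("peak detection handles degenerate and textbook inputs", {
    expect_equal(nrow(detectPeaks(numeric(2000))), 0)
    expect_equal(nrow(detectPeaks(rep(0.7, 2000))), 0)

    # a 10-sigma triangular pulse peaking at 25 ms over noise of SD sigma;
    # the pulse dominates the rectified-segment SD, so the 2-SD prominence
    # threshold admits the pulse and rejects every noise maximum
    set.seed(7)
    sigma <- 0.01
    x <- rnorm(2000, 0, sigma)
    tri <- 10 * sigma * (1 - abs(seq(-300, 300)) / 301)
    x[201:801] <- x[201:801] + tri
    pk <- detectPeaks(x)
    expect_equal(nrow(pk), 1)
    expect_equal(pk$time_ms[1], 25, tolerance = 0.1)

    # the same pulse placed before the cutoff is invisible
    y <- numeric(2000)
    y[196:204] <- c(1, 2, 3, 4, 5, 4, 3, 2, 1) / 5  # 10 ms
    expect_equal(nrow(detectPeaks(y)), 0)
})

test_that("peak indices and times respect the cutoff and grid", {
    x <- numeric(2000)
    x[351] <- 1  # 0-based index 350 = exactly 17.5 ms
    pk <- detectPeaks(x)
    expect_equal(pk$index, 350)
    expect_equal(pk$time_ms, 17.5)
    expect_true(all(pk$prominence > 0))
})

test_that("plateau maxima are assigned to the leftmost sample", {
    x <- numeric(2000)
    x[601:605] <- 1
    pk <- detectPeaks(x)
    expect_equal(pk$index, 600)
})

test_that("the preselection gate enforces the 1..10 peak rule", {
    # zero peaks: rejected
    r0 <- preselectTrace(numeric(2000))
    expect_false(r0$accepted)
    expect_equal(r0$reason, "no_peaks")

    # 11 distinct qualifying pulses: rejected
    x <- numeric(2000)
    for (i in seq(400, 1900, length.out = 11))
        x[round(i)] <- 1
    r11 <- preselectTrace(x)
    expect_equal(r11$nPeaks, 11)
    expect_false(r11$accepted)
    expect_equal(r11$reason, "too_many_peaks")

    # a clean single-peak trace: accepted, 1650 samples retained
    y <- numeric(2000)
    y[701] <- 1
    ry <- preselectTrace(y)
    expect_true(ry$accepted)
    expect_length(ry$samples, 1650)
    expect_identical(ry$samples, y[351:2000])

    expect_error(preselectTrace(numeric(100)), "2000")
})

test_that("gate decisions match brute-force enumeration on short traces", {
    set.seed(11)
    fs <- 1000  # 64-sample windows at 1 kHz, cutoff 10 ms
    for (i in 1:200) {
        n <- 64
        x <- rnorm(n)
        if (i %% 3 == 0) x <- round(x, 1)      # induce plateaus and ties
        if (i %% 5 == 0) x[20:40] <- x[20:40] + 3
        got <- preselectTrace(x, samplingRate = fs, cutoffMs = 10,
                              expectedLength = n)$accepted
        expect_identical(got, oracleGate(x, fs, cutoffMs = 10),
                         label = paste("case", i))
    }
})

test_that("adding a sub-threshold bump never changes acceptance", {
    set.seed(13)
    for (i in 1:40) {
        x <- rnorm(2000, 0, 0.01)
        x[801] <- 0.2
        base <- preselectTrace(x)
        y <- x
        y[1201] <- y[1201] + 1e-9  # far below any prominence threshold
        expect_identical(preselectTrace(y)$accepted, base$accepted)
    }
})

test_that("per-patient normalization divides by the patient maximum", {
    mk <- function(v) { x <- numeric(1650); x[100:110] <- v; cbind(x) }
    coh <- makePreselectedCohort(
        list(mk(c(rep(1, 5), -2, rep(1, 5))), mk(0.5)),
        muscle = c("APB", "EXT"), patientId = c("p1", "p1"))
    norm <- normalizePatients(coh)
    sig <- signalMatrix(norm)
    expect_equal(max(sig[, 1]), 0.5)
    expect_equal(min(sig[, 1]), -1.0)
    expect_equal(max(abs(sig)), 1)

    # a patient already peaking at 1.0 is unchanged
    coh2 <- makePreselectedCohort(list(mk(1.0), mk(0.25)),
                                  muscle = c("TA", "TA"),
                                  patientId = c("q", "q"))
    expect_equal(signalMatrix(normalizePatients(coh2)),
                 signalMatrix(coh2))

    # two traces with maxima 0.5 and 2.0: both divided by 2
    coh3 <- makePreselectedCohort(list(mk(0.5), mk(2.0)),
                                  muscle = c("AH", "AH"),
                                  patientId = c("r", "r"))
    sig3 <- signalMatrix(normalizePatients(coh3))
    expect_equal(max(sig3[, 1]), 0.25)
    expect_equal(max(sig3[, 2]), 1.0)

    # degenerate patient
    coh4 <- makePreselectedCohort(list(cbind(numeric(1650))), "EXT", "z")
    expect_error(normalizePatients(coh4), "degenerate")
})

test_that("normalization is exact across a generated multi-patient cohort", {
    cfg <- generatorConfig(nPatients = 3, seed = 21,
                           tracesPerPatient = c(EXT = 10, APB = 10))
    pre <- preselectCohort(generateCohort(cfg))
    norm <- normalizePatients(pre$accepted)
    sig <- signalMatrix(norm)
    for (p in unique(patientId(norm)))
        expect_equal(max(abs(sig[, patientId(norm) == p])), 1)
})

test_that("preselection of a cohort records peaks and reasons", {
    cfg <- generatorConfig(nPatients = 2, seed = 33,
                           tracesPerPatient = c(APB = 20))
    coh <- generateCohort(cfg)
    pre <- preselectCohort(coh)
    expect_equal(ncol(pre$accepted) + nrow(pre$rejections), ncol(coh))
    expect_equal(nrow(signalMatrix(pre$accepted)), 1650)
    cd <- SummarizedExperiment::colData(pre$accepted)
    expect_true(all(cd$n_peaks >= 1 & cd$n_peaks <= 10))
    expect_true(all(cd$peak_latency_ms >= 17.5))
    expect_true(all(pre$rejections$reason %in%
                    c("no_peaks", "too_many_peaks")))
    # deterministic: no randomness anywhere in preselection
    pre2 <- preselectCohort(coh)
    expect_identical(signalMatrix(pre$accepted),
                     signalMatrix(pre2$accepted))
})
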