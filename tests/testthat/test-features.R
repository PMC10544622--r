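test_that("onset latency is the first departure from the baseline band", {
    # all-zero trace: no crossing
    expect_true(is.na(onsetLatency(numeric(2000))))

    # noiseless step to 1.0 at 30 ms, back to zero before the last 20 ms
    x <- numeric(2000)
    x[601:1500] <- 1
    expect_equal(onsetLatency(x), 30, tolerance = 0.05)

    # activity confined to before the cutoff is not an onset
    y <- numeric(2000)
    y[100:200] <- 1
    expect_true(is.na(onsetLatency(y)))

    expect_error(onsetLatency(numeric(100)), "baseline")
})

test_that("onset latency is invariant under constant offsets", {
    set.seed(19)
    x <- numeric(2000)
    x[700:900] <- sin(seq(0, 3 * pi, length.out = 201))
    x <- x + rnorm(2000, 0, 0.001)
    o1 <- onsetLatency(x)
    o2 <- onsetLatency(x + 5)
    expect_equal(o1, o2)
})

test_that("peak amplitude is max minus min", {
    expect_equal(peakAmplitude(rep(0.3, 10)), 0)
    th <- seq(0, 2 * pi, length.out = 2001)[-2001]
    expect_equal(peakAmplitude(sin(th)), 2, tolerance = 1e-6)
    expect_equal(peakAmplitude(c(-0.3, 0.1, 0.6)), 0.9)
    expect_error(peakAmplitude(numeric(0)), "empty")
})

test_that("AUC agrees with a rectangular-sum oracle on short traces", {
    set.seed(23)
    for (i in 1:50) {
        x <- rnorm(32)
        fs <- 1000
        got <- traceAuc(x, samplingRate = fs)
        rect <- sum(abs(x)) * 1000 / fs
        # trapezoid vs rectangle differ by exactly half the end weights
        expect_lte(abs(got - rect), (abs(x[1]) + abs(x[32])) / 2 + 1e-12)
        expect_gte(got, 0)
    }
})

test_that("feature extraction yields 7 consistent features per trace", {
    cfg <- generatorConfig(nPatients = 2, seed = 31,
                           tracesPerPatient = c(APB = 15, TA = 15))
    pre <- preselectCohort(generateCohort(cfg))
    norm <- normalizePatients(pre$accepted)
    ft <- extractFeatures(norm)
    expect_equal(sum(colnames(ft) %in% featureNames()), 7)
    expect_equal(nrow(ft), ncol(norm))
    expect_true(all(ft$n_peaks >= 1))
    expect_true(all(ft$auc >= 0))
    # ordering: onset <= first peak <= end of signal
    expect_true(all(ft$onset_latency_ms <= ft$peak_latency_ms + 1e-9))
    expect_true(all(ft$peak_latency_ms <= ft$end_of_signal_ms + 1e-9))
    # n_peaks agrees with the preselection record
    expect_equal(ft$n_peaks,
                 unname(SummarizedExperiment::colData(norm)$n_peaks))
})

test_that("end of signal mirrors onset for a palindromic trace", {
    n <- 1650
    x <- numeric(n)
    burst <- exp(-abs(seq(-200, 200)) / 60) *
        cos(seq(-200, 200) * 2 * pi / 50)
    mid <- 825
    x[(mid - 200):(mid + 200)] <- burst
    x <- x + rev(x)  # exact palindrome
    onset <- onsetLatency(x, cutoffMs = 0)
    eos <- endOfSignal(x)
    total <- (n - 1) * 0.05
    expect_equal(eos, total - onset, tolerance = 0.051)
})

test_that("PCA retains the explained-variance target", {
    # rank-1 data: one component, full variance
    set.seed(37)
    t1 <- rnorm(40)
    x1 <- cbind(t1) %*% rbind(rnorm(10))
    m1 <- fitPca(x1)
    expect_equal(m1@nComponents, 1L)
    expect_equal(sum(m1@varExplained[1]), 1, tolerance = 1e-9)

    # isotropic 3-D cloud: all three components needed for 95%
    x3 <- matrix(rnorm(3000), 1000, 3)
    expect_equal(fitPca(x3)@nComponents, 3L)

    # retained variance >= target on the fitting data, transform centred
    x <- matrix(rnorm(600), 60, 10) %*% diag(c(5:1, rep(0.2, 5)))
    m <- fitPca(x)
    expect_gte(sum(m@varExplained[seq_len(m@nComponents)]), 0.95)
    z <- applyPca(m, x)
    expect_equal(ncol(z), m@nComponents)
    expect_equal(colMeans(z), rep(0, ncol(z)), tolerance = 1e-9,
                 ignore_attr = TRUE)

    # zero-variance matrix: zero components, transform errors
    m0 <- fitPca(matrix(1, 5, 4))
    expect_equal(m0@nComponents, 0L)
    expect_error(applyPca(m0, matrix(1, 2, 4)), "zero")
})
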