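injectedTrace <- function(times, qMean, noiseSd, durationS, fs = 10000,
                          tauRise = 5e-4, tauDecay = 5e-3, seed = 3L) {
    p <- simParams(qCv = 0, noiseSd = 0, qMean = qMean, tauRise = tauRise,
        tauDecay = tauDecay, samplingRate = fs)
    truth <- new("GroundTruth", apTimes = numeric(0),
        syncQuanta = numeric(0), syncTimes = times,
        asyncTimes = numeric(0), asyncExpected = numeric(0),
        miniTimes = numeric(0), occupancyTimes = numeric(0),
        occupancy = numeric(0), contRate = numeric(0),
        replenishedQuanta = numeric(0), trueRrpCharge = 0, truePr = 0,
        trueReplenishmentFlux = 0, quantalCharge = 0,
        englerinWindow = numeric(0))
    tr <- renderCurrent(truth, p, durationS)
    set.seed(seed)
    currentTrace(samples(tr) + rnorm(length(samples(tr)), 0, noiseSd),
        samplingRate = fs)
}

test_that("baseline noise SD is estimated robustly", {
    set.seed(1)
    tr <- currentTrace(rnorm(1e5, 0, 2), samplingRate = 10000)
    expect_equal(baselineNoiseSd(tr), 2, tolerance = 0.05 * 2)
    # constant trace has zero noise
    expect_equal(baselineNoiseSd(constTrace(-30)), 0)
    # sparse large events barely perturb the masked estimate
    times <- seq(0.5, 9.5, by = 0.5)
    tr2 <- injectedTrace(times, qMean = 100, noiseSd = 2, durationS = 10)
    mask <- rep(FALSE, length(samples(tr2)))
    for (t in times) mask[(t * 10000):((t + 0.05) * 10000)] <- TRUE
    expect_equal(baselineNoiseSd(tr2, exclude = mask), 2,
        tolerance = 0.05 * 2)
})

test_that("pure noise yields no detected events", {
    set.seed(2)
    tr <- currentTrace(rnorm(60 * 10000, 0, 2), samplingRate = 10000)
    ev <- detectMinis(tr)
    expect_equal(nrow(ev), 0L)
})

test_that("injected quanta are detected with accurate onsets and amplitudes", {
    times <- seq(1, 58, length.out = 20)
    tr <- injectedTrace(times, qMean = 20, noiseSd = 2, durationS = 60)
    ev <- detectMinis(tr)
    expect_equal(nrow(ev), 20L)
    # onsets within 1 ms of the true event times
    expect_equal(matchEvents(ev$onset, times, tol = 1e-3), 20L)
    # amplitudes unbiased within 5 percent (noise-free injection)
    trClean <- injectedTrace(times, qMean = 20, noiseSd = 0, durationS = 60)
    evClean <- detectMinis(trClean, noiseSd = 2)
    expect_equal(nrow(evClean), 20L)
    expect_lt(max(abs(evClean$amplitude - 20)) / 20, 0.05)
    expect_gt(min(ev$charge), 25)
})

test_that("the charge criterion rejects brief suprathreshold events", {
    # 20 pA events on 2 pA noise pass the amplitude criterion (10 SD) but
    # carry only ~21 fC with a 0.8 ms decay: all must be rejected
    times <- seq(1, 28, length.out = 10)
    tr <- injectedTrace(times, qMean = 20, noiseSd = 2, durationS = 30,
        fs = 50000, tauRise = 1e-4, tauDecay = 8e-4)
    ev <- detectMinis(tr)
    expect_equal(nrow(ev), 0L)
    # the same events with the standard kernel are accepted
    trStd <- injectedTrace(times, qMean = 20, noiseSd = 2, durationS = 30,
        fs = 50000)
    expect_equal(nrow(detectMinis(trStd)), 10L)
})

test_that("detection is deterministic for a fixed trace and config", {
    times <- seq(1, 28, length.out = 15)
    tr <- injectedTrace(times, qMean = 20, noiseSd = 2, durationS = 30)
    expect_identical(detectMinis(tr), detectMinis(tr))
})

test_that("mini statistics summarise counts, rates and intervals", {
    ev <- data.frame(onset = seq(0.5, 59.5, by = 2),
        peakTime = seq(0.5, 59.5, by = 2) + 0.002,
        amplitude = rep(25, 30), charge = rep(120, 30),
        riseTime1090 = rep(0.9, 30), decayTau = rep(4, 30))
    st <- miniStats(ev, 60)
    expect_equal(st@frequency, 0.5)
    expect_equal(st@amplitudeMean, 25)
    expect_equal(length(st@interEventIntervals), 29L)
    expect_equal(unname(interEventCdf(st)(2)), 1)
    stEmpty <- miniStats(emptyEvents <- data.frame(onset = numeric(0),
        amplitude = numeric(0)), 60)
    expect_equal(stEmpty@frequency, 0)
    expect_equal(stEmpty@nEvents, 0L)
})

test_that("simulated spontaneous event counts follow Poisson statistics", {
    proto <- quietProtocol()
    p <- simParams(miniRate0 = 2)
    ca <- simulateCalcium(p, proto, duration = 120)
    freqs <- vapply(1:100, function(s) {
        p@seed <- s
        length(simulatePool(p, ca, proto)@miniTimes) / 120
    }, numeric(1L))
    sem <- sd(freqs) / sqrt(length(freqs))
    expect_lt(abs(mean(freqs) - 2), 3 * sem)
})

test_that("agonist fold change uses a strict responder threshold", {
    tr <- constTrace(-10, durationS = 110)
    mkEvents <- function(n, win)
        data.frame(onset = seq(win[1] + 0.1, win[2] - 0.1,
            length.out = n))
    evEqual <- rbind(mkEvents(100, c(0, 50)), mkEvents(100, c(55, 105)))
    arEq <- agonistResponse(tr, c(0, 50), c(55, 105), evEqual)
    expect_equal(arEq@freqFoldChange, 1)
    expect_false(arEq@responder)
    # 1.19-fold is a failure to respond; 1.20-fold responds
    ev119 <- rbind(mkEvents(100, c(0, 50)), mkEvents(119, c(55, 105)))
    expect_false(agonistResponse(tr, c(0, 50), c(55, 105), ev119)@responder)
    ev120 <- rbind(mkEvents(100, c(0, 50)), mkEvents(120, c(55, 105)))
    expect_true(agonistResponse(tr, c(0, 50), c(55, 105), ev120)@responder)
    # zero baseline events: fold undefined and flagged
    ar0 <- agonistResponse(tr, c(0, 50), c(55, 105), mkEvents(10, c(55, 105)))
    expect_true(is.na(ar0@freqFoldChange))
    expect_match(ar0@flags, "undefined")
})

test_that("the simulated agonist inward current is quantified accurately", {
    proto <- stimulusProtocol(apTimes = numeric(0), trainCount = 0,
        drugWindows = data.frame(label = "EnglerinA", start = 25, end = 45))
    p <- simParams(englerinMode = TRUE, seed = 7L)
    sim <- simulateExperiment(p, proto, duration = 60)
    ev <- detectMinis(sim$trace)
    ar <- agonistResponse(sim$trace, c(2, 22), c(25, 45), ev)
    expect_lt(abs(ar@maxInwardCurrent - 500) / 500, 0.1)
    expect_gt(ar@freqFoldChange, 1.2)
    expect_true(ar@responder)
})
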