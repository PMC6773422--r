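detSim <- function(...) {
    p <- simParams(deterministic = TRUE, ...)
    proto <- stimulusProtocol()
    sim <- simulateExperiment(p, proto)
    list(p = p, proto = proto, sim = sim,
        tm = measureTrain(sim$trace, proto))
}

test_that("a constant offset current is pure asynchronous charge", {
    proto <- stimulusProtocol()
    fs <- 10000
    # -20 pA standing current developing with the first stimulus at 0.2 s
    cur <- rep(0, 2.5 * fs)
    cur[(0.2 * fs + 1):(2.5 * fs)] <- -20
    tr <- currentTrace(cur, samplingRate = fs)
    tm <- measureTrain(tr, proto)
    expect_lt(max(abs(charges(tm, "sync"))), 1e-6)
    expect_equal(charges(tm, "async"), rep(20 * 0.05, 40),
        tolerance = 1e-6)
    # local pre-stimulus baselines absorb the standing current from the
    # second stimulus on
    expect_lt(max(abs(amplitudes(tm)[-1L])), 1e-9)
})

test_that("fully decaying quanta give zero asynchronous charge", {
    d <- detSim(k0 = 0, kCa = 0, jTrpc = 0, asyncGain = 0, miniRate0 = 0)
    expect_lt(max(abs(charges(d$tm, "async"))), 0.01)
    expect_equal(charges(d$tm, "sync"), charges(d$tm, "total"),
        tolerance = 1e-3)
})

test_that("measured synchronous charge tracks the simulated quanta", {
    d <- detSim(jTrpc = 4000)
    trueCharge <- d$sim$truth@syncQuanta * d$sim$truth@quantalCharge
    relErr <- abs(charges(d$tm, "sync") - trueCharge) / trueCharge
    expect_lt(max(relErr), 0.05)
})

test_that("charge decomposition is conservative on every input", {
    d <- detSim(jTrpc = 8000)
    expect_lt(max(abs(d$tm@syncCharge + d$tm@asyncCharge -
        d$tm@totalCharge)), 1e-9)
    expect_true(all(diff(d$tm@cumulativeTotal) >= 0))
})

test_that("back-extrapolation intercepts match closed forms", {
    # constant charge: the cumulative line passes through the origin
    tm <- metricsFromCharges(rep(2.5, 40))
    expect_equal(estimateRrpTrain(tm)$intercept, 0, tolerance = 1e-9)
    # geometric depletion, p = 0.5: cumulative flat at Q for late stimuli
    Q <- 37.3
    p <- 0.5
    k <- seq_len(40)
    sync <- Q * p * (1 - p)^(k - 1)
    est <- estimateRrpTrain(metricsFromCharges(sync))
    expect_equal(est$rrpCharge, Q, tolerance = 1e-6 * Q)
    expect_true(est$steadyStateReached)
})

test_that("regressions agree with a brute-force OLS oracle", {
    d <- detSim(jTrpc = 4000)
    cfg <- analysisConfig()
    nS <- 40L
    idx <- (nS - cfg@regressionPointsSync + 1L):nS
    oracle <- olsBrute(idx, d$tm@cumulativeSync[idx])
    est <- estimateRrpTrain(d$tm, cfg)
    expect_equal(est$intercept, oracle$intercept,
        tolerance = 1e-9 * max(1, abs(oracle$intercept)))
    idxT <- (nS - cfg@regressionPointsTotal + 1L):nS
    oracleT <- olsBrute(idxT, d$tm@cumulativeTotal[idxT])
    rep <- replenishmentRate(d$tm, cfg, 20)
    expect_equal(rep$ratePerStimulus, oracleT$slope,
        tolerance = 1e-9 * abs(oracleT$slope))
})

test_that("negative intercepts are flagged undefined, never clamped", {
    # accelerating late-train charges drive the intercept negative
    sync <- c(rep(1, 30), seq(2, 20, length.out = 10))
    est <- estimateRrpTrain(metricsFromCharges(sync))
    expect_true(est$undefined)
    expect_true(is.na(est$rrpCharge))
    expect_lt(est$intercept, 0)
    expect_true(is.na(releaseProbability(metricsFromCharges(sync),
        est$rrpCharge)))
})

test_that("release probability recovers the simulated pR", {
    d <- detSim(k0 = 0, kCa = 0, jTrpc = 0, asyncGain = 0, miniRate0 = 0)
    est <- estimateRrpTrain(d$tm)
    pr <- releaseProbability(d$tm, est$rrpCharge)
    expect_lt(abs(pr - 0.3), 0.02)
    # trivial identity
    tm <- metricsFromCharges(c(5, rep(1, 39)))
    expect_equal(releaseProbability(tm, 5), 1)
})

test_that("replenishment slope converts to pC per second", {
    tm <- metricsFromCharges(rep(1.7, 40))
    rep <- replenishmentRate(tm, analysisConfig(), 20)
    expect_equal(rep$ratePerSecond, 20 * 1.7, tolerance = 1e-9)
    expect_equal(rep$ratePerStimulus, 1.7, tolerance = 1e-12)
    tmZero <- metricsFromCharges(c(rep(3, 30), rep(0, 10)))
    expect_equal(replenishmentRate(tmZero)$ratePerSecond, 0,
        tolerance = 1e-9)
})

test_that("measured replenishment rate matches the simulator ledger", {
    for (j in c(0, 4000)) {
        p <- simParams(deterministic = TRUE, jTrpc = j)
        proto <- stimulusProtocol()
        sim <- simulateExperiment(p, proto)
        tm <- analyzeTrain(sim$trace, proto)
        expect_lt(abs(tm@replenishmentRate -
            sim$truth@trueReplenishmentFlux) /
            sim$truth@trueReplenishmentFlux, 0.1)
    }
})

test_that("plasticity indices follow their definitions and tie-break", {
    tm <- metricsFromCharges(rep(1, 40), amps = rep(3, 40))
    pl <- plasticityIndices(tm)
    expect_equal(pl$ppr, 1)
    expect_equal(pl$steRatio, 1)
    expect_equal(pl$plasticityClass, "STD")   # ratio of exactly 1 is STD
    amps <- 3 * 0.5^(0:39)
    pl2 <- plasticityIndices(metricsFromCharges(rep(1, 40), amps = amps))
    expect_equal(pl2$steRatio, 2^-9)
    pl3 <- plasticityIndices(metricsFromCharges(rep(1, 40),
        amps = c(0, rep(1, 39))))
    expect_true(is.na(pl3$steRatio))
    expect_match(pl3$flags, "noise floor")
})

test_that("few-stimulus inputs are rejected as configured", {
    tm <- metricsFromCharges(rep(1, 3))
    expect_error(estimateRrpTrain(tm), "configuration error")
    expect_error(plasticityIndices(tm), "10")
})
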