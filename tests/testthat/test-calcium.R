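test_that("Hill activation matches its defining points", {
    expect_equal(hillActivation(635, 635, 2), 0.5)
    expect_equal(hillActivation(635, 635, 1.7), 0.5)
    expect_equal(hillActivation(0, 635, 2), 0)
    # algebraic solution of hill(c) = 0.9: c = ec50 * 9^(1/n)
    for (n in c(1, 2, 4))
        expect_equal(hillActivation(635 * 9^(1 / n), 635, n), 0.9,
            tolerance = 1e-12)
    # strictly increasing
    cs <- seq(0, 3000, by = 50)
    expect_true(all(diff(hillActivation(cs, 635, 2)) > 0))
    expect_error(hillActivation(-1, 635, 2), "negative")
    expect_error(hillActivation(100, 0, 2), "ec50")
})

test_that("chelation capture length reproduces the diffusion estimate", {
    len <- egtaCaptureLength(2.2e-6, 1e-4)
    expect_equal(len, sqrt(6 * 2.2e-6 * 1e-4) * 1e7)
    expect_equal(len, 363.3, tolerance = 1e-3)
    expect_gt(len, 350)
    # square-root scaling: quadrupling tau doubles the length
    expect_equal(egtaCaptureLength(2.2e-6, 4e-4) / len, 2, tolerance = 1e-12)
    # tau -> 0 limit
    expect_lt(egtaCaptureLength(2.2e-6, 1e-12), 0.1)
    expect_error(egtaCaptureLength(0, 1e-4), "domain")
})

test_that("single-AP calcium decays mono-exponentially without TRPC", {
    p <- simParams(jTrpc = 0, deterministic = TRUE)
    proto <- stimulusProtocol(apTimes = 0.1, trainCount = 1,
        trainFrequency = 20)
    ca <- simulateCalcium(p, proto, duration = 1)
    sel <- ca@times >= 0.1
    expected <- p@cRest + p@deltaCap *
        exp(-(ca@times[sel] - 0.1) / p@tauClear)
    expect_lt(max(abs(ca@concentration[sel] - expected)) / p@deltaCap, 0.01)
})

test_that("TRPC influx raises the train calcium peak and slows its decay", {
    proto <- stimulusProtocol()
    ca0 <- simulateCalcium(simParams(jTrpc = 0), proto, duration = 3)
    caJ <- simulateCalcium(simParams(jTrpc = 8000), proto, duration = 3)
    expect_gt(max(caJ@concentration), max(ca0@concentration))
    # supra-resting fraction remaining 300 ms after the train end
    tEnd <- 2.2
    frac <- function(ca) {
        at <- function(t) ca@concentration[which.min(abs(ca@times - t))]
        (at(tEnd + 0.3) - ca@restingCa) / (at(tEnd) - ca@restingCa)
    }
    expect_gt(frac(caJ), frac(ca0))
})

test_that("EGTA buffering scales the train-evoked calcium rise down", {
    proto <- stimulusProtocol()
    pHi <- simParams(jTrpc = 8000)
    pEg <- simParams(jTrpc = 8000, egtaMode = TRUE, egtaKappa = 9)
    caHi <- simulateCalcium(pHi, proto, duration = 3)
    caEg <- simulateCalcium(pEg, proto, duration = 3)
    riseHi <- max(caHi@concentration) - caHi@restingCa
    riseEg <- max(caEg@concentration) - caEg@restingCa
    expect_lt(riseEg / riseHi, 1 / (1 + 9) * 1.1)
})

test_that("calcium and occupancy are stable at rest over 60 s", {
    # an AP at 59.9 s forces full Euler integration of the quiescent epoch
    p <- simParams(jTrpc = 8000, deterministic = TRUE)
    proto <- stimulusProtocol(apTimes = 59.9, trainCount = 1)
    ca <- simulateCalcium(p, proto, duration = 60)
    pre <- ca@times < 59.5
    expect_lt(max(abs(ca@concentration[pre] - ca@restingCa)) /
        ca@restingCa, 0.01)
    truth <- simulatePool(p, ca, proto)
    occPre <- truth@occupancy[truth@occupancyTimes < 59.5]
    expect_lt(max(abs(occPre - p@nMax)) / p@nMax, 0.01)
})
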