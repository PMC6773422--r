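depletionParams <- function(...) {
    simParams(k0 = 0, kCa = 0, jTrpc = 0, asyncGain = 0, miniRate0 = 0,
        deterministic = TRUE, ...)
}

test_that("pure depletion follows the geometric closed form", {
    p <- depletionParams()
    proto <- stimulusProtocol()
    sim <- simulateExperiment(p, proto)
    k <- seq_len(40)
    expected <- p@nMax * p@pR * (1 - p@pR)^(k - 1)
    expect_equal(sim$truth@syncQuanta, expected, tolerance = 1e-12)
})

test_that("full release on the first AP empties the pool", {
    p <- depletionParams(pR = 1)
    proto <- stimulusProtocol(trainCount = 5)
    ca <- simulateCalcium(p, proto)
    truth <- simulatePool(p, ca, proto)
    expect_equal(truth@syncQuanta, c(300, 0, 0, 0, 0))
})

test_that("stochastic first-AP release matches the binomial expectation", {
    proto <- stimulusProtocol(trainCount = 2)
    p <- simParams(k0 = 0, kCa = 0, jTrpc = 0, asyncGain = 0,
        miniRate0 = 0, nMax = 100L, pR = 0.3)
    ca <- simulateCalcium(p, proto)
    firsts <- vapply(1:500, function(s) {
        p@seed <- s
        simulatePool(p, ca, proto)@syncQuanta[1L]
    }, numeric(1L))
    sem <- sd(firsts) / sqrt(length(firsts))
    expect_lt(abs(mean(firsts) - 30), 3 * sem)
    expect_equal(sd(firsts), sqrt(100 * 0.3 * 0.7), tolerance = 0.15)
})

test_that("stochastic mode requires a seed", {
    p <- simParams(seed = NA_integer_)
    proto <- stimulusProtocol(trainCount = 2)
    ca <- simulateCalcium(p, proto)
    expect_error(simulatePool(p, ca, proto), "seed")
})

test_that("vesicle conservation holds exactly in deterministic mode", {
    for (j in c(0, 8000)) {
        p <- simParams(jTrpc = j, deterministic = TRUE)
        sim <- simulateExperiment(p, stimulusProtocol())
        released <- sum(sim$truth@syncQuanta) + sum(sim$truth@asyncExpected)
        budget <- p@nMax +
            sim$truth@replenishedQuanta[length(sim$truth@replenishedQuanta)]
        expect_lte(released, budget + 1)
    }
})

test_that("stochastic means match the deterministic expectation", {
    proto <- stimulusProtocol(trainCount = 10)
    pDet <- simParams(deterministic = TRUE)
    ca <- simulateCalcium(pDet, proto)
    det <- simulatePool(pDet, ca, proto)
    pSto <- simParams()
    nSeeds <- 200
    sync1 <- syncTot <- asyncN <- numeric(nSeeds)
    for (s in seq_len(nSeeds)) {
        pSto@seed <- s
        tr <- simulatePool(pSto, ca, proto)
        sync1[s] <- tr@syncQuanta[1L]
        syncTot[s] <- sum(tr@syncQuanta)
        asyncN[s] <- length(tr@asyncTimes)
    }
    sem <- function(x) sd(x) / sqrt(length(x))
    expect_lt(abs(mean(sync1) - det@syncQuanta[1L]), 3 * sem(sync1))
    expect_lt(abs(mean(syncTot) - sum(det@syncQuanta)), 3 * sem(syncTot))
    expect_lt(abs(mean(asyncN) - sum(det@asyncExpected)), 3 * sem(asyncN))
})

test_that("identical seeds give bit-identical simulated experiments", {
    p <- simParams(seed = 11L)
    proto <- stimulusProtocol(trainCount = 10)
    a <- simulateExperiment(p, proto)
    b <- simulateExperiment(p, proto)
    expect_identical(samples(a$trace), samples(b$trace))
    expect_identical(a$truth@syncQuanta, b$truth@syncQuanta)
    expect_identical(a$truth@miniTimes, b$truth@miniTimes)
})
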