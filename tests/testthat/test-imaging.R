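constStack <- function(level = 100, nFrames = 22, dims = c(32, 32)) {
    imagingStack(array(level, c(nFrames, dims)), frameRate = 5,
        prestimulusFrames = 3L)
}

test_that("a constant stack has zero dF/F0 everywhere", {
    rt <- computeDff(constStack(), c(5, 5))
    expect_equal(dff(rt), rep(0, 22))
    expect_false(rt@undefined)
})

test_that("a stepwise doubling gives dF/F0 of one", {
    arr <- array(100, c(22, 32, 32))
    arr[4:22, , ] <- 200
    rt <- computeDff(imagingStack(arr, prestimulusFrames = 3L), c(9, 9))
    expect_equal(dff(rt)[1:3], rep(0, 3))
    expect_equal(dff(rt)[4:22], rep(1, 19))
})

test_that("dF/F0 is invariant to multiplicative gain", {
    p <- simParams(deterministic = TRUE, jTrpc = 8000)
    ca <- simulateCalcium(p, stimulusProtocol(trainStart = 0.6),
        duration = 5)
    ri <- renderImaging(ca, 3, gcampParams(photonNoise = FALSE), seed = 2)
    rt1 <- computeDff(ri$stack, unlist(ri$rois[1, ]), allRois = ri$rois)
    gained <- imagingStack(ri$stack@frames * 3.7,
        prestimulusFrames = ri$stack@prestimulusFrames)
    rt2 <- computeDff(gained, unlist(ri$rois[1, ]), allRois = ri$rois)
    expect_equal(dff(rt2), dff(rt1), tolerance = 1e-12)
})

test_that("noise-free dF/F0 matches the reporter model closed form", {
    p <- simParams(deterministic = TRUE, jTrpc = 4000)
    ca <- simulateCalcium(p, stimulusProtocol(trainStart = 0.6),
        duration = 5)
    g <- gcampParams(photonNoise = FALSE)
    ri <- renderImaging(ca, 2, g, seed = 4)
    rt <- computeDff(ri$stack, unlist(ri$rois[1, ]), allRois = ri$rois)
    nFrames <- dim(ri$stack@frames)[1L]
    cbar <- vapply(seq_len(nFrames), function(k)
        mean(ca@concentration[ca@times >= (k - 1) / 5 &
            ca@times < k / 5]), numeric(1L))
    fModel <- g$fRest * (1 + g$rMax * hillActivation(cbar, g$kd, g$nHill))
    f0 <- mean(fModel[1:3])
    expect_equal(dff(rt), (fModel - f0) / f0, tolerance = 1e-6)
    # monotone transform: ordering of frame-averaged calcium is preserved
    expect_equal(order(dff(rt)), order(cbar))
})

test_that("the responsiveness threshold is strict at 3 background SDs", {
    mk <- function(maxd) new("RoiTrace", roiOrigin = c(1L, 1L),
        roiSize = 4L, dff = c(rep(0, 5), maxd, rep(0, 14)),
        backgroundSd = 1, f0 = 100, undefined = FALSE)
    expect_false(detectResponsive(list(mk(2.9)))[1L])
    expect_false(detectResponsive(list(mk(3.0)))[1L])
    expect_true(detectResponsive(list(mk(3.1)))[1L])
})

test_that("slope metrics recover exact linear ramps", {
    ramp <- new("RoiTrace", roiOrigin = c(1L, 1L), roiSize = 4L,
        dff = 0.02 * (0:21), backgroundSd = 0.001, f0 = 100,
        undefined = FALSE)
    m <- dffMetrics(ramp)
    expect_equal(m@slopeHfs, 0.02, tolerance = 1e-12)
    expect_equal(m@slopePost, 0.02, tolerance = 1e-12)
    flat <- new("RoiTrace", roiOrigin = c(1L, 1L), roiSize = 4L,
        dff = rep(0.5, 22), backgroundSd = 0.001, f0 = 100,
        undefined = FALSE)
    expect_equal(dffMetrics(flat)@slopeHfs, 0)
    short <- new("RoiTrace", roiOrigin = c(1L, 1L), roiSize = 4L,
        dff = rep(0, 10), backgroundSd = 0.001, f0 = 100,
        undefined = FALSE)
    expect_error(dffMetrics(short), "frames")
})

test_that("a responding simulated synapse is classed responsive", {
    p <- simParams(deterministic = TRUE, jTrpc = 8000)
    ca <- simulateCalcium(p, stimulusProtocol(trainStart = 0.6),
        duration = 5)
    ri <- renderImaging(ca, 2, gcampParams(photonNoise = TRUE), seed = 9)
    rts <- computeDffAll(ri$stack, ri$rois)
    expect_true(all(detectResponsive(rts)))
})

test_that("imaging-train pairing joins by cell and ranks correlations", {
    imaging <- data.frame(cellId = c("a", "b", "c"),
        slopeHfs = c(0.01, 0.03, 0.02))
    train <- data.frame(cellId = c("a", "b", "c"),
        replenishmentRate = c(100, 300, 200))
    pr <- pairWithTrain(imaging, train)
    expect_equal(nrow(pr$table), 3L)
    expect_equal(pr$rankCorrelation, 1)
    expect_equal(length(pr$unmatched), 0L)
    # partial overlap excludes unmatched ids
    pr2 <- pairWithTrain(imaging,
        data.frame(cellId = c("b", "d"), replenishmentRate = c(1, 2)))
    expect_equal(pr2$table$cellId, "b")
    expect_true(all(c("a", "c", "d") %in% pr2$unmatched))
    expect_warning(pairWithTrain(imaging,
        data.frame(cellId = "z", replenishmentRate = 1)), "matching")
})
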