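test_that("trace round trip is lossless in samples and metadata", {
    tr <- currentTrace(sin(seq_len(5000)) * 50 - 20, samplingRate = 10000,
        metadata = list(cell = "c01", condition = "EGTA",
            drug_windows = list(label = "TEA", start = 1, end = 2)))
    path <- withr::local_tempfile(fileext = ".csv")
    writeTrace(tr, path)
    back <- readTrace(path)
    expect_lt(max(abs(samples(back) - samples(tr))), 1e-9)
    expect_equal(samplingRate(back), 10000)
    expect_equal(back@metadata$condition, "EGTA")
    expect_equal(back@metadata$drug_windows$label, "TEA")
})

test_that("reader applies declared nA to pA conversion", {
    path <- withr::local_tempfile(fileext = ".csv")
    utils::write.csv(data.frame(time_s = c(0, 1e-4, 2e-4),
        current_pA = c(-1.5, -2, 0.5)), path, row.names = FALSE)
    jsonlite::write_json(list(sampling_rate_hz = 10000, units = "nA"),
        paste0(path, ".json"), auto_unbox = TRUE)
    tr <- readTrace(path)
    expect_equal(samples(tr), c(-1500, -2000, 500))
})

test_that("invalid traces and missing sidecars are rejected", {
    expect_error(currentTrace(c(1, NaN, 3), 10000), "finite")
    expect_error(currentTrace(numeric(0), 10000), "2 samples")
    expect_error(currentTrace(rnorm(10), -1), "samplingRate")
    path <- withr::local_tempfile(fileext = ".csv")
    utils::write.csv(data.frame(time_s = 0:1, current_pA = c(0, 1)), path,
        row.names = FALSE)
    expect_error(readTrace(path), "sidecar")
    expect_error(readTrace("/nonexistent/file.csv"), "exist")
})

test_that("protocol shorthand expands to explicit AP times", {
    path <- withr::local_tempfile(fileext = ".json")
    jsonlite::write_json(list(train = list(freq = 20, count = 40, t0 = 0.1)),
        path, auto_unbox = TRUE)
    p <- loadProtocol(path)
    expect_equal(length(apTimes(p)), 40L)
    expect_equal(apTimes(p)[1], 0.1)
    expect_equal(apTimes(p)[40], 2.05)
    expect_equal(diff(apTimes(p)), rep(0.05, 39))
})

test_that("the default recovery specification expands to 8 intervals", {
    path <- withr::local_tempfile(fileext = ".json")
    jsonlite::write_json(list(train = list(freq = 20, count = 40, t0 = 0.2),
        recovery = "default"), path, auto_unbox = TRUE)
    p <- loadProtocol(path)
    expect_equal(recoveryIntervals(p),
        c(0.020, 0.050, 0.150, 0.350, 0.650, 1.150, 2.150, 4.150))
})

test_that("degenerate protocols are rejected", {
    path <- withr::local_tempfile(fileext = ".json")
    jsonlite::write_json(list(train = list(freq = 20, count = 0)), path,
        auto_unbox = TRUE)
    expect_error(loadProtocol(path), "count")
    expect_error(stimulusProtocol(apTimes = c(0.2, 0.1)), "increasing")
    expect_error(stimulusProtocol(drugWindows = data.frame(
        label = c("a", "b"), start = c(1, 2), end = c(3, 4))), "overlap")
})

test_that("protocol and config JSON round trips preserve every field", {
    p <- stimulusProtocol(recoveryIntervals = "default",
        sucroseWindow = c(3, 8),
        drugWindows = data.frame(label = "EnglerinA", start = 10, end = 20))
    path <- withr::local_tempfile(fileext = ".json")
    writeProtocol(p, path)
    q <- loadProtocol(path)
    expect_equal(apTimes(q), apTimes(p))
    expect_equal(q@sucroseWindow, c(3, 8))
    expect_equal(q@drugWindows$label, "EnglerinA")

    cfg <- analysisConfig(regressionPointsTotal = 4L, steadyStateWindow = 0.004)
    cpath <- withr::local_tempfile(fileext = ".json")
    writeConfig(cfg, cpath)
    cfg2 <- loadConfig(cpath)
    for (s in slotNames("AnalysisConfig"))
        expect_equal(slot(cfg2, s), slot(cfg, s), label = s)
    jsonlite::write_json(list(noSuchKey = 1), cpath, auto_unbox = TRUE)
    expect_error(loadConfig(cpath), "unknown config")
})

test_that("imaging stack TIFF round trip preserves counts", {
    arr <- array(sample(0:4000, 6 * 16 * 16, TRUE), c(6, 16, 16))
    st <- imagingStack(arr, frameRate = 5, prestimulusFrames = 3L)
    path <- withr::local_tempfile(fileext = ".tif")
    writeStack(st, path)
    back <- readStack(path)
    expect_lt(max(abs(back@frames - arr)), 1e-3)
    expect_equal(back@frameRate, 5)
    expect_equal(back@prestimulusFrames, 3L)
})

test_that("analyses reject traces shorter than the protocol window", {
    tr <- constTrace(0, durationS = 1)
    expect_error(measureTrain(tr, stimulusProtocol(), analysisConfig()),
        "does not cover")
    expect_error(analyzeSucrose(tr, c(0.2, 1.5)), "does not cover")
})
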