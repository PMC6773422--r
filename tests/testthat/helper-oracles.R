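# Brute-force ordinary least squares via explicit normal equations,
# independent of the stats::lm path used by the package.
olsBrute <- function(x, y) {
    n <- length(x)
    sx <- sum(x); sy <- sum(y)
    sxx <- sum(x * x); sxy <- sum(x * y)
    slope <- (n * sxy - sx * sy) / (n * sxx - sx * sx)
    intercept <- (sy - slope * sx) / n
    list(intercept = intercept, slope = slope)
}

# Greedy one-to-one matching of detected event onsets to true onsets.
matchEvents <- function(detected, truth, tol) {
    used <- logical(length(detected))
    hits <- 0L
    for (t in truth) {
        d <- abs(detected - t)
        d[used] <- Inf
        i <- which.min(d)
        if (length(i) && is.finite(d[i]) && d[i] <= tol) {
            used[i] <- TRUE
            hits <- hits + 1L
        }
    }
    hits
}

# A constant-current trace (pA, signed as recorded).
constTrace <- function(level, durationS = 3, fs = 10000) {
    currentTrace(rep(level, durationS * fs), samplingRate = fs)
}

# Protocol with no stimuli (spontaneous-activity recording).
quietProtocol <- function() {
    stimulusProtocol(apTimes = numeric(0), trainCount = 0)
}

# TrainMetrics built directly from per-stimulus charges (bypasses trace
# measurement; used for regression unit tests).
metricsFromCharges <- function(sync, total = sync, amps = NULL) {
    n <- length(sync)
    if (is.null(amps)) amps <- rep(1, n)
    new("TrainMetrics", amplitudes = amps, totalCharge = total,
        asyncCharge = total - sync, syncCharge = sync,
        cumulativeSync = cumsum(sync), cumulativeTotal = cumsum(total))
}
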