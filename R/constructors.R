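#' Construct a CurrentTrace
#'
#' @param samples numeric vector of currents in pA (inward negative).
#' @param samplingRate sampling rate in Hz.
#' @param startTime time of the first sample (s).
#' @param channelLabel channel label.
#' @param metadata named list of metadata.
#' @return A \linkS4class{CurrentTrace}.
#' @examples
#' tr <- currentTrace(rnorm(1000), samplingRate = 10000)
#' duration(tr)
#' @export
currentTrace <- function(samples, samplingRate, startTime = 0,
                         channelLabel = "Imon", metadata = list()) {
    new("CurrentTrace", samples = as.numeric(samples),
        samplingRate = samplingRate, startTime = startTime,
        channelLabel = channelLabel, metadata = metadata)
}

#' Construct a StimulusProtocol
#'
#' Either pass explicit \code{apTimes}, or a train shorthand
#' (\code{trainFrequency}, \code{trainCount}, \code{trainStart}) which is
#' expanded to explicit AP times. \code{recoveryIntervals = "default"}
#' expands to the standard eight test-pulse intervals
#' 20, 50, 150, 350, 650, 1150, 2150 and 4150 ms.
#'
#' @param apTimes explicit AP times (s), or NULL to use the shorthand.
#' @param trainFrequency train frequency in Hz.
#' @param trainCount number of APs in the train.
#' @param trainStart time of the first AP (s).
#' @param recoveryIntervals numeric intervals (s) or \code{"default"}.
#' @param sucroseWindow optional numeric length-2 (start, end) in s.
#' @param drugWindows optional data.frame(label, start, end).
#' @param basalFrequency basal stimulation frequency (Hz).
#' @return A \linkS4class{StimulusProtocol}.
#' @examples
#' p <- stimulusProtocol(trainFrequency = 20, trainCount = 40)
#' head(apTimes(p))
#' @export
stimulusProtocol <- function(apTimes = NULL, trainFrequency = 20,
                             trainCount = 40, trainStart = 0.2,
                             recoveryIntervals = numeric(0),
                             sucroseWindow = numeric(0),
                             drugWindows = NULL, basalFrequency = 0.2) {
    if (is.null(apTimes)) {
        trainCount <- as.integer(trainCount)
        if (trainCount < 1L)
            stop("trainCount must be >= 1")
        apTimes <- trainStart + seq(0L, trainCount - 1L) / trainFrequency
    } else {
        trainCount <- as.integer(trainCount)
    }
    if (identical(recoveryIntervals, "default"))
        recoveryIntervals <- defaultRecoveryIntervals()
    if (is.null(drugWindows))
        drugWindows <- data.frame(label = character(0), start = numeric(0),
            end = numeric(0), stringsAsFactors = FALSE)
    new("StimulusProtocol", apTimes = as.numeric(apTimes),
        trainFrequency = trainFrequency, trainCount = trainCount,
        recoveryIntervals = as.numeric(recoveryIntervals),
        sucroseWindow = as.numeric(sucroseWindow),
        drugWindows = drugWindows, basalFrequency = basalFrequency)
}

#' Standard recovery test-pulse intervals
#'
#' The eight intervals (s after train end) at which recovery test pulses
#' are delivered: 20, 50, 150, 350, 650, 1150, 2150 and 4150 ms.
#'
#' @return numeric vector of 8 intervals in s.
#' @export
defaultRecoveryIntervals <- function() {
    c(0.020, 0.050, 0.150, 0.350, 0.650, 1.150, 2.150, 4.150)
}

#' Construct an AnalysisConfig
#'
#' All arguments default to the package's standard analysis constants; see
#' \linkS4class{AnalysisConfig} for their meaning.
#'
#' @param ... named slot overrides, e.g.
#'   \code{analysisConfig(regressionPointsTotal = 4L)}.
#' @return An \linkS4class{AnalysisConfig}.
#' @export
analysisConfig <- function(...) {
    args <- list(...)
    intSlots <- c("regressionPointsSync", "regressionPointsTotal",
        "dffRoiSize", "slopeHfsPoints", "slopePostPoints")
    for (s in intersect(names(args), intSlots))
        args[[s]] <- as.integer(args[[s]])
    do.call(new, c(list(Class = "AnalysisConfig"), args))
}

#' Construct a SimParams object
#'
#' All arguments default to the package's reference simulation conditions;
#' see \linkS4class{SimParams} for the model and units.
#'
#' @param ... named slot overrides, e.g. \code{simParams(jTrpc = 0)}.
#' @return A \linkS4class{SimParams}.
#' @examples
#' p <- simParams(jTrpc = 0, deterministic = TRUE)
#' @export
simParams <- function(...) {
    args <- list(...)
    if ("nMax" %in% names(args)) args$nMax <- as.integer(args$nMax)
    if ("seed" %in% names(args)) args$seed <- as.integer(args$seed)
    do.call(new, c(list(Class = "SimParams"), args))
}

#' Construct an ImagingStack
#'
#' @param frames 3-D numeric array (frame, row, col) of counts.
#' @param frameRate acquisition rate (Hz).
#' @param prestimulusFrames frames acquired before the stimulus.
#' @param pixelSize pixel size (micrometres).
#' @return An \linkS4class{ImagingStack}.
#' @export
imagingStack <- function(frames, frameRate = 5, prestimulusFrames = 3L,
                         pixelSize = 0.4) {
    new("ImagingStack", frames = frames, frameRate = frameRate,
        prestimulusFrames = as.integer(prestimulusFrames),
        pixelSize = pixelSize)
}

## ---------------------------------------------------------------------------
## Accessors
## ---------------------------------------------------------------------------

#' @rdname currentTrace
#' @param x a CurrentTrace.
#' @export
samples <- function(x) x@samples

#' @rdname currentTrace
#' @export
samplingRate <- function(x) x@samplingRate

#' Trace duration in seconds
#' @param x a CurrentTrace.
#' @return duration (s) = sample count / sampling rate.
#' @export
duration <- function(x) length(x@samples) / x@samplingRate

#' Sample times of a trace
#' @param x a CurrentTrace.
#' @return numeric vector of sample times (s).
#' @export
traceTimes <- function(x)
    x@startTime + (seq_along(x@samples) - 1L) / x@samplingRate

#' @rdname stimulusProtocol
#' @param x a StimulusProtocol.
#' @export
apTimes <- function(x) x@apTimes

#' @rdname stimulusProtocol
#' @export
recoveryIntervals <- function(x) x@recoveryIntervals

#' Per-stimulus amplitudes of a TrainMetrics object
#' @param x a TrainMetrics.
#' @return numeric vector of peak amplitudes (pA).
#' @export
amplitudes <- function(x) x@amplitudes

#' Per-stimulus charges of a TrainMetrics object
#' @param x a TrainMetrics.
#' @param component one of "total", "sync", "async".
#' @return numeric vector of charges (pC).
#' @export
charges <- function(x, component = c("total", "sync", "async")) {
    switch(match.arg(component), total = x@totalCharge,
        sync = x@syncCharge, async = x@asyncCharge)
}

#' RRP charge estimate of a TrainMetrics object
#' @param x a TrainMetrics.
#' @return RRP charge (pC) or NA when undefined.
#' @export
rrpCharge <- function(x) x@rrpCharge

#' Release probability stored in a TrainMetrics object
#' @param x a TrainMetrics.
#' @return release probability, or NA when undefined.
#' @export
releaseProb <- function(x) x@pr

#' Per-frame delta-F/F0 values of a RoiTrace
#' @param x a RoiTrace.
#' @return numeric vector of delta-F/F0 values.
#' @export
dff <- function(x) x@dff

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "CurrentTrace", function(object) {
    cat(sprintf("CurrentTrace: %d samples @ %g kHz (%.3f s), '%s'\n",
        length(object@samples), object@samplingRate / 1000,
        duration(object), object@channelLabel))
    if (length(object@metadata))
        cat("  metadata:", paste(names(object@metadata), collapse = ", "),
            "\n")
})

setMethod("show", "StimulusProtocol", function(object) {
    cat(sprintf("StimulusProtocol: %d APs", length(object@apTimes)))
    if (!is.na(object@trainFrequency) && object@trainCount > 0L)
        cat(sprintf(" (train %g Hz x %d)", object@trainFrequency,
            object@trainCount))
    if (length(object@recoveryIntervals))
        cat(sprintf(", %d recovery intervals",
            length(object@recoveryIntervals)))
    if (length(object@sucroseWindow))
        cat(sprintf(", sucrose %.2f-%.2f s", object@sucroseWindow[1L],
            object@sucroseWindow[2L]))
    if (nrow(object@drugWindows))
        cat(sprintf(", drug: %s",
            paste(object@drugWindows$label, collapse = ", ")))
    cat("\n")
})

setMethod("show", "TrainMetrics", function(object) {
    cat(sprintf("TrainMetrics: %d stimuli\n", length(object@amplitudes)))
    cat(sprintf("  Amp1 %.1f pA, PPR %.3f, Amp10/Amp1 %.3f (%s)\n",
        if (length(object@amplitudes)) object@amplitudes[1L] else NA,
        object@ppr, object@steRatio, object@plasticityClass))
    cat(sprintf("  RRP %.2f pC%s, Pr %.3f, replenishment %.2f pC/s\n",
        object@rrpCharge,
        if (isTRUE(object@rrpUndefined)) " (undefined)" else "",
        object@pr, object@replenishmentRate))
})

setMethod("show", "RecoveryFit", function(object) {
    cat(sprintf(
        "RecoveryFit: kOff %.4f, epscInf %.4f, tau %.4f s (rss %.3g)%s\n",
        object@kOff, object@epscInf, object@tau, object@rss,
        if (object@degenerate) " [degenerate]" else ""))
})

setMethod("show", "MiniStats", function(object) {
    cat(sprintf("MiniStats: %d events in %.1f s (%.3f Hz), amp %.1f pA\n",
        object@nEvents, object@duration, object@frequency,
        object@amplitudeMean))
})

setMethod("show", "AgonistResponse", function(object) {
    cat(sprintf(
        "AgonistResponse: max inward %.1f pA, fold change %.2f, %s\n",
        object@maxInwardCurrent, object@freqFoldChange,
        if (isTRUE(object@responder)) "responder" else "non-responder"))
})

setMethod("show", "ImagingStack", function(object) {
    d <- dim(object@frames)
    cat(sprintf("ImagingStack: %d frames of %dx%d @ %g Hz (%d prestimulus)\n",
        d[1L], d[2L], d[3L], object@frameRate, object@prestimulusFrames))
})

setMethod("show", "SimParams", function(object) {
    cat(sprintf(
        "SimParams: nMax %d, pR %.2f, k0 %.2f/s, kCa %.3g/(nM s), jTrpc %g nM/s\n",
        object@nMax, object@pR, object@k0, object@kCa, object@jTrpc))
    modes <- c(if (object@egtaMode) "EGTA", if (object@teaMode) "TEA",
        if (object@englerinMode) "EnglerinA",
        if (object@deterministic) "deterministic")
    if (length(modes)) cat("  modes:", paste(modes, collapse = ", "), "\n")
})
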