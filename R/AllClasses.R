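#' @import methods
NULL

## ---------------------------------------------------------------------------
## Data containers
## ---------------------------------------------------------------------------

#' CurrentTrace: a uniformly sampled membrane-current recording
#'
#' Holds a whole-cell voltage-clamp current time series in pA with the
#' convention that inward (synaptic) currents are negative. All analysis
#' functions flip the sign internally and report magnitudes (amplitudes,
#' charges) as positive numbers.
#'
#' @slot samples numeric vector of current values (pA, inward negative).
#' @slot samplingRate sampling rate in Hz.
#' @slot startTime time of the first sample in s (0 by convention).
#' @slot channelLabel free-text channel label.
#' @slot metadata named list of recording metadata (holding potential,
#'   cell id, condition tags such as \code{"EGTA"}, \code{"TEA"},
#'   \code{"EnglerinA"}).
#'
#' @exportClass CurrentTrace
setClass("CurrentTrace",
    representation(
        samples = "numeric",
        samplingRate = "numeric",
        startTime = "numeric",
        channelLabel = "character",
        metadata = "list"
    ),
    prototype(startTime = 0, channelLabel = "Imon", metadata = list())
)

setValidity("CurrentTrace", function(object) {
    msg <- NULL
    if (length(object@samplingRate) != 1L || !is.finite(object@samplingRate) ||
        object@samplingRate <= 0)
        msg <- c(msg, "samplingRate must be a single positive finite number")
    if (length(object@samples) < 2L)
        msg <- c(msg, "a trace needs at least 2 samples")
    if (!all(is.finite(object@samples)))
        msg <- c(msg, "all samples must be finite")
    if (length(object@startTime) != 1L || !is.finite(object@startTime))
        msg <- c(msg, "startTime must be a single finite number")
    if (is.null(msg)) TRUE else msg
})

#' StimulusProtocol: action-potential times and experiment epochs
#'
#' @slot apTimes strictly increasing AP (stimulus) times in s, absolute in
#'   trace time.
#' @slot trainFrequency nominal train frequency in Hz (NA if no train).
#' @slot trainCount number of stimuli in the train block.
#' @slot recoveryIntervals intervals (s after train end) at which recovery
#'   test pulses are given.
#' @slot sucroseWindow numeric length-2 (start, end) of a hypertonic sucrose
#'   application in s, or length-0 if none.
#' @slot drugWindows data.frame with columns label, start, end (s).
#' @slot basalFrequency basal stimulation frequency in Hz (0.2 by default).
#'
#' @exportClass StimulusProtocol
setClass("StimulusProtocol",
    representation(
        apTimes = "numeric",
        trainFrequency = "numeric",
        trainCount = "integer",
        recoveryIntervals = "numeric",
        sucroseWindow = "numeric",
        drugWindows = "data.frame",
        basalFrequency = "numeric"
    ),
    prototype(
        apTimes = numeric(0), trainFrequency = NA_real_, trainCount = 0L,
        recoveryIntervals = numeric(0), sucroseWindow = numeric(0),
        drugWindows = data.frame(label = character(0), start = numeric(0),
            end = numeric(0), stringsAsFactors = FALSE),
        basalFrequency = 0.2
    )
)

setValidity("StimulusProtocol", function(object) {
    msg <- NULL
    ap <- object@apTimes
    if (length(ap) && any(diff(ap) <= 0))
        msg <- c(msg, "apTimes must be strictly increasing")
    ri <- object@recoveryIntervals
    if (length(ri) && (any(ri <= 0) || any(diff(ri) <= 0)))
        msg <- c(msg, "recoveryIntervals must be positive and strictly increasing")
    if (length(object@sucroseWindow) %in% c(0L, 2L)) {
        if (length(object@sucroseWindow) == 2L &&
            diff(object@sucroseWindow) <= 0)
            msg <- c(msg, "sucroseWindow end must exceed start")
    } else msg <- c(msg, "sucroseWindow must have length 0 or 2")
    dw <- object@drugWindows
    if (nrow(dw)) {
        if (!all(c("label", "start", "end") %in% names(dw)))
            msg <- c(msg, "drugWindows needs columns label, start, end")
        else {
            if (any(dw$end <= dw$start))
                msg <- c(msg, "drugWindows must have end > start")
            o <- order(dw$start)
            if (nrow(dw) > 1L &&
                any(dw$start[o][-1L] < dw$end[o][-nrow(dw)]))
                msg <- c(msg, "drugWindows must not overlap")
        }
    }
    if (is.null(msg)) TRUE else msg
})

#' ImagingStack: a multi-frame fluorescence image stack
#'
#' @slot frames 3-D numeric array (frame, row, col) of fluorescence counts.
#' @slot frameRate acquisition rate in Hz (5 Hz default).
#' @slot prestimulusFrames number of frames acquired before the stimulus.
#' @slot pixelSize pixel size in micrometres.
#'
#' @exportClass ImagingStack
setClass("ImagingStack",
    representation(
        frames = "array",
        frameRate = "numeric",
        prestimulusFrames = "integer",
        pixelSize = "numeric"
    ),
    prototype(frameRate = 5, prestimulusFrames = 3L, pixelSize = 0.4)
)

setValidity("ImagingStack", function(object) {
    msg <- NULL
    if (length(dim(object@frames)) != 3L)
        msg <- c(msg, "frames must be a 3-D array (frame, row, col)")
    else {
        if (dim(object@frames)[1L] < object@prestimulusFrames + 1L)
            msg <- c(msg, "frame count must exceed prestimulusFrames")
        if (any(object@frames < 0))
            msg <- c(msg, "all pixel values must be >= 0")
    }
    if (object@frameRate <= 0) msg <- c(msg, "frameRate must be > 0")
    if (is.null(msg)) TRUE else msg
})

#' AnalysisConfig: fixed constants of the analysis pipeline
#'
#' Central container for every tunable analysis constant. Defaults encode
#' the conventions used throughout the package: back-extrapolation over the
#' last 5 cumulative points, a 5-ms steady-state window at the end of each
#' interstimulus interval, mEPSC acceptance at 5 times the baseline noise SD
#' plus a 25-fC charge criterion, a 1.2-fold frequency threshold for agonist
#' responders, 4x4-pixel imaging ROIs with a 3-SD responsiveness rule, and
#' during-/post-train slope windows over data points 6-13 and 14-20.
#'
#' @slot regressionPointsSync points used for the cumulative synchronous
#'   charge back-extrapolation (RRP estimate).
#' @slot regressionPointsTotal points used for the cumulative total charge
#'   slope (replenishment rate).
#' @slot steadyStateWindow width (s) of the steady-state current window at
#'   the end of each interstimulus interval.
#' @slot amplitudeSearchWindow post-stimulus window (s) searched for the
#'   EPSC peak.
#' @slot artifactBlank time (s) blanked after each stimulus before peak
#'   search (covers the 0.7-ms depolarisation artifact).
#' @slot baselineWindow width (s) of the pre-stimulus baseline window.
#' @slot amplitudeBaseline "local" (1 ms before each stimulus) or "global"
#'   (pre-train) baseline for amplitude measurement.
#' @slot steadyStateTolerance relative tolerance for declaring a late-train
#'   steady state (compares mean synchronous charge of the last 5 stimuli
#'   with the 5 before).
#' @slot miniAmpSdMult mEPSC amplitude acceptance threshold in baseline
#'   noise SDs.
#' @slot miniChargeMin mEPSC charge acceptance criterion in fC.
#' @slot miniChargeCap cap (s) on the mEPSC charge-integration window.
#' @slot miniRefractory minimum onset separation (s); closer onsets merge.
#' @slot miniSmoothWindow smoothing window (s) for mini detection.
#' @slot miniDerivSdMult derivative threshold for candidate onsets, in
#'   robust SDs of the smoothed derivative.
#' @slot responderFoldThreshold mEPSC frequency fold-change at or above
#'   which a cell is classed an agonist responder.
#' @slot agonistSmoothWindow smoothing window (s) for the agonist inward
#'   current measurement.
#' @slot dffRoiSize imaging ROI edge length in pixels.
#' @slot dffSdMult responsiveness threshold in background-noise SDs.
#' @slot slopeHfsPoints 1-based inclusive (first, last) data points of the
#'   during-train dF/F0 slope.
#' @slot slopePostPoints (first, last) data points of the post-train slope.
#'
#' @exportClass AnalysisConfig
setClass("AnalysisConfig",
    representation(
        regressionPointsSync = "integer",
        regressionPointsTotal = "integer",
        steadyStateWindow = "numeric",
        amplitudeSearchWindow = "numeric",
        artifactBlank = "numeric",
        baselineWindow = "numeric",
        amplitudeBaseline = "character",
        steadyStateTolerance = "numeric",
        miniAmpSdMult = "numeric",
        miniChargeMin = "numeric",
        miniChargeCap = "numeric",
        miniRefractory = "numeric",
        miniSmoothWindow = "numeric",
        miniDerivSdMult = "numeric",
        responderFoldThreshold = "numeric",
        agonistSmoothWindow = "numeric",
        dffRoiSize = "integer",
        dffSdMult = "numeric",
        slopeHfsPoints = "integer",
        slopePostPoints = "integer"
    ),
    prototype(
        regressionPointsSync = 5L,
        regressionPointsTotal = 5L,
        steadyStateWindow = 0.005,
        amplitudeSearchWindow = 0.010,
        artifactBlank = 0.001,
        baselineWindow = 0.001,
        amplitudeBaseline = "local",
        steadyStateTolerance = 0.15,
        miniAmpSdMult = 5,
        miniChargeMin = 25,
        miniChargeCap = 0.050,
        miniRefractory = 0.002,
        miniSmoothWindow = 0.0005,
        miniDerivSdMult = 4,
        responderFoldThreshold = 1.2,
        agonistSmoothWindow = 0.1,
        dffRoiSize = 4L,
        dffSdMult = 3,
        slopeHfsPoints = c(6L, 13L),
        slopePostPoints = c(14L, 20L)
    )
)

setValidity("AnalysisConfig", function(object) {
    msg <- NULL
    wins <- c(object@steadyStateWindow, object@amplitudeSearchWindow,
        object@baselineWindow, object@miniChargeCap, object@miniRefractory,
        object@miniSmoothWindow, object@agonistSmoothWindow)
    if (any(wins <= 0)) msg <- c(msg, "all window lengths must be > 0")
    if (object@regressionPointsSync < 2L || object@regressionPointsTotal < 2L)
        msg <- c(msg, "regression point counts must be >= 2")
    if (!object@amplitudeBaseline %in% c("local", "global"))
        msg <- c(msg, "amplitudeBaseline must be 'local' or 'global'")
    if (length(object@slopeHfsPoints) != 2L ||
        length(object@slopePostPoints) != 2L)
        msg <- c(msg, "slope point specifications must have length 2")
    if (is.null(msg)) TRUE else msg
})

## ---------------------------------------------------------------------------
## Simulation containers
## ---------------------------------------------------------------------------

#' SimParams: generative parameters of the presynaptic simulator
#'
#' Parameters of the coupled calcium / vesicle-pool model. Calcium follows
#' dC/dt = -(C - cRest)/tauClear + jTrpc * hill(C; ec50Trpc, nHill), with a
#' per-AP bulk increment deltaCap; the readily releasable pool evolves by a
#' baseline term k0 * (nMax - N) plus a calcium-dependent recruitment term
#' kCa * (C - c0)+ * (overfillFactor * nMax - N) that can transiently
#' overfill the pool beyond its resting capacity (c0 is the resting fixed
#' point of the calcium equation).
#'
#' @slot nMax resting RRP capacity (vesicles).
#' @slot pR per-AP release probability per docked vesicle.
#' @slot k0 baseline replenishment rate constant (1/s).
#' @slot kCa calcium-dependent replenishment gain (1/(nM s)).
#' @slot overfillFactor transient overfill capacity as a multiple of nMax.
#' @slot cRest resting bulk calcium (nM) of the clearance term.
#' @slot deltaCap per-AP bulk calcium increment (nM).
#' @slot tauClear calcium clearance time constant (s).
#' @slot jTrpc maximal calcium-activated (TRPC-like) influx rate (nM/s).
#' @slot ec50Trpc half-activation calcium of the TRPC term (nM, default 635).
#' @slot nHill Hill coefficient of the TRPC activation (default 2).
#' @slot asyncGain asynchronous release rate gain (1/(nM s), multiplied by
#'   supra-resting calcium and pool occupancy fraction).
#' @slot miniRate0 baseline spontaneous mEPSC rate (Hz).
#' @slot qMean,qCv quantal peak amplitude mean (pA) and coefficient of
#'   variation (lognormal).
#' @slot tauRise,tauDecay quantal kernel time constants (s).
#' @slot syncLatency,syncJitter synchronous release latency after the AP and
#'   its Gaussian jitter SD (s; jitter applies in stochastic mode only).
#' @slot noiseSd Gaussian recording noise SD (pA).
#' @slot sucroseRate rate constant (1/s) of pool emptying under hypertonic
#'   sucrose.
#' @slot egtaMode,egtaKappa slow-chelator mode: scales all bulk calcium
#'   increments and the TRPC influx by 1/(1 + egtaKappa); phasic release is
#'   untouched.
#' @slot teaMode,fTea,fPr K-channel-block mode: multiplies deltaCap by fTea
#'   and pR by fPr (both > 1).
#' @slot englerinMode,englerinCurrent,englerinCaInflux agonist mode: adds a
#'   smooth direct inward current (pA) and a constant calcium influx (nM/s)
#'   during the drug window.
#' @slot deterministic if TRUE, expectation mode: no sampling, no noise.
#' @slot seed RNG seed (required in stochastic mode).
#' @slot dt integration step (s, default 1e-4).
#' @slot samplingRate sampling rate of rendered traces (Hz).
#'
#' @exportClass SimParams
setClass("SimParams",
    representation(
        nMax = "integer", pR = "numeric", k0 = "numeric", kCa = "numeric",
        overfillFactor = "numeric", cRest = "numeric", deltaCap = "numeric",
        tauClear = "numeric", jTrpc = "numeric", ec50Trpc = "numeric",
        nHill = "numeric", asyncGain = "numeric", miniRate0 = "numeric",
        qMean = "numeric", qCv = "numeric", tauRise = "numeric",
        tauDecay = "numeric", syncLatency = "numeric", syncJitter = "numeric",
        noiseSd = "numeric", sucroseRate = "numeric",
        egtaMode = "logical", egtaKappa = "numeric",
        teaMode = "logical", fTea = "numeric", fPr = "numeric",
        englerinMode = "logical", englerinCurrent = "numeric",
        englerinCaInflux = "numeric",
        deterministic = "logical", seed = "integer",
        dt = "numeric", samplingRate = "numeric"
    ),
    prototype(
        nMax = 300L, pR = 0.3, k0 = 0.3, kCa = 0.017, overfillFactor = 1.8,
        cRest = 100, deltaCap = 100, tauClear = 0.1, jTrpc = 4000,
        ec50Trpc = 635, nHill = 2, asyncGain = 0.3, miniRate0 = 1,
        qMean = 30, qCv = 0.3, tauRise = 5e-4, tauDecay = 5e-3,
        syncLatency = 1e-3, syncJitter = 3e-4, noiseSd = 3,
        sucroseRate = 2,
        egtaMode = FALSE, egtaKappa = 9,
        teaMode = FALSE, fTea = 2, fPr = 1.5,
        englerinMode = FALSE, englerinCurrent = 500, englerinCaInflux = 20,
        deterministic = FALSE, seed = NA_integer_,
        dt = 1e-4, samplingRate = 1e4
    )
)

setValidity("SimParams", function(object) {
    msg <- NULL
    if (object@pR <= 0 || object@pR > 1)
        msg <- c(msg, "pR must satisfy 0 < pR <= 1")
    nonneg <- c(object@k0, object@kCa, object@cRest, object@deltaCap,
        object@jTrpc, object@asyncGain, object@miniRate0, object@noiseSd,
        object@qCv, object@englerinCaInflux)
    if (any(nonneg < 0))
        msg <- c(msg, "rates, concentrations and gains must be >= 0")
    if (object@ec50Trpc <= 0) msg <- c(msg, "ec50Trpc must be > 0")
    if (object@nHill < 1) msg <- c(msg, "nHill must be >= 1")
    if (object@tauClear <= 0 || object@tauRise <= 0 || object@tauDecay <= 0)
        msg <- c(msg, "time constants must be > 0")
    if (object@tauRise >= object@tauDecay)
        msg <- c(msg, "tauRise must be < tauDecay")
    if (object@overfillFactor < 1)
        msg <- c(msg, "overfillFactor must be >= 1")
    if (object@nMax < 1L) msg <- c(msg, "nMax must be >= 1")
    if (object@dt <= 0 || object@dt > 5e-4)
        msg <- c(msg, "dt must be positive and <= 0.5 ms")
    if (object@samplingRate <= 0) msg <- c(msg, "samplingRate must be > 0")
    if (is.null(msg)) TRUE else msg
})

#' CaTrace: simulated bulk presynaptic calcium concentration
#'
#' @slot times time grid (s).
#' @slot concentration bulk calcium (nM) on the grid.
#' @slot dt integration step (s).
#' @slot restingCa resting fixed point c0 (nM) of the calcium equation used
#'   for supra-resting terms.
#'
#' @exportClass CaTrace
setClass("CaTrace",
    representation(times = "numeric", concentration = "numeric",
        dt = "numeric", restingCa = "numeric")
)

setValidity("CaTrace", function(object) {
    msg <- NULL
    if (length(object@times) != length(object@concentration))
        msg <- c(msg, "times and concentration lengths differ")
    if (any(object@concentration < 0))
        msg <- c(msg, "concentration must be >= 0 everywhere")
    if (is.null(msg)) TRUE else msg
})

#' GroundTruth: latent per-stimulus truths of a simulated experiment
#'
#' @slot apTimes stimulus times (s).
#' @slot syncQuanta per-AP synchronous released quanta (expectation in
#'   deterministic mode).
#' @slot syncTimes event times of synchronous quanta (stochastic mode).
#' @slot asyncTimes asynchronous release event times (stochastic mode).
#' @slot asyncExpected expected asynchronous quanta per inter-AP interval
#'   (deterministic mode; aligned with apTimes).
#' @slot miniTimes spontaneous (non-pool-consuming) mEPSC event times.
#' @slot occupancyTimes,occupancy RRP occupancy over time.
#' @slot contRate continuous (asynchronous + spontaneous) release rate in
#'   quanta/s at occupancyTimes; used to render the expectation-mode trace.
#' @slot replenishedQuanta cumulative replenished quanta at occupancyTimes.
#' @slot englerinWindow agonist application window (s), length 0 or 2.
#' @slot trueRrpCharge nMax times the mean quantal charge (pC).
#' @slot truePr per-vesicle release probability actually used (after any
#'   drug-mode scaling).
#' @slot trueReplenishmentFlux replenishment flux (pC/s) averaged over the
#'   late steady-state phase of the train.
#' @slot quantalCharge mean charge of one quantum (pC).
#'
#' @exportClass GroundTruth
setClass("GroundTruth",
    representation(
        apTimes = "numeric", syncQuanta = "numeric", syncTimes = "numeric",
        asyncTimes = "numeric", asyncExpected = "numeric",
        miniTimes = "numeric", occupancyTimes = "numeric",
        occupancy = "numeric", contRate = "numeric",
        replenishedQuanta = "numeric",
        trueRrpCharge = "numeric", truePr = "numeric",
        trueReplenishmentFlux = "numeric", quantalCharge = "numeric",
        englerinWindow = "numeric"
    ),
    prototype(englerinWindow = numeric(0))
)

## ---------------------------------------------------------------------------
## Result containers
## ---------------------------------------------------------------------------

#' TrainMetrics: per-stimulus measurements and derived train statistics
#'
#' @slot amplitudes per-stimulus peak EPSC magnitude (pA, positive).
#' @slot totalCharge,asyncCharge,syncCharge per-stimulus charges (pC).
#' @slot cumulativeSync,cumulativeTotal running sums (pC).
#' @slot ppr paired-pulse ratio Amp2/Amp1.
#' @slot steRatio Amp10/Amp1.
#' @slot plasticityClass "STE" if steRatio > 1 else "STD".
#' @slot steadyStateReached whether the late train reached steady state.
#' @slot rrpCharge back-extrapolated RRP charge (pC; NA if undefined).
#' @slot rrpUndefined TRUE when the intercept was negative (reported as
#'   undefined, never clamped).
#' @slot pr release probability (first synchronous charge / RRP charge).
#' @slot replenishmentRate late-train replenishment rate (pC/s).
#' @slot replenishmentPerStimulus same slope in pC per stimulus.
#' @slot fitDiagnostics list of regression slopes/intercepts/R2 and the
#'   configuration values actually used.
#' @slot qualityFlags character vector of per-run quality annotations.
#'
#' @exportClass TrainMetrics
setClass("TrainMetrics",
    representation(
        amplitudes = "numeric", totalCharge = "numeric",
        asyncCharge = "numeric", syncCharge = "numeric",
        cumulativeSync = "numeric", cumulativeTotal = "numeric",
        ppr = "numeric", steRatio = "numeric", plasticityClass = "character",
        steadyStateReached = "logical", rrpCharge = "numeric",
        rrpUndefined = "logical", pr = "numeric",
        replenishmentRate = "numeric", replenishmentPerStimulus = "numeric",
        fitDiagnostics = "list", qualityFlags = "character"
    ),
    prototype(ppr = NA_real_, steRatio = NA_real_,
        plasticityClass = NA_character_, steadyStateReached = NA,
        rrpCharge = NA_real_, rrpUndefined = FALSE, pr = NA_real_,
        replenishmentRate = NA_real_, replenishmentPerStimulus = NA_real_,
        fitDiagnostics = list(), qualityFlags = character(0))
)

#' RecoveryFit: single-exponential fit of recovery from depression
#'
#' Model: f(t) = kOff + epscInf * (1 - exp(-t / tau)).
#'
#' @slot intervals test-pulse intervals (s after train end).
#' @slot fractions recovery fractions (test amplitude / first train
#'   amplitude).
#' @slot kOff,epscInf,tau fitted parameters (tau in s).
#' @slot rss residual sum of squares.
#' @slot converged whether the fit converged.
#' @slot degenerate TRUE when tau is unidentifiable (flat data).
#'
#' @exportClass RecoveryFit
setClass("RecoveryFit",
    representation(intervals = "numeric", fractions = "numeric",
        kOff = "numeric", epscInf = "numeric", tau = "numeric",
        rss = "numeric", converged = "logical", degenerate = "logical"),
    prototype(kOff = NA_real_, epscInf = NA_real_, tau = NA_real_,
        rss = NA_real_, converged = FALSE, degenerate = FALSE)
)

#' SucroseResult: RRP estimate from a hypertonic sucrose application
#'
#' @slot transientCharge charge (pC) of the transient component after
#'   subtracting the steady-state current (the RRP estimate).
#' @slot steadyStateCurrent steady-state current magnitude (pA) at the end
#'   of the application.
#' @slot window the (start, end) analysis window (s).
#'
#' @exportClass SucroseResult
setClass("SucroseResult",
    representation(transientCharge = "numeric",
        steadyStateCurrent = "numeric", window = "numeric")
)

#' MiniStats: summary statistics of detected mEPSCs
#'
#' @slot frequency event frequency (Hz) over the analysed duration.
#' @slot amplitudeMean,amplitudeMedian amplitude summaries (pA).
#' @slot interEventIntervals inter-event intervals (s).
#' @slot riseTimeMean,decayTauMean kinetic summaries (ms).
#' @slot nEvents number of events.
#' @slot duration analysed duration (s).
#'
#' @exportClass MiniStats
setClass("MiniStats",
    representation(frequency = "numeric", amplitudeMean = "numeric",
        amplitudeMedian = "numeric", interEventIntervals = "numeric",
        riseTimeMean = "numeric", decayTauMean = "numeric",
        nEvents = "integer", duration = "numeric")
)

#' AgonistResponse: quantification of a drug-application epoch
#'
#' @slot baselineCurrent median current (pA, signed) in the baseline window.
#' @slot maxInwardCurrent maximal inward deviation from baseline (pA,
#'   positive magnitude) within the drug window.
#' @slot freqFoldChange mEPSC frequency in the drug window divided by the
#'   baseline frequency (NA when the baseline rate is zero).
#' @slot responder TRUE when freqFoldChange >= the responder threshold.
#' @slot flags character annotations (e.g. undefined fold change).
#'
#' @exportClass AgonistResponse
setClass("AgonistResponse",
    representation(baselineCurrent = "numeric", maxInwardCurrent = "numeric",
        freqFoldChange = "numeric", responder = "logical",
        flags = "character"),
    prototype(flags = character(0))
)

#' RoiTrace: per-ROI delta-F/F0 time series
#'
#' @slot roiOrigin (row, col) of the ROI's top-left pixel.
#' @slot roiSize ROI edge length in pixels.
#' @slot dff per-frame delta-F/F0 values.
#' @slot backgroundSd background noise SD in delta-F/F0 units.
#' @slot f0 baseline ROI fluorescence (counts).
#' @slot undefined TRUE when F0 <= 0 made the ROI unusable.
#'
#' @exportClass RoiTrace
setClass("RoiTrace",
    representation(roiOrigin = "integer", roiSize = "integer",
        dff = "numeric", backgroundSd = "numeric", f0 = "numeric",
        undefined = "logical"),
    prototype(undefined = FALSE)
)

#' DffMetrics: summary metrics of a delta-F/F0 trace
#'
#' @slot maxDff maximal delta-F/F0 over all frames.
#' @slot slopeHfs OLS slope (per frame) over the during-train data points.
#' @slot slopePost OLS slope over the post-train data points.
#' @slot responsive TRUE when maxDff exceeds the background threshold.
#'
#' @exportClass DffMetrics
setClass("DffMetrics",
    representation(maxDff = "numeric", slopeHfs = "numeric",
        slopePost = "numeric", responsive = "logical")
)
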