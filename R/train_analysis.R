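#' Measure per-stimulus amplitudes and charges of an EPSC train
#'
#' For every stimulus k the peak EPSC magnitude is the maximum sign-flipped
#' current in (t_k + artifactBlank, t_k + amplitudeSearchWindow] minus the
#' pre-stimulus baseline (local 1-ms baseline by default, which tolerates
#' summation during trains). The total charge is the integral of the
#' sign-flipped, pre-train-baseline-subtracted current over [t_k, t_{k+1});
#' the asynchronous charge is the mean current over the final
#' steadyStateWindow of the interstimulus interval times the interval
#' duration, and the synchronous charge is their difference.
#'
#' @param trace a \linkS4class{CurrentTrace} (pA, inward negative).
#' @param protocol a \linkS4class{StimulusProtocol} with >= 2 train stimuli.
#' @param config an \linkS4class{AnalysisConfig}.
#' @return A \linkS4class{TrainMetrics} with amplitudes (pA) and charges
#'   (pC) populated; derived quantities are filled by
#'   \code{\link{analyzeTrain}}.
#' @export
measureTrain <- function(trace, protocol, config = analysisConfig()) {
    validObject(trace)
    validObject(config)
    ap <- protocol@apTimes
    nTrain <- if (protocol@trainCount > 0L)
        min(protocol@trainCount, length(ap)) else length(ap)
    if (nTrain < 2L)
        stop("train analysis needs at least 2 stimuli")
    ap <- ap[seq_len(nTrain)]
    isi <- if (!is.na(protocol@trainFrequency))
        1 / protocol@trainFrequency else stats::median(diff(ap))
    bounds <- c(ap, ap[nTrain] + isi)
    checkTraceCovers(trace, bounds[nTrain + 1L], "stimulus interval")

    fs <- trace@samplingRate
    y <- -(trace@samples)   # inward magnitude positive
    tIdx <- function(t) pmin(pmax(round((t - trace@startTime) * fs) + 1L, 1L),
        length(y))
    winMean <- function(t0, t1) {
        i0 <- tIdx(t0); i1 <- tIdx(t1)
        if (i1 < i0) i1 <- i0
        mean(y[i0:i1])
    }
    globalBase <- winMean(ap[1L] - config@baselineWindow, ap[1L] - 1 / fs)
    y0 <- y - globalBase

    amplitudes <- totalCharge <- asyncCharge <- numeric(nTrain)
    for (k in seq_len(nTrain)) {
        t0 <- bounds[k]; t1 <- bounds[k + 1L]
        localBase <- if (config@amplitudeBaseline == "local")
            winMean(t0 - config@baselineWindow, t0 - 1 / fs) else globalBase
        iA0 <- tIdx(t0 + config@artifactBlank)
        iA1 <- tIdx(t0 + config@amplitudeSearchWindow)
        amplitudes[k] <- max(y[iA0:iA1]) - localBase
        iC0 <- tIdx(t0); iC1 <- tIdx(t1 - 1 / fs)
        totalCharge[k] <- sum(y0[iC0:iC1]) / fs
        ss <- winMean(t1 - config@steadyStateWindow, t1 - 1 / fs) -
            globalBase
        asyncCharge[k] <- ss * (t1 - t0)
    }
    syncCharge <- totalCharge - asyncCharge
    new("TrainMetrics",
        amplitudes = amplitudes, totalCharge = totalCharge,
        asyncCharge = asyncCharge, syncCharge = syncCharge,
        cumulativeSync = cumsum(syncCharge),
        cumulativeTotal = cumsum(totalCharge),
        fitDiagnostics = list(
            steadyStateWindow = config@steadyStateWindow,
            amplitudeBaseline = config@amplitudeBaseline,
            artifactBlank = config@artifactBlank))
}

## least-squares line through (x, y); returns intercept, slope, r2
olsLine <- function(x, y) {
    fit <- stats::lm(y ~ x)
    co <- stats::coef(fit)
    ssTot <- sum((y - mean(y))^2)
    r2 <- if (ssTot > 0) 1 - sum(stats::residuals(fit)^2) / ssTot else NA_real_
    list(intercept = unname(co[1L]), slope = unname(co[2L]), r2 = r2)
}

#' Back-extrapolated RRP estimate from cumulative synchronous charge
#'
#' Ordinary least squares on (stimulus index, cumulative synchronous
#' charge) over the last \code{regressionPointsSync} points of the train;
#' the y-intercept at stimulus 0 estimates the RRP charge with minimal
#' contribution of refilling. A negative intercept is reported as undefined
#' (NA with a flag), never clamped. Steady state is declared when the mean
#' synchronous charge of the last five stimuli differs from that of the
#' five before by less than \code{steadyStateTolerance}.
#'
#' @param metrics a \linkS4class{TrainMetrics} from
#'   \code{\link{measureTrain}}.
#' @param config an \linkS4class{AnalysisConfig}.
#' @return list with \code{rrpCharge} (pC or NA), \code{undefined},
#'   \code{steadyStateReached}, \code{slope}, \code{intercept}, \code{r2}.
#' @export
estimateRrpTrain <- function(metrics, config = analysisConfig()) {
    nP <- config@regressionPointsSync
    nStim <- length(metrics@cumulativeSync)
    if (nStim < nP)
        stop("fewer stimuli than regressionPointsSync (configuration error)")
    idx <- seq(nStim - nP + 1L, nStim)
    fit <- olsLine(idx, metrics@cumulativeSync[idx])
    undefined <- fit$intercept < 0
    ssReached <- NA
    if (nStim >= 10L) {
        mLast <- mean(metrics@syncCharge[(nStim - 4L):nStim])
        mPrev <- mean(metrics@syncCharge[(nStim - 9L):(nStim - 5L)])
        ## the comparison scale is floored at 1% of the first-stimulus
        ## charge so that a fully depleted (essentially zero) tail still
        ## counts as a steady state
        scale <- max(abs(mPrev), 0.01 * abs(metrics@syncCharge[1L]), 1e-12)
        ssReached <- is.finite(mLast) && is.finite(mPrev) &&
            abs(mLast - mPrev) < config@steadyStateTolerance * scale
    }
    list(rrpCharge = if (undefined) NA_real_ else fit$intercept,
        undefined = undefined, steadyStateReached = ssReached,
        slope = fit$slope, intercept = fit$intercept, r2 = fit$r2)
}

#' Release probability from the first EPSC charge and the RRP charge
#'
#' @param metrics a \linkS4class{TrainMetrics}.
#' @param rrpCharge RRP charge (pC); NA propagates to an NA Pr.
#' @return first synchronous charge / RRP charge, or NA when the RRP is
#'   undefined.
#' @export
releaseProbability <- function(metrics, rrpCharge) {
    if (is.na(rrpCharge) || rrpCharge <= 0) return(NA_real_)
    metrics@syncCharge[1L] / rrpCharge
}

#' Late-train vesicle replenishment rate
#'
#' OLS slope of cumulative total charge against stimulus index over the
#' last \code{regressionPointsTotal} points, converted to pC/s by
#' multiplying with the train frequency.
#'
#' @param metrics a \linkS4class{TrainMetrics}.
#' @param config an \linkS4class{AnalysisConfig}.
#' @param trainFrequency train frequency (Hz).
#' @return list with \code{ratePerSecond} (pC/s), \code{ratePerStimulus}
#'   (pC), \code{r2}.
#' @export
replenishmentRate <- function(metrics, config = analysisConfig(),
                              trainFrequency = 20) {
    nP <- config@regressionPointsTotal
    nStim <- length(metrics@cumulativeTotal)
    if (nStim < nP)
        stop("fewer stimuli than regressionPointsTotal (configuration error)")
    idx <- seq(nStim - nP + 1L, nStim)
    fit <- olsLine(idx, metrics@cumulativeTotal[idx])
    list(ratePerSecond = fit$slope * trainFrequency,
        ratePerStimulus = fit$slope, r2 = fit$r2)
}

#' Paired-pulse ratio and short-term plasticity classification
#'
#' PPR = Amp2/Amp1; the plasticity index is Amp10/Amp1, classed "STE"
#' strictly above 1 and "STD" otherwise (a ratio of exactly 1 is STD).
#'
#' @param metrics a \linkS4class{TrainMetrics} with >= 10 amplitudes.
#' @param noiseFloor amplitudes at or below this level (pA) make the
#'   indices undefined.
#' @return list with \code{ppr}, \code{steRatio}, \code{plasticityClass},
#'   \code{flags}.
#' @export
plasticityIndices <- function(metrics, noiseFloor = 0) {
    a <- metrics@amplitudes
    if (length(a) < 10L)
        stop("plasticity indices need at least 10 measured stimuli")
    if (!is.finite(a[1L]) || a[1L] <= noiseFloor)
        return(list(ppr = NA_real_, steRatio = NA_real_,
            plasticityClass = NA_character_,
            flags = "first amplitude at or below noise floor"))
    ratio <- a[10L] / a[1L]
    list(ppr = a[2L] / a[1L], steRatio = ratio,
        plasticityClass = if (ratio > 1) "STE" else "STD",
        flags = character(0))
}

#' Full train analysis
#'
#' Runs \code{\link{measureTrain}} and fills in the RRP estimate, release
#' probability, replenishment rate and plasticity indices.
#'
#' @param trace a \linkS4class{CurrentTrace}.
#' @param protocol a \linkS4class{StimulusProtocol}.
#' @param config an \linkS4class{AnalysisConfig}.
#' @return A completed \linkS4class{TrainMetrics}.
#' @examples
#' sim <- simulateExperiment(simParams(deterministic = TRUE),
#'     stimulusProtocol())
#' tm <- analyzeTrain(sim$trace, stimulusProtocol())
#' @export
analyzeTrain <- function(trace, protocol, config = analysisConfig()) {
    m <- measureTrain(trace, protocol, config)
    rrp <- estimateRrpTrain(m, config)
    freq <- if (!is.na(protocol@trainFrequency)) protocol@trainFrequency
        else 1 / stats::median(diff(protocol@apTimes))
    rep <- replenishmentRate(m, config, freq)
    pl <- if (length(m@amplitudes) >= 10L) plasticityIndices(m) else
        list(ppr = m@amplitudes[2L] / m@amplitudes[1L], steRatio = NA_real_,
            plasticityClass = NA_character_, flags = character(0))
    m@rrpCharge <- rrp$rrpCharge
    m@rrpUndefined <- rrp$undefined
    m@steadyStateReached <- rrp$steadyStateReached
    m@pr <- releaseProbability(m, rrp$rrpCharge)
    m@replenishmentRate <- rep$ratePerSecond
    m@replenishmentPerStimulus <- rep$ratePerStimulus
    m@ppr <- pl$ppr
    m@steRatio <- pl$steRatio
    m@plasticityClass <- pl$plasticityClass
    m@qualityFlags <- c(m@qualityFlags, pl$flags)
    m@fitDiagnostics <- c(m@fitDiagnostics, list(
        rrpRegression = rrp[c("slope", "intercept", "r2")],
        replenishmentRegression = rep,
        regressionPointsSync = config@regressionPointsSync,
        regressionPointsTotal = config@regressionPointsTotal))
    m
}

#' Fit single-exponential recovery from depression
#'
#' Fractions of recovery (test-pulse amplitude over the first train
#' amplitude) at each interval t are fitted with
#' \deqn{f(t) = k_{off} + EPSC_\infty (1 - e^{-t/\tau})}
#' by multi-start Levenberg-Marquardt least squares (tau starts at 0.1,
#' 0.5 and 2 s; tau is bounded positive). Flat data make tau
#' unidentifiable; the fit is then flagged degenerate with
#' \code{kOff = mean(fractions)} and \code{epscInf = 0}, never silently
#' reported as converged.
#'
#' @param testAmplitudes test-pulse amplitudes (pA) per interval.
#' @param firstTrainAmplitude amplitude of the first train EPSC (pA), > 0.
#' @param intervals test-pulse intervals (s after train end), >= 4.
#' @return A \linkS4class{RecoveryFit}.
#' @examples
#' t <- defaultRecoveryIntervals()
#' f <- 0.4 + 0.8 * (1 - exp(-t / 0.5))
#' fitRecovery(f * 100, 100, t)
#' @export
fitRecovery <- function(testAmplitudes, firstTrainAmplitude, intervals) {
    if (length(intervals) < 4L)
        stop("recovery fit needs at least 4 intervals")
    if (firstTrainAmplitude <= 0)
        stop("firstTrainAmplitude must be > 0")
    if (length(testAmplitudes) != length(intervals))
        stop("testAmplitudes and intervals lengths differ")
    f <- testAmplitudes / firstTrainAmplitude

    if (diff(range(f)) < 1e-9) {
        return(new("RecoveryFit", intervals = intervals, fractions = f,
            kOff = mean(f), epscInf = 0, tau = NA_real_,
            rss = sum((f - mean(f))^2), converged = TRUE,
            degenerate = TRUE))
    }

    df <- data.frame(t = intervals, f = f)
    best <- NULL
    for (tau0 in c(0.1, 0.5, 2)) {
        fit <- tryCatch(
            minpack.lm::nlsLM(f ~ kOff + epscInf * (1 - exp(-t / tau)),
                data = df,
                start = list(kOff = min(f), epscInf = max(f) - min(f),
                    tau = tau0),
                lower = c(-Inf, -Inf, 1e-6),
                control = minpack.lm::nls.lm.control(maxiter = 200,
                    ftol = 1e-14, ptol = 1e-14)),
            error = function(e) NULL)
        if (is.null(fit)) next
        rss <- sum(stats::residuals(fit)^2)
        if (is.null(best) || rss < best$rss)
            best <- list(coef = stats::coef(fit), rss = rss)
    }
    if (is.null(best))
        return(new("RecoveryFit", intervals = intervals, fractions = f,
            converged = FALSE))
    new("RecoveryFit", intervals = intervals, fractions = f,
        kOff = unname(best$coef["kOff"]),
        epscInf = unname(best$coef["epscInf"]),
        tau = unname(best$coef["tau"]), rss = best$rss,
        converged = TRUE, degenerate = FALSE)
}

#' Predicted recovery curve of a fitted model
#'
#' @param fit a \linkS4class{RecoveryFit}.
#' @param t times (s) at which to evaluate the fit.
#' @return predicted recovery fractions.
#' @export
predictRecovery <- function(fit, t = fit@intervals) {
    if (fit@degenerate || !fit@converged) return(rep(fit@kOff, length(t)))
    fit@kOff + fit@epscInf * (1 - exp(-t / fit@tau))
}

#' Analyse a hypertonic sucrose response
#'
#' The steady-state current is the mean sign-flipped current over the
#' final 10 percent of the application window; the transient charge (the
#' RRP estimate) is the integral of the current above that steady state
#' over the window, with negative excursions truncated at 0. When at least
#' 100 ms of pre-window trace exist, the pre-application baseline is
#' subtracted first.
#'
#' @param trace a \linkS4class{CurrentTrace}.
#' @param window application window (start, end) in s, >= 1 s wide, inside
#'   the trace.
#' @param config an \linkS4class{AnalysisConfig} (reserved).
#' @return A \linkS4class{SucroseResult}.
#' @export
analyzeSucrose <- function(trace, window, config = analysisConfig()) {
    validObject(trace)
    if (length(window) != 2L || diff(window) < 1)
        stop("sucrose window must be (start, end) and >= 1 s wide")
    checkTraceCovers(trace, window[2L], "sucrose window")
    fs <- trace@samplingRate
    y <- -(trace@samples)
    tIdx <- function(t) pmin(pmax(round((t - trace@startTime) * fs) + 1L, 1L),
        length(y))
    if (window[1L] - trace@startTime >= 0.1) {
        base <- mean(y[tIdx(window[1L] - 0.1):tIdx(window[1L] - 1 / fs)])
        y <- y - base
    }
    i0 <- tIdx(window[1L]); i1 <- tIdx(window[2L])
    ssStart <- tIdx(window[2L] - 0.1 * diff(window))
    ssCurrent <- mean(y[ssStart:i1])
    transient <- sum(pmax(y[i0:i1] - ssCurrent, 0)) / fs
    new("SucroseResult", transientCharge = transient,
        steadyStateCurrent = ssCurrent, window = window)
}

#' Release probability from a single evoked EPSC and a sucrose RRP
#'
#' @param epscCharge charge of the AP-evoked EPSC (pC).
#' @param sucrose a \linkS4class{SucroseResult}.
#' @return EPSC charge / sucrose transient charge.
#' @export
sucrosePr <- function(epscCharge, sucrose) {
    if (sucrose@transientCharge <= 0) return(NA_real_)
    epscCharge / sucrose@transientCharge
}
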