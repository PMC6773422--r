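## Boxcar smoother (centred running mean over w samples, w made odd).
boxcar <- function(x, w) {
    w <- max(1L, as.integer(w))
    if (w %% 2L == 0L) w <- w + 1L
    if (w == 1L) return(x)
    as.numeric(stats::filter(x, rep(1 / w, w), sides = 2L)) ->
        out
    ## fill filter() NAs at the edges with the nearest computed value
    h <- (w - 1L) %/% 2L
    out[seq_len(h)] <- out[h + 1L]
    n <- length(out)
    out[(n - h + 1L):n] <- out[n - h]
    out
}

#' Robust baseline noise SD of a recording
#'
#' Median-absolute-deviation estimate (scaled by 1.4826) of the high-pass
#' detrended signal (signal minus a 25-ms running median), computed outside
#' any excluded event regions.
#'
#' @param trace a \linkS4class{CurrentTrace}.
#' @param exclude optional logical mask (length of the trace) of samples to
#'   exclude (detected events).
#' @return noise SD in pA.
#' @export
baselineNoiseSd <- function(trace, exclude = NULL) {
    validObject(trace)
    y <- trace@samples
    fs <- trace@samplingRate
    k <- as.integer(round(0.025 * fs))
    if (k %% 2L == 0L) k <- k + 1L
    detr <- y - stats::runmed(y, max(3L, k))
    if (!is.null(exclude)) {
        if (length(exclude) != length(y))
            stop("exclusion mask length must match the trace")
        detr <- detr[!exclude]
    }
    if (length(detr) < 0.5 * fs)
        stop("less than 0.5 s of event-free trace available")
    stats::mad(detr)
}

#' Detect miniature EPSCs
#'
#' Candidate onsets come from threshold crossings of the smoothed first
#' derivative of the sign-flipped current; each candidate's peak is
#' measured against a local pre-onset baseline. An event is accepted only
#' if its amplitude exceeds \code{miniAmpSdMult} (default 5) times the
#' baseline noise SD \emph{and} its charge (integral from onset to return
#' to within one noise SD of baseline, capped at \code{miniChargeCap})
#' exceeds \code{miniChargeMin} fC (default 25). Onsets closer than the
#' refractory interval merge into one event. Detection is deterministic
#' given the trace and configuration.
#'
#' @param trace a \linkS4class{CurrentTrace} sampled at >= 5 kHz.
#' @param config an \linkS4class{AnalysisConfig}.
#' @param noiseSd optional pre-computed baseline noise SD (pA); estimated
#'   with \code{\link{baselineNoiseSd}} when NULL.
#' @return data.frame of accepted events with columns \code{onset} (s),
#'   \code{peakTime} (s), \code{amplitude} (pA), \code{charge} (fC),
#'   \code{riseTime1090} (ms), \code{decayTau} (ms). Zero rows when
#'   nothing is detected.
#' @export
detectMinis <- function(trace, config = analysisConfig(), noiseSd = NULL) {
    validObject(trace)
    fs <- trace@samplingRate
    if (fs < 5000)
        stop("mini detection needs a sampling rate of at least 5 kHz")
    if (is.null(noiseSd)) noiseSd <- baselineNoiseSd(trace)
    y <- -(trace@samples)
    n <- length(y)
    wS <- max(1L, round(config@miniSmoothWindow * fs))
    ys <- boxcar(y, wS)
    lag <- max(1L, round(0.0005 * fs))
    d <- c(rep(0, lag), diff(ys, lag = lag)) / (lag / fs)
    ampThr <- config@miniAmpSdMult * noiseSd
    ## floor on the derivative threshold: an acceptable event must climb to
    ## the amplitude criterion within a few ms, so slower slopes (and the
    ## numerical ripple of noise-free traces) are never candidates
    dThr <- max(config@miniDerivSdMult * stats::mad(d), ampThr / 0.005)

    cross <- which(d[-1L] > dThr & d[-n] <= dThr) + 1L
    if (!length(cross)) return(emptyEvents())

    refr <- round(config@miniRefractory * fs)
    keep <- logical(length(cross))
    lastKept <- -Inf
    for (j in seq_along(cross)) {
        if (cross[j] - lastKept > refr) {
            keep[j] <- TRUE
            lastKept <- cross[j]
        }
    }
    cross <- cross[keep]

    searchW <- round(0.010 * fs)
    baseW <- max(1L, round(0.002 * fs))
    capW <- round(config@miniChargeCap * fs)
    events <- vector("list", length(cross))
    lastEnd <- 0L
    for (j in seq_along(cross)) {
        i <- cross[j]
        if (i <= lastEnd) next
        winEnd <- min(n, i + searchW)
        iPk <- i + which.max(ys[i:winEnd]) - 1L
        ## extend while the maximum sits on the window edge (late peak)
        while (iPk == winEnd && winEnd < n) {
            winEnd <- min(n, iPk + searchW)
            iPkNew <- iPk + which.max(ys[iPk:winEnd]) - 1L
            if (iPkNew == iPk) break
            iPk <- iPkNew
        }
        b0 <- max(1L, i - baseW)
        base <- stats::median(ys[b0:max(b0, i - 1L)])
        amp <- ys[iPk] - base
        if (amp <= ampThr) next
        ## onset: last sample before the peak within 1 SD of baseline
        pre <- ys[max(1L, iPk - searchW):iPk]
        below <- which(pre < base + noiseSd)
        iOn <- if (length(below))
            max(1L, iPk - searchW) + below[length(below)] - 1L else i
        ## charge: onset to return within 1 SD of baseline, capped
        iEnd <- min(n, iOn + capW)
        post <- ys[iPk:iEnd]
        ret <- which(post < base + noiseSd)
        if (length(ret)) iEnd <- iPk + ret[1L] - 1L
        charge <- sum(ys[iOn:iEnd] - base) / fs * 1000  # pC -> fC
        if (charge <= config@miniChargeMin) next
        ## kinetics
        seg <- ys[iOn:iPk] - base
        i10 <- which(seg >= 0.1 * amp)[1L]
        i90 <- which(seg >= 0.9 * amp)[1L]
        rise <- if (!is.na(i10) && !is.na(i90))
            (i90 - i10) / fs * 1000 else NA_real_
        dec <- ys[iPk:iEnd] - base
        i37 <- which(dec <= amp * exp(-1))[1L]
        dtau <- if (!is.na(i37)) (i37 - 1L) / fs * 1000 else NA_real_
        lastEnd <- iPk
        events[[j]] <- data.frame(
            onset = trace@startTime + (iOn - 1L) / fs,
            peakTime = trace@startTime + (iPk - 1L) / fs,
            amplitude = amp, charge = charge,
            riseTime1090 = rise, decayTau = dtau)
    }
    events <- events[!vapply(events, is.null, logical(1L))]
    if (!length(events)) return(emptyEvents())
    out <- do.call(rbind, events)
    rownames(out) <- NULL
    out
}

emptyEvents <- function() {
    data.frame(onset = numeric(0), peakTime = numeric(0),
        amplitude = numeric(0), charge = numeric(0),
        riseTime1090 = numeric(0), decayTau = numeric(0))
}

#' Summary statistics of detected mEPSCs
#'
#' @param events event data.frame from \code{\link{detectMinis}}.
#' @param analysedDuration analysed duration (s), > 0.
#' @return A \linkS4class{MiniStats}.
#' @export
miniStats <- function(events, analysedDuration) {
    if (analysedDuration <= 0) stop("analysedDuration must be > 0")
    nEv <- nrow(events)
    new("MiniStats",
        frequency = nEv / analysedDuration,
        amplitudeMean = if (nEv) mean(events$amplitude) else NA_real_,
        amplitudeMedian = if (nEv) stats::median(events$amplitude)
            else NA_real_,
        interEventIntervals = if (nEv > 1L) diff(sort(events$onset))
            else numeric(0),
        riseTimeMean = if (nEv) mean(events$riseTime1090, na.rm = TRUE)
            else NA_real_,
        decayTauMean = if (nEv) mean(events$decayTau, na.rm = TRUE)
            else NA_real_,
        nEvents = as.integer(nEv), duration = analysedDuration)
}

#' Empirical CDF of inter-event intervals
#'
#' @param stats a \linkS4class{MiniStats}.
#' @return an \code{\link[stats]{ecdf}} function, or NULL with fewer than
#'   two events.
#' @export
interEventCdf <- function(stats) {
    if (length(stats@interEventIntervals) < 1L) return(NULL)
    stats::ecdf(stats@interEventIntervals)
}

#' Quantify an agonist application epoch
#'
#' The baseline current is the median current in the baseline window; the
#' maximal inward current is the largest inward (sign-flipped) deviation of
#' the smoothed current from baseline within the drug window. The mEPSC
#' frequency fold change is the event rate in the drug window over the
#' baseline rate, and a cell is classed a responder when the fold change
#' reaches \code{responderFoldThreshold} (default 1.2; an increase below
#' the threshold is a failure to respond).
#'
#' @param trace a \linkS4class{CurrentTrace}.
#' @param baselineWindow (start, end) s of the pre-drug epoch, >= 5 s.
#' @param drugWindow (start, end) s of the drug epoch, >= 5 s, disjoint
#'   from the baseline window.
#' @param events mEPSC event data.frame from \code{\link{detectMinis}}.
#' @param config an \linkS4class{AnalysisConfig}.
#' @return An \linkS4class{AgonistResponse}.
#' @export
agonistResponse <- function(trace, baselineWindow, drugWindow, events,
                            config = analysisConfig()) {
    validObject(trace)
    if (diff(baselineWindow) < 5 || diff(drugWindow) < 5)
        stop("baseline and drug windows must each be >= 5 s")
    if (baselineWindow[2L] > drugWindow[1L] &&
        drugWindow[2L] > baselineWindow[1L])
        stop("baseline and drug windows must be disjoint")
    checkTraceCovers(trace, max(baselineWindow[2L], drugWindow[2L]),
        "drug window")
    fs <- trace@samplingRate
    tt <- traceTimes(trace)
    inBase <- tt >= baselineWindow[1L] & tt < baselineWindow[2L]
    inDrug <- tt >= drugWindow[1L] & tt < drugWindow[2L]
    baseI <- stats::median(trace@samples[inBase])
    sm <- boxcar(trace@samples, round(config@agonistSmoothWindow * fs))
    maxInward <- max(baseI - sm[inDrug])

    rate <- function(win) {
        sum(events$onset >= win[1L] & events$onset < win[2L]) / diff(win)
    }
    rBase <- rate(baselineWindow)
    rDrug <- rate(drugWindow)
    flags <- character(0)
    fold <- if (rBase > 0) rDrug / rBase else {
        flags <- "zero baseline event rate; fold change undefined"
        NA_real_
    }
    new("AgonistResponse", baselineCurrent = baseI,
        maxInwardCurrent = maxInward, freqFoldChange = fold,
        responder = !is.na(fold) && fold >= config@responderFoldThreshold,
        flags = flags)
}
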