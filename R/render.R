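## Peak-normalised quantal kernel sampled on the trace grid.
quantalKernel <- function(params, fs) {
    tk <- seq(0, 8 * params@tauDecay, by = 1 / fs)
    (exp(-tk / params@tauDecay) - exp(-tk / params@tauRise)) /
        kernelPeakFactor(params@tauRise, params@tauDecay)
}

## Convolve an impulse train (peak-amplitude units at sample resolution)
## with the quantal kernel via FFT.
convolveKernel <- function(imp, kernel) {
    n <- length(imp)
    m <- length(kernel)
    N <- stats::nextn(n + m - 1L, 2L)  # power-of-two FFT length
    fi <- stats::fft(c(imp, numeric(N - n)))
    fk <- stats::fft(c(kernel, numeric(N - m)))
    Re(stats::fft(fi * fk, inverse = TRUE))[seq_len(n)] / N
}

lognormAmps <- function(nEvents, params) {
    if (params@qCv <= 0) return(rep(params@qMean, nEvents))
    sdlog <- sqrt(log(1 + params@qCv^2))
    stats::rlnorm(nEvents, log(params@qMean) - sdlog^2 / 2, sdlog)
}

## Smooth on/off gate for the agonist direct current (raised-cosine edges).
smoothGate <- function(times, window, ramp = 0.5) {
    g <- numeric(length(times))
    up <- times >= window[1L] & times < window[1L] + ramp
    g[up] <- 0.5 * (1 - cos(pi * (times[up] - window[1L]) / ramp))
    g[times >= window[1L] + ramp & times <= window[2L]] <- 1
    dn <- times > window[2L] & times < window[2L] + ramp
    g[dn] <- 0.5 * (1 + cos(pi * (times[dn] - window[2L]) / ramp))
    g
}

#' Render a current trace from simulated ground truth
#'
#' Each released quantum contributes a peak-normalised double-exponential
#' kernel \eqn{A (e^{-t/\tau_d} - e^{-t/\tau_r})/k}; amplitudes A are
#' lognormal with mean \code{qMean} and CV \code{qCv} (fixed by the seed).
#' In deterministic mode the expected synchronous quanta per AP and the
#' continuous release-rate trace are rendered as their expectation, and no
#' noise is added. Gaussian noise of SD \code{noiseSd} is added in
#' stochastic mode, and \code{englerinMode} adds a smooth direct inward
#' current during the agonist window. Sign convention: inward negative.
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param params a \linkS4class{SimParams}.
#' @param duration trace duration (s).
#' @return A \linkS4class{CurrentTrace}.
#' @export
renderCurrent <- function(truth, params, duration) {
    validObject(params)
    fs <- params@samplingRate
    nS <- ceiling(duration * fs)
    times <- (seq_len(nS) - 1L) / fs
    stochastic <- !params@deterministic
    imp <- numeric(nS)

    addEvents <- function(imp, tEv, amps) {
        idx <- round(tEv * fs) + 1L
        ok <- idx >= 1L & idx <= nS
        if (any(ok)) {
            agg <- rowsum(amps[ok], idx[ok])
            ii <- as.integer(rownames(agg))
            imp[ii] <- imp[ii] + agg[, 1L]
        }
        imp
    }

    if (stochastic) {
        ev <- c(truth@syncTimes, truth@asyncTimes, truth@miniTimes)
        if (any(ev >= duration))
            stop("event times must lie within the trace duration")
        if (length(ev))
            imp <- addEvents(imp, ev, lognormAmps(length(ev), params))
    } else {
        if (length(truth@apTimes)) {
            tEv <- truth@apTimes + params@syncLatency
            imp <- addEvents(imp, tEv, truth@syncQuanta * params@qMean)
        }
        if (length(truth@contRate)) {
            r <- stats::approx(truth@occupancyTimes, truth@contRate,
                xout = times, rule = 2)$y
            imp <- imp + r / fs * params@qMean
        }
    }

    current <- -convolveKernel(imp, quantalKernel(params, fs))
    if (params@englerinMode && length(truth@englerinWindow) == 2L)
        current <- current -
            params@englerinCurrent * smoothGate(times, truth@englerinWindow)
    if (stochastic && params@noiseSd > 0)
        current <- current + stats::rnorm(nS, 0, params@noiseSd)

    currentTrace(current, samplingRate = fs,
        metadata = list(simulated = TRUE,
            deterministic = params@deterministic))
}

#' Simulate a complete recording
#'
#' Composition of \code{\link{simulateCalcium}}, \code{\link{simulatePool}}
#' and \code{\link{renderCurrent}}. Identical (params, protocol, seed) give
#' bit-identical outputs; the pool simulation seeds the RNG stream with
#' \code{params@seed} and the renderer continues the same stream.
#'
#' @param params a \linkS4class{SimParams}.
#' @param protocol a \linkS4class{StimulusProtocol}.
#' @param duration optional trace duration (s).
#' @return list with elements \code{trace} (\linkS4class{CurrentTrace}),
#'   \code{ca} (\linkS4class{CaTrace}) and \code{truth}
#'   (\linkS4class{GroundTruth}).
#' @examples
#' sim <- simulateExperiment(simParams(deterministic = TRUE),
#'     stimulusProtocol(trainCount = 4))
#' @export
simulateExperiment <- function(params, protocol, duration = NULL) {
    if (is.null(duration))
        duration <- protocolDuration(params, protocol)
    ca <- simulateCalcium(params, protocol, duration)
    truth <- simulatePool(params, ca, protocol)
    trace <- renderCurrent(truth, params, duration)
    list(trace = trace, ca = ca, truth = truth)
}

#' Simulate a hypertonic sucrose application
#'
#' The pool empties at rate \code{sucroseRate} per vesicle while baseline
#' replenishment continues: dN/dt = -r N + k0 (nMax - N). The release-rate
#' current r N(t) q produces a decaying transient whose charge equals the
#' RRP charge when k0 = 0, plus a constant replenishment-release plateau for
#' k0 > 0 that persists to the end of the application.
#'
#' @param params a \linkS4class{SimParams}.
#' @param window application window (start, end) in s; default 5 s starting
#'   at 0.5 s.
#' @param duration trace duration (s).
#' @return A \linkS4class{CurrentTrace} with the window and the true RRP
#'   charge recorded in its metadata.
#' @export
simulateSucrose <- function(params, window = c(0.5, 5.5),
                            duration = window[2L] + 0.5) {
    validObject(params)
    stochastic <- !params@deterministic
    if (stochastic) {
        if (is.na(params@seed))
            stop("seed is required in stochastic mode (configuration error)")
        set.seed(params@seed)
    }
    fs <- params@samplingRate
    dt <- params@dt
    tg <- seq(0, duration, by = dt)
    N <- numeric(length(tg))
    Ni <- as.numeric(params@nMax)
    r <- params@sucroseRate
    k0 <- params@k0
    inWin <- tg >= window[1L] & tg <= window[2L]
    for (i in seq_along(tg)) {
        rel <- if (inWin[i]) r * Ni else 0
        Ni <- Ni + dt * (k0 * (params@nMax - Ni) - rel)
        N[i] <- Ni
    }
    rate <- ifelse(inWin, r * pmax(c(params@nMax, N[-length(N)]), 0), 0)

    nS <- ceiling(duration * fs)
    times <- (seq_len(nS) - 1L) / fs
    rateS <- stats::approx(tg, rate, xout = times, rule = 2)$y
    imp <- numeric(nS)
    if (stochastic) {
        lam <- rateS / fs
        kEv <- stats::rpois(nS, lam)
        idx <- which(kEv > 0)
        if (length(idx)) {
            tEv <- rep(times[idx], kEv[idx])
            amps <- lognormAmps(length(tEv), params)
            agg <- rowsum(amps, rep(idx, kEv[idx]))
            imp[as.integer(rownames(agg))] <- agg[, 1L]
        }
    } else {
        imp <- rateS / fs * params@qMean
    }
    current <- -convolveKernel(imp, quantalKernel(params, fs))
    if (stochastic && params@noiseSd > 0)
        current <- current + stats::rnorm(nS, 0, params@noiseSd)
    currentTrace(current, samplingRate = fs,
        metadata = list(sucrose_window = window,
            true_rrp_charge = trueRrpChargeOf(params)))
}

#' Default parameters of the fluorescence reporter model
#'
#' @param kd half-saturation calcium (nM) of the indicator; the default
#'   1000 nM keeps the reporter within its dynamic range over the bulk
#'   calcium excursions the simulator produces.
#' @param nHill Hill coefficient.
#' @param fRest resting fluorescence (counts).
#' @param rMax maximal fractional fluorescence increase at saturation.
#' @param photonNoise add Poisson photon noise?
#' @return named list of reporter parameters.
#' @export
gcampParams <- function(kd = 1000, nHill = 2, fRest = 100, rMax = 5,
                        photonNoise = TRUE) {
    list(kd = kd, nHill = nHill, fRest = fRest, rMax = rMax,
        photonNoise = photonNoise)
}

#' Render a fluorescence imaging stack from a calcium trace
#'
#' Synaptic ROIs are placed at random non-overlapping positions; per frame,
#' ROI fluorescence is \code{fRest * (1 + rMax * hill(Cbar; kd, nHill))}
#' where Cbar is the mean calcium over the frame interval, background pixels
#' sit at \code{fRest}, and Poisson photon noise is added when enabled.
#'
#' @param ca a \linkS4class{CaTrace}.
#' @param nSynapses number of synapse ROIs to place.
#' @param gcamp reporter parameters from \code{\link{gcampParams}}.
#' @param frameRate acquisition rate (Hz); must not exceed 1/ca@dt.
#' @param seed RNG seed for placement and photon noise.
#' @param dims frame dimensions (rows, cols).
#' @param roiSize ROI edge length in pixels.
#' @param prestimulusFrames frames before the stimulus (metadata).
#' @return list with \code{stack} (an \linkS4class{ImagingStack}) and
#'   \code{rois} (data.frame of ROI origins row, col).
#' @export
renderImaging <- function(ca, nSynapses, gcamp = gcampParams(),
                          frameRate = 5, seed = 1L, dims = c(64L, 64L),
                          roiSize = 4L, prestimulusFrames = 3L) {
    if (frameRate > 1 / ca@dt)
        stop("frameRate must not exceed 1/ca@dt")
    set.seed(seed)
    nFrames <- floor(max(ca@times) * frameRate)
    cbar <- vapply(seq_len(nFrames), function(k) {
        sel <- ca@times >= (k - 1L) / frameRate & ca@times < k / frameRate
        mean(ca@concentration[sel])
    }, numeric(1L))
    act <- hillActivation(cbar, gcamp$kd, gcamp$nHill)
    roiF <- gcamp$fRest * (1 + gcamp$rMax * act)

    ## non-overlapping random ROI placement on a roiSize-spaced lattice
    nr <- dims[1L] %/% roiSize
    nc <- dims[2L] %/% roiSize
    if (nSynapses > nr * nc)
        stop("too many synapses for the frame size (placement error)")
    cells <- sample.int(nr * nc, nSynapses)
    rois <- data.frame(
        row = ((cells - 1L) %/% nc) * roiSize + 1L,
        col = ((cells - 1L) %% nc) * roiSize + 1L)

    frames <- array(gcamp$fRest, c(nFrames, dims[1L], dims[2L]))
    for (k in seq_len(nFrames))
        for (s in seq_len(nSynapses)) {
            rr <- rois$row[s]:(rois$row[s] + roiSize - 1L)
            cc <- rois$col[s]:(rois$col[s] + roiSize - 1L)
            frames[k, rr, cc] <- roiF[k]
        }
    if (isTRUE(gcamp$photonNoise))
        frames[] <- stats::rpois(length(frames), frames)
    list(stack = imagingStack(frames, frameRate = frameRate,
            prestimulusFrames = prestimulusFrames),
        rois = rois)
}
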