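## Quantal kernel helpers ----------------------------------------------------

## Peak value of exp(-t/tauD) - exp(-t/tauR) (used to normalise kernels so
## that the drawn amplitude is the peak current).
kernelPeakFactor <- function(tauRise, tauDecay) {
    tStar <- tauRise * tauDecay / (tauDecay - tauRise) *
        log(tauDecay / tauRise)
    exp(-tStar / tauDecay) - exp(-tStar / tauRise)
}

#' Mean charge of one quantum
#'
#' Closed-form integral of the peak-normalised double-exponential quantal
#' kernel times the mean quantal amplitude: q = A (tauDecay - tauRise) / k,
#' where k is the kernel peak factor. Units: pA * s = pC.
#'
#' @param params a \linkS4class{SimParams}.
#' @return mean quantal charge (pC).
#' @export
quantalChargeOf <- function(params) {
    params@qMean * (params@tauDecay - params@tauRise) /
        kernelPeakFactor(params@tauRise, params@tauDecay)
}

#' True RRP charge of a parameter set
#'
#' @param params a \linkS4class{SimParams}.
#' @return nMax times the mean quantal charge (pC).
#' @export
trueRrpChargeOf <- function(params) params@nMax * quantalChargeOf(params)

effectivePr <- function(params)
    min(1, params@pR * (if (params@teaMode) params@fPr else 1))

## ---------------------------------------------------------------------------

#' Simulate vesicle-pool dynamics and release
#'
#' Integrates pool occupancy N on the calcium grid. Between APs,
#' \deqn{dN/dt = k_0 (n_{max} - N) + k_{Ca} (C - c_0)_+ (f_{over} n_{max} - N)}
#' so that baseline replenishment restores (and, after transient overfill,
#' drains back to) the resting capacity, while the calcium-dependent
#' recruitment term can transiently overfill the pool up to
#' \code{overfillFactor * nMax}. At each AP, synchronous release is
#' Binomial(N, pR) (expectation N * pR in deterministic mode). Asynchronous
#' release is an inhomogeneous Poisson process with rate
#' \code{asyncGain * (C - c0)+ * N/nMax}, each event consuming one vesicle;
#' spontaneous minis are Poisson at \code{miniRate0} plus the same
#' calcium-dependent term, without consuming the pool. All sampling uses
#' \code{params@seed}.
#'
#' @param params a \linkS4class{SimParams}.
#' @param ca a \linkS4class{CaTrace} covering the protocol duration.
#' @param protocol a \linkS4class{StimulusProtocol}.
#' @return A \linkS4class{GroundTruth}.
#' @export
simulatePool <- function(params, ca, protocol) {
    validObject(params)
    stochastic <- !params@deterministic
    if (stochastic) {
        if (is.na(params@seed))
            stop("seed is required in stochastic mode (configuration error)")
        set.seed(params@seed)
    }
    if (length(protocol@apTimes) &&
        max(protocol@apTimes) > max(ca@times) + 1e-9)
        stop("calcium trace does not cover the protocol duration")

    dt <- ca@dt
    C <- ca@concentration
    n <- length(C)
    c0 <- ca@restingCa
    nMax <- as.numeric(params@nMax)
    nTot <- params@overfillFactor * nMax
    pr <- effectivePr(params)
    dC <- pmax(0, C - c0)

    apIdx <- if (length(protocol@apTimes))
        pmin(pmax(round(protocol@apTimes / dt) + 1L, 1L), n) else integer(0)

    quiescent <- !length(apIdx) && !params@englerinMode &&
        max(dC) < 1e-9
    if (quiescent) {
        ## Constant-rate regime: N stays at nMax, minis are homogeneous
        ## Poisson at miniRate0.
        dur <- (n - 1L) * dt
        miniTimes <- if (stochastic && params@miniRate0 > 0)
            sort(stats::runif(stats::rpois(1L, params@miniRate0 * dur),
                0, dur)) else numeric(0)
        return(new("GroundTruth", apTimes = numeric(0),
            syncQuanta = numeric(0), syncTimes = numeric(0),
            asyncTimes = numeric(0), asyncExpected = numeric(0),
            miniTimes = miniTimes, occupancyTimes = ca@times,
            occupancy = rep(nMax, n),
            contRate = rep(params@miniRate0, n),
            replenishedQuanta = rep(0, n),
            trueRrpCharge = trueRrpChargeOf(params), truePr = pr,
            trueReplenishmentFlux = 0,
            quantalCharge = quantalChargeOf(params),
            englerinWindow = numeric(0)))
    }

    isAp <- logical(n)
    isAp[apIdx] <- TRUE
    nAp <- length(apIdx)
    syncQuanta <- numeric(nAp)
    syncTimes <- vector("list", nAp)
    asyncTimes <- numeric(0)
    miniTimes <- numeric(0)
    N <- numeric(n)
    replCum <- numeric(n)
    replFlux <- numeric(n)
    contRate <- numeric(n)
    Ni <- nMax
    rc <- 0
    apK <- 0L
    k0 <- params@k0
    kCa <- params@kCa
    gain <- params@asyncGain
    m0 <- params@miniRate0

    for (i in seq_len(n)) {
        if (isAp[i]) {
            apK <- apK + 1L
            rel <- if (stochastic)
                stats::rbinom(1L, max(0L, as.integer(round(Ni))), pr)
            else Ni * pr
            syncQuanta[apK] <- rel
            if (stochastic && rel > 0) {
                tt <- ca@times[i] + params@syncLatency +
                    stats::rnorm(rel, 0, params@syncJitter)
                syncTimes[[apK]] <- tt
            }
            Ni <- Ni - rel
        }
        aRate <- gain * dC[i] * max(Ni, 0) / nMax
        contRate[i] <- m0 + aRate + (if (stochastic) 0 else aRate)
        repl <- k0 * (nMax - Ni) + kCa * dC[i] * max(nTot - Ni, 0)
        replFlux[i] <- repl
        if (stochastic) {
            if (aRate > 0) {
                ka <- stats::rpois(1L, aRate * dt)
                if (ka > 0) {
                    asyncTimes <- c(asyncTimes,
                        ca@times[i] + stats::runif(ka, 0, dt))
                    Ni <- Ni - ka
                }
            }
            mRate <- m0 + aRate
            if (mRate > 0) {
                km <- stats::rpois(1L, mRate * dt)
                if (km > 0)
                    miniTimes <- c(miniTimes,
                        ca@times[i] + stats::runif(km, 0, dt))
            }
            Ni <- Ni + dt * repl
        } else {
            Ni <- Ni + dt * (repl - aRate)
        }
        if (Ni < 0) Ni <- 0
        rc <- rc + dt * repl
        N[i] <- Ni
        replCum[i] <- rc
    }

    ## Expected asynchronous quanta per inter-AP interval (deterministic
    ## bookkeeping; in stochastic mode counts are implied by asyncTimes).
    asyncExpected <- numeric(nAp)
    if (nAp && !stochastic) {
        aRateAll <- gain * dC * pmax(N, 0) / nMax
        bounds <- c(apIdx, n)
        for (k in seq_len(nAp))
            asyncExpected[k] <-
                sum(aRateAll[bounds[k]:(bounds[k + 1L] - 1L)]) * dt
    }

    ## Late-train steady-state replenishment flux (pC/s).
    flux <- 0
    if (nAp >= 2L) {
        tTrainEnd <- ca@times[apIdx[nAp]] +
            (if (!is.na(protocol@trainFrequency))
                1 / protocol@trainFrequency else 0.05)
        sel <- ca@times >= tTrainEnd - 0.25 & ca@times <= tTrainEnd
        if (any(sel))
            flux <- mean(replFlux[sel]) * quantalChargeOf(params)
    }

    new("GroundTruth",
        apTimes = protocol@apTimes, syncQuanta = syncQuanta,
        syncTimes = as.numeric(sort(unlist(syncTimes, use.names = FALSE))),
        asyncTimes = sort(asyncTimes), asyncExpected = asyncExpected,
        miniTimes = sort(miniTimes), occupancyTimes = ca@times,
        occupancy = N, contRate = contRate, replenishedQuanta = replCum,
        trueRrpCharge = trueRrpChargeOf(params), truePr = pr,
        trueReplenishmentFlux = flux,
        quantalCharge = quantalChargeOf(params),
        englerinWindow = englerinWindowOf(params, protocol,
            max(ca@times)))
}
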