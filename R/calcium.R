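#' Hill activation curve
#'
#' Fractional activation c^n / (c^n + ec50^n) of a calcium-activated
#' conductance; the package default for the TRPC-like pathway is a
#' half-activation concentration of 635 nM with Hill coefficient 2.
#'
#' @param c calcium concentration (nM); vectorised.
#' @param ec50 half-activation concentration (nM), > 0.
#' @param n Hill coefficient, >= 1.
#' @return activation fraction in [0, 1], strictly increasing in \code{c}.
#' @examples
#' hillActivation(635, 635, 2)  # 0.5 by definition
#' @export
hillActivation <- function(c, ec50 = 635, n = 2) {
    if (ec50 <= 0) stop("ec50 must be > 0")
    if (n < 1) stop("n must be >= 1")
    if (any(c < 0)) stop("negative concentration (domain error)")
    cn <- (c / ec50)^n
    cn / (cn + 1)
}

#' Chelation-limited calcium capture length
#'
#' Mean three-dimensional diffusion distance r = sqrt(6 * D * tau) a calcium
#' ion travels before capture by a slow chelator with chelation time
#' constant tau; returned in nm. With D = 2.2e-6 cm^2/s and tau = 100 us
#' this exceeds 350 nm, the scale separating active-zone calcium
#' nanodomains from perisynaptic entry sites.
#'
#' @param dCa calcium diffusion coefficient (cm^2/s), > 0.
#' @param tauChel chelation time constant (s), > 0.
#' @return capture length in nm.
#' @examples
#' egtaCaptureLength(2.2e-6, 1e-4)  # ~363 nm
#' @export
egtaCaptureLength <- function(dCa = 2.2e-6, tauChel = 1e-4) {
    if (dCa <= 0 || tauChel <= 0)
        stop("dCa and tauChel must be > 0 (domain error)")
    sqrt(6 * dCa * tauChel) * 1e7  # cm -> nm
}

## Resting fixed point of dC/dt = -(C - cRest)/tau + gE*J*hill(C): scan for
## the first sign change, then polish with uniroot.
restingCalcium <- function(params) {
    gE <- if (params@egtaMode) 1 / (1 + params@egtaKappa) else 1
    f <- function(C) -(C - params@cRest) / params@tauClear +
        gE * params@jTrpc * hillActivation(C, params@ec50Trpc, params@nHill)
    if (params@jTrpc == 0) return(params@cRest)
    upper <- params@cRest + params@tauClear * gE * params@jTrpc
    grid <- seq(params@cRest, upper, length.out = 512L)
    fv <- f(grid)
    i <- which(fv <= 0)[1L]
    if (is.na(i) || i == 1L) return(params@cRest)
    stats::uniroot(f, c(grid[i - 1L], grid[i]), tol = 1e-10)$root
}

## Duration implied by a protocol (last AP + one interval + margin, plus any
## drug/sucrose windows).
protocolDuration <- function(params, protocol, margin = 0.4) {
    tEnd <- 0
    if (length(protocol@apTimes)) {
        isi <- if (!is.na(protocol@trainFrequency))
            1 / protocol@trainFrequency else 0.05
        tEnd <- max(tEnd, max(protocol@apTimes) + isi)
    }
    if (nrow(protocol@drugWindows))
        tEnd <- max(tEnd, max(protocol@drugWindows$end))
    if (length(protocol@sucroseWindow))
        tEnd <- max(tEnd, protocol@sucroseWindow[2L])
    tEnd + margin
}

#' Simulate bulk presynaptic calcium
#'
#' Fixed-step explicit Euler integration of
#' \deqn{dC/dt = -(C - c_{rest})/\tau_{clear} + J_{TRPC} \cdot hill(C)}
#' with an instantaneous bulk increment at every AP time. Under
#' \code{egtaMode} all increments and the TRPC influx term are scaled by
#' 1/(1 + kappa); under \code{teaMode} the per-AP increment is scaled by
#' \code{fTea}; under \code{englerinMode} a constant influx is added during
#' the agonist window. The integration starts at the resting fixed point and
#' is fully deterministic (no RNG).
#'
#' @param params a \linkS4class{SimParams}.
#' @param protocol a \linkS4class{StimulusProtocol}.
#' @param duration total simulated time (s); defaults to the protocol
#'   duration plus a margin.
#' @return A \linkS4class{CaTrace}.
#' @examples
#' ca <- simulateCalcium(simParams(jTrpc = 0, deterministic = TRUE),
#'     stimulusProtocol(trainCount = 1))
#' @export
simulateCalcium <- function(params, protocol, duration = NULL) {
    validObject(params)
    validObject(protocol)
    if (is.null(duration))
        duration <- protocolDuration(params, protocol)
    dt <- params@dt
    n <- ceiling(duration / dt) + 1L
    times <- (seq_len(n) - 1L) * dt
    gE <- if (params@egtaMode) 1 / (1 + params@egtaKappa) else 1
    dAp <- params@deltaCap * (if (params@teaMode) params@fTea else 1) * gE
    c0 <- restingCalcium(params)

    apIdx <- pmin(pmax(round(protocol@apTimes / dt) + 1L, 1L), n)
    apAdd <- numeric(n)
    if (length(apIdx)) for (i in apIdx) apAdd[i] <- apAdd[i] + dAp

    engAdd <- numeric(n)
    engWin <- englerinWindowOf(params, protocol, duration)
    if (length(engWin))
        engAdd[times >= engWin[1L] & times <= engWin[2L]] <-
            gE * params@englerinCaInflux

    C <- numeric(n)
    C[1L] <- c0 + apAdd[1L]
    cRest <- params@cRest
    tau <- params@tauClear
    J <- gE * params@jTrpc
    ec50 <- params@ec50Trpc
    nh <- params@nHill
    for (i in seq_len(n - 1L)) {
        ci <- C[i]
        cn <- (ci / ec50)^nh
        dC <- -(ci - cRest) / tau + J * cn / (cn + 1) + engAdd[i]
        C[i + 1L] <- ci + dt * dC + apAdd[i + 1L]
        if (C[i + 1L] < 0 || !is.finite(C[i + 1L]))
            stop("calcium integration unstable; reduce dt")
    }
    new("CaTrace", times = times, concentration = C, dt = dt,
        restingCa = c0)
}

## Agonist window: taken from the protocol's drug windows when a window
## labelled "EnglerinA" exists, otherwise the whole post-margin epoch.
englerinWindowOf <- function(params, protocol, duration) {
    if (!params@englerinMode) return(numeric(0))
    dw <- protocol@drugWindows
    if (nrow(dw)) {
        hit <- grepl("englerin", dw$label, ignore.case = TRUE)
        if (any(hit))
            return(c(dw$start[which(hit)[1L]], dw$end[which(hit)[1L]]))
        return(c(dw$start[1L], dw$end[1L]))
    }
    c(duration * 0.3, duration * 0.8)
}
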