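#' Measure a single EPSC amplitude at a stimulus time
#'
#' Peak sign-flipped current in (t + artifactBlank, t +
#' amplitudeSearchWindow] minus the local 1-ms pre-stimulus baseline.
#'
#' @param trace a \linkS4class{CurrentTrace}.
#' @param tStim stimulus time (s).
#' @param config an \linkS4class{AnalysisConfig}.
#' @return amplitude (pA, positive magnitude).
#' @export
measureAmplitudeAt <- function(trace, tStim, config = analysisConfig()) {
    fs <- trace@samplingRate
    y <- -(trace@samples)
    tIdx <- function(t) pmin(pmax(round((t - trace@startTime) * fs) + 1L, 1L),
        length(y))
    base <- mean(y[tIdx(tStim - config@baselineWindow):
        max(tIdx(tStim - config@baselineWindow), tIdx(tStim - 1 / fs))])
    max(y[tIdx(tStim + config@artifactBlank):
        tIdx(tStim + config@amplitudeSearchWindow)]) - base
}

#' Simulate and analyse a recovery-from-depression experiment
#'
#' Runs one simulated high-frequency train per test interval with a single
#' test pulse delivered that interval after the last train stimulus,
#' measures the test amplitude relative to the first train amplitude, and
#' fits the single-exponential recovery model with
#' \code{\link{fitRecovery}}.
#'
#' @param params a \linkS4class{SimParams}. In stochastic mode the seed of
#'   run i is \code{params@seed + i}.
#' @param intervals test intervals (s after the last train AP); defaults to
#'   the standard eight.
#' @param trainFrequency,trainCount,trainStart train geometry.
#' @param config an \linkS4class{AnalysisConfig}.
#' @return list with \code{fractions}, \code{intervals} and \code{fit}
#'   (a \linkS4class{RecoveryFit}).
#' @export
recoveryExperiment <- function(params,
                               intervals = defaultRecoveryIntervals(),
                               trainFrequency = 20, trainCount = 40,
                               trainStart = 0.2,
                               config = analysisConfig()) {
    tLast <- trainStart + (trainCount - 1L) / trainFrequency
    fractions <- numeric(length(intervals))
    amp1 <- NA_real_
    for (i in seq_along(intervals)) {
        pI <- params
        if (!params@deterministic && !is.na(params@seed))
            pI@seed <- params@seed + i
        tTest <- tLast + intervals[i]
        protocol <- stimulusProtocol(
            apTimes = c(trainStart + seq(0L, trainCount - 1L) /
                trainFrequency, tTest),
            trainFrequency = trainFrequency, trainCount = trainCount)
        sim <- simulateExperiment(pI, protocol, duration = tTest + 0.1)
        a1 <- measureAmplitudeAt(sim$trace, trainStart, config)
        fractions[i] <- measureAmplitudeAt(sim$trace, tTest, config) / a1
        if (i == 1L) amp1 <- a1
    }
    list(fractions = fractions, intervals = intervals,
        fit = fitRecovery(fractions, 1, intervals))
}

#' Deterministic sweep over the TRPC influx strength
#'
#' Simulates one deterministic train experiment per \code{jTrpc} value and
#' returns the analysed train metrics per value.
#'
#' @param jTrpcValues TRPC influx rates (nM/s) to sweep.
#' @param params base \linkS4class{SimParams} (forced deterministic).
#' @param protocol a \linkS4class{StimulusProtocol}.
#' @param config an \linkS4class{AnalysisConfig}.
#' @return data.frame with one row per value: jTrpc, amp1, ppr, steRatio,
#'   asyncChargeLast, replenishmentRate, rrpCharge.
#' @export
sweepJtrpc <- function(jTrpcValues, params = simParams(),
                       protocol = stimulusProtocol(),
                       config = analysisConfig()) {
    rows <- lapply(jTrpcValues, function(j) {
        p <- params
        p@jTrpc <- j
        p@deterministic <- TRUE
        sim <- simulateExperiment(p, protocol)
        tm <- analyzeTrain(sim$trace, protocol, config)
        data.frame(jTrpc = j, amp1 = tm@amplitudes[1L], ppr = tm@ppr,
            steRatio = tm@steRatio,
            asyncChargeLast = tm@asyncCharge[length(tm@asyncCharge)],
            replenishmentRate = tm@replenishmentRate,
            rrpCharge = if (is.na(tm@rrpCharge)) NA_real_ else tm@rrpCharge)
    })
    do.call(rbind, rows)
}

#' Run a complete simulate-and-analyse pipeline into an output directory
#'
#' Simulates a train experiment, analyses it, and writes the trace
#' (CSV + JSON sidecar), the ground truth, the train metrics, a comparison
#' of estimated versus true parameters, and a run manifest recording the
#' package version, seed, configuration (with MD5 checksums of every
#' output). Rerunning with identical inputs reproduces the trace and
#' result files byte-identically.
#'
#' @param params a \linkS4class{SimParams}.
#' @param protocol a \linkS4class{StimulusProtocol}.
#' @param config an \linkS4class{AnalysisConfig}.
#' @param seed seed overriding \code{params@seed} (optional).
#' @param outDir output directory (created if missing).
#' @return invisibly, a list with \code{metrics}, \code{truth} and
#'   \code{manifest}.
#' @export
runEndToEnd <- function(params = simParams(), protocol = stimulusProtocol(),
                        config = analysisConfig(), seed = NULL,
                        outDir) {
    if (!is.null(seed)) params@seed <- as.integer(seed)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
        trace = file.path(outDir, "trace.csv"),
        truth = file.path(outDir, "ground_truth.json"),
        metrics = file.path(outDir, "train_metrics.csv"),
        comparison = file.path(outDir, "estimates_vs_truth.csv"),
        config = file.path(outDir, "config.json"),
        protocol = file.path(outDir, "protocol.json"),
        manifest = file.path(outDir, "manifest.json"))

    sim <- simulateExperiment(params, protocol)
    tm <- analyzeTrain(sim$trace, protocol, config)

    writeTrace(sim$trace, paths$trace)
    writeProtocol(protocol, paths$protocol)
    writeConfig(config, paths$config)
    jsonlite::write_json(list(
        ap_times_s = sim$truth@apTimes,
        sync_quanta = sim$truth@syncQuanta,
        n_async_events = length(sim$truth@asyncTimes),
        true_rrp_charge_pc = sim$truth@trueRrpCharge,
        true_pr = sim$truth@truePr,
        true_replenishment_flux_pc_s = sim$truth@trueReplenishmentFlux,
        quantal_charge_pc = sim$truth@quantalCharge),
        paths$truth, auto_unbox = TRUE, digits = NA)
    utils::write.csv(data.frame(
        stimulus = seq_along(tm@amplitudes),
        amplitude_pA = tm@amplitudes,
        total_charge_pC = tm@totalCharge,
        sync_charge_pC = tm@syncCharge,
        async_charge_pC = tm@asyncCharge,
        cumulative_sync_pC = tm@cumulativeSync,
        cumulative_total_pC = tm@cumulativeTotal),
        paths$metrics, row.names = FALSE)
    utils::write.csv(data.frame(
        quantity = c("rrp_charge_pc", "pr", "replenishment_rate_pc_s"),
        estimated = c(tm@rrpCharge, tm@pr, tm@replenishmentRate),
        truth = c(sim$truth@trueRrpCharge, sim$truth@truePr,
            sim$truth@trueReplenishmentFlux)),
        paths$comparison, row.names = FALSE)

    outFiles <- unlist(paths[names(paths) != "manifest"])
    md5 <- tools::md5sum(outFiles)
    names(md5) <- names(outFiles)
    manifest <- list(
        package = "presynaptica",
        version = as.character(utils::packageVersion("presynaptica")),
        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
        seed = params@seed,
        deterministic = params@deterministic,
        config_md5 = unname(tools::md5sum(paths$config)),
        outputs = as.list(md5))
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
        digits = NA)
    invisible(list(metrics = tm, truth = sim$truth, manifest = manifest))
}
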