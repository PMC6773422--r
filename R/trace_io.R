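## File formats: traces are two-column CSV (time_s, current_pA) with a JSON
## sidecar (<path>.json) carrying sampling rate, units and metadata; imaging
## stacks are multi-page TIFF with a JSON sidecar; protocols and configs are
## plain JSON.

sidecarPath <- function(path) paste0(path, ".json")

#' Write a CurrentTrace to CSV with a JSON sidecar
#'
#' Writes a two-column CSV (\code{time_s}, \code{current_pA}) and a JSON
#' sidecar \code{<path>.json} with sampling rate, units and metadata. The
#' round trip through \code{\link{readTrace}} reproduces samples to within
#' 1e-9 pA and preserves all metadata.
#'
#' @param trace a \linkS4class{CurrentTrace}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeTrace <- function(trace, path) {
    validObject(trace)
    df <- data.frame(time_s = traceTimes(trace),
        current_pA = trace@samples)
    ok <- tryCatch({
        utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = NA),
            path, row.names = FALSE, quote = FALSE)
        TRUE
    }, error = function(e) e)
    if (!isTRUE(ok))
        stop("cannot write trace to '", path, "': ",
            conditionMessage(ok))
    side <- list(
        sampling_rate_hz = trace@samplingRate,
        units = "pA",
        start_time_s = trace@startTime,
        channel_label = trace@channelLabel,
        metadata = trace@metadata
    )
    jsonlite::write_json(side, sidecarPath(path), auto_unbox = TRUE,
        digits = NA, null = "null")
    invisible(path)
}

#' Read a CurrentTrace from CSV + JSON sidecar
#'
#' The sidecar must declare \code{sampling_rate_hz} and \code{units}
#' (\code{"pA"} or \code{"nA"}; nA samples are converted to pA on read).
#'
#' @param path CSV path written by \code{\link{writeTrace}} (or compatible).
#' @return A \linkS4class{CurrentTrace} in pA.
#' @export
readTrace <- function(path) {
    if (!file.exists(path))
        stop("trace file '", path, "' does not exist")
    sp <- sidecarPath(path)
    if (!file.exists(sp))
        stop("missing JSON sidecar '", sp, "' (format error)")
    side <- jsonlite::read_json(sp, simplifyVector = TRUE)
    if (is.null(side$sampling_rate_hz) || is.null(side$units))
        stop("sidecar must declare sampling_rate_hz and units (format error)")
    sr <- as.numeric(side$sampling_rate_hz)
    if (!is.finite(sr) || sr <= 0)
        stop("invalid sampling rate in sidecar")
    df <- utils::read.csv(path)
    cur <- as.numeric(df$current_pA)
    scale <- switch(tolower(side$units), pa = 1, na = 1000,
        stop("unknown units '", side$units, "' in sidecar"))
    meta <- side$metadata
    if (is.null(meta)) meta <- list()
    if (!is.list(meta)) meta <- as.list(meta)
    currentTrace(cur * scale, samplingRate = sr,
        startTime = if (is.null(side$start_time_s)) 0 else
            as.numeric(side$start_time_s),
        channelLabel = if (is.null(side$channel_label)) "Imon" else
            side$channel_label,
        metadata = meta)
}

#' Write a StimulusProtocol to JSON
#'
#' @param protocol a \linkS4class{StimulusProtocol}.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
writeProtocol <- function(protocol, path) {
    validObject(protocol)
    obj <- list(
        ap_times_s = protocol@apTimes,
        train_frequency_hz = protocol@trainFrequency,
        train_count = protocol@trainCount,
        recovery_intervals_s = protocol@recoveryIntervals,
        sucrose_window_s = protocol@sucroseWindow,
        drug_windows = protocol@drugWindows,
        basal_frequency_hz = protocol@basalFrequency
    )
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
        dataframe = "rows", null = "null")
    invisible(path)
}

#' Load a StimulusProtocol from JSON
#'
#' Accepts either explicit fields (as written by
#' \code{\link{writeProtocol}}) or the shorthand
#' \code{{"train": {"freq": 20, "count": 40, "t0": 0.1}}}, which is
#' expanded to explicit AP times. A \code{"recovery": "default"} entry
#' expands to the standard eight test-pulse intervals.
#'
#' @param path JSON path.
#' @return A \linkS4class{StimulusProtocol}.
#' @export
loadProtocol <- function(path) {
    if (!file.exists(path))
        stop("protocol file '", path, "' does not exist")
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!is.null(obj$train)) {
        tr <- obj$train
        if (is.null(tr$freq) || is.null(tr$count))
            stop("train shorthand needs 'freq' and 'count'")
        if (as.integer(tr$count) < 1L)
            stop("train count must be >= 1 (validation error)")
        t0 <- if (is.null(tr$t0)) 0 else as.numeric(tr$t0)
        ri <- obj$recovery
        if (is.null(ri)) ri <- numeric(0)
        if (identical(ri, "default")) ri <- defaultRecoveryIntervals()
        return(stimulusProtocol(trainFrequency = as.numeric(tr$freq),
            trainCount = as.integer(tr$count), trainStart = t0,
            recoveryIntervals = as.numeric(ri),
            sucroseWindow = as.numeric(obj$sucrose_window_s %||% numeric(0)),
            drugWindows = asDrugWindows(obj$drug_windows),
            basalFrequency = as.numeric(obj$basal_frequency_hz %||% 0.2)))
    }
    ri <- obj$recovery_intervals_s
    if (identical(ri, "default")) ri <- defaultRecoveryIntervals()
    new("StimulusProtocol",
        apTimes = as.numeric(obj$ap_times_s),
        trainFrequency = as.numeric(obj$train_frequency_hz %||% NA_real_),
        trainCount = as.integer(obj$train_count %||% 0L),
        recoveryIntervals = as.numeric(ri %||% numeric(0)),
        sucroseWindow = as.numeric(obj$sucrose_window_s %||% numeric(0)),
        drugWindows = asDrugWindows(obj$drug_windows),
        basalFrequency = as.numeric(obj$basal_frequency_hz %||% 0.2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

asDrugWindows <- function(x) {
    if (is.null(x) || (is.data.frame(x) && !nrow(x)) || !length(x))
        return(data.frame(label = character(0), start = numeric(0),
            end = numeric(0), stringsAsFactors = FALSE))
    df <- as.data.frame(x, stringsAsFactors = FALSE)
    df$start <- as.numeric(df$start)
    df$end <- as.numeric(df$end)
    df
}

#' Write an ImagingStack to multi-page TIFF with a JSON sidecar
#'
#' Pixel counts are scaled into [0, 1] by the stack maximum and stored as
#' 32-bit float; the scale factor, frame rate, prestimulus frame count and
#' pixel size are recorded in \code{<path>.json}.
#'
#' @param stack an \linkS4class{ImagingStack}.
#' @param path output TIFF path.
#' @return \code{path}, invisibly.
#' @export
writeStack <- function(stack, path) {
    validObject(stack)
    mx <- max(stack@frames, 1)
    pages <- lapply(seq_len(dim(stack@frames)[1L]),
        function(i) stack@frames[i, , ] / mx)
    suppressWarnings(tiff::writeTIFF(pages, path, bits.per.sample = 32L,
        reduce = FALSE))
    side <- list(frame_rate_hz = stack@frameRate,
        prestimulus_frames = stack@prestimulusFrames,
        pixel_size_um = stack@pixelSize, count_scale = mx)
    jsonlite::write_json(side, sidecarPath(path), auto_unbox = TRUE,
        digits = NA)
    invisible(path)
}

#' Read an ImagingStack written by \code{\link{writeStack}}
#'
#' @param path TIFF path.
#' @return An \linkS4class{ImagingStack}.
#' @export
readStack <- function(path) {
    if (!file.exists(path))
        stop("stack file '", path, "' does not exist")
    sp <- sidecarPath(path)
    if (!file.exists(sp))
        stop("missing JSON sidecar '", sp, "' (format error)")
    side <- jsonlite::read_json(sp, simplifyVector = TRUE)
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    d <- dim(pages[[1L]])
    arr <- array(0, c(length(pages), d[1L], d[2L]))
    for (i in seq_along(pages)) arr[i, , ] <- pages[[i]]
    arr <- arr * as.numeric(side$count_scale %||% 1)
    imagingStack(arr, frameRate = as.numeric(side$frame_rate_hz %||% 5),
        prestimulusFrames = as.integer(side$prestimulus_frames %||% 3L),
        pixelSize = as.numeric(side$pixel_size_um %||% 0.4))
}

#' Load an AnalysisConfig from JSON
#'
#' Unknown keys are rejected; missing keys keep their defaults.
#'
#' @param path JSON path with named config overrides.
#' @return An \linkS4class{AnalysisConfig}.
#' @export
loadConfig <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    known <- slotNames("AnalysisConfig")
    bad <- setdiff(names(obj), known)
    if (length(bad))
        stop("unknown config keys: ", paste(bad, collapse = ", "))
    do.call(analysisConfig, obj)
}

#' Write an AnalysisConfig to JSON
#'
#' @param config an \linkS4class{AnalysisConfig}.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
writeConfig <- function(config, path) {
    validObject(config)
    obj <- lapply(slotNames("AnalysisConfig"), function(s) slot(config, s))
    names(obj) <- slotNames("AnalysisConfig")
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

## Reject traces too short for the protocol's analysis windows.
checkTraceCovers <- function(trace, tEnd, what = "analysis window") {
    if (duration(trace) + trace@startTime < tEnd - 1e-9)
        stop(sprintf(
            "trace (%.3f s) does not cover the last %s (%.3f s)",
            duration(trace) + trace@startTime, what, tEnd))
    invisible(TRUE)
}
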