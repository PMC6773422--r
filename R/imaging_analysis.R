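roiMeanSeries <- function(frames, origin, size) {
    rr <- origin[1L]:(origin[1L] + size - 1L)
    cc <- origin[2L]:(origin[2L] + size - 1L)
    apply(frames[, rr, cc, drop = FALSE], 1L, mean)
}

## F0 frames: the 3 prestimulus images (the last 3 when more exist).
f0Frames <- function(stack) {
    p <- stack@prestimulusFrames
    seq(max(1L, p - 2L), p)
}

## Pooled background noise SD in dF/F0 units: the non-ROI area is tiled
## into ROI-sized blocks, each tile gets its own dF/F0 series, and the SD
## pools all tiles across the post-baseline frames (background is
## stimulus-free by construction, so every such frame is a valid noise
## sample; the baseline frames are excluded because they share the F0
## estimate and would bias the SD low).
backgroundDffSd <- function(stack, rois, size) {
    d <- dim(stack@frames)
    occupied <- matrix(FALSE, d[2L], d[3L])
    for (s in seq_len(nrow(rois))) {
        rr <- rois$row[s]:min(d[2L], rois$row[s] + size - 1L)
        cc <- rois$col[s]:min(d[3L], rois$col[s] + size - 1L)
        occupied[rr, cc] <- TRUE
    }
    f0f <- f0Frames(stack)
    post <- seq(stack@prestimulusFrames + 1L, d[1L])
    vals <- numeric(0)
    for (r0 in seq(1L, d[2L] - size + 1L, by = size))
        for (c0 in seq(1L, d[3L] - size + 1L, by = size)) {
            if (any(occupied[r0:(r0 + size - 1L), c0:(c0 + size - 1L)]))
                next
            f <- roiMeanSeries(stack@frames, c(r0, c0), size)
            f0 <- mean(f[f0f])
            if (f0 <= 0) next
            vals <- c(vals, (f[post] - f0) / f0)
        }
    if (!length(vals)) return(NA_real_)
    stats::sd(vals)
}

#' Compute a per-ROI delta-F/F0 trace
#'
#' F0 is the ROI mean of the 3 prestimulus images;
#' dff[n] = (Fbar_n - Fbar_0) / Fbar_0 for every frame of the stack. The
#' background noise SD (in dF/F0 units) is estimated from ROI-sized tiles
#' of the non-ROI area pooled across all frames.
#'
#' @param stack an \linkS4class{ImagingStack} with >= 3 prestimulus frames.
#' @param roi ROI origin c(row, col), 1-based top-left pixel.
#' @param config an \linkS4class{AnalysisConfig}.
#' @param allRois optional data.frame(row, col) of every ROI in the field,
#'   excluded from the background estimate; defaults to \code{roi} alone.
#' @param backgroundSd optional pre-computed background noise SD (dF/F0
#'   units); estimated from the stack when NULL.
#' @return A \linkS4class{RoiTrace}; flagged undefined when F0 <= 0.
#' @export
computeDff <- function(stack, roi, config = analysisConfig(),
                       allRois = NULL, backgroundSd = NULL) {
    validObject(stack)
    if (stack@prestimulusFrames < 3L)
        stop("at least 3 prestimulus frames are required")
    size <- config@dffRoiSize
    d <- dim(stack@frames)
    if (roi[1L] < 1L || roi[2L] < 1L || roi[1L] + size - 1L > d[2L] ||
        roi[2L] + size - 1L > d[3L])
        stop("ROI does not lie fully inside the frame")
    if (is.null(allRois))
        allRois <- data.frame(row = roi[1L], col = roi[2L])
    f <- roiMeanSeries(stack@frames, roi, size)
    f0 <- mean(f[f0Frames(stack)])
    bg <- if (is.null(backgroundSd))
        backgroundDffSd(stack, allRois, size) else backgroundSd
    if (f0 <= 0)
        return(new("RoiTrace", roiOrigin = as.integer(roi),
            roiSize = size, dff = rep(NA_real_, d[1L]),
            backgroundSd = bg, f0 = f0, undefined = TRUE))
    new("RoiTrace", roiOrigin = as.integer(roi), roiSize = size,
        dff = (f - f0) / f0, backgroundSd = bg, f0 = f0,
        undefined = FALSE)
}

#' Compute delta-F/F0 for a set of ROIs with a shared background estimate
#'
#' @param stack an \linkS4class{ImagingStack}.
#' @param rois data.frame(row, col) of ROI origins.
#' @param config an \linkS4class{AnalysisConfig}.
#' @return list of \linkS4class{RoiTrace} objects.
#' @export
computeDffAll <- function(stack, rois, config = analysisConfig()) {
    bg <- backgroundDffSd(stack, rois, config@dffRoiSize)
    lapply(seq_len(nrow(rois)), function(s)
        computeDff(stack, c(rois$row[s], rois$col[s]), config,
            allRois = rois, backgroundSd = bg))
}

#' Flag responsive ROIs
#'
#' A ROI is responsive when its maximal dF/F0 strictly exceeds
#' \code{dffSdMult} (default 3) times the background noise SD.
#'
#' @param roiTraces list of \linkS4class{RoiTrace} objects.
#' @param config an \linkS4class{AnalysisConfig}.
#' @return logical vector of responsiveness flags (FALSE for undefined
#'   ROIs).
#' @export
detectResponsive <- function(roiTraces, config = analysisConfig()) {
    vapply(roiTraces, function(r) {
        if (r@undefined || !is.finite(r@backgroundSd)) return(FALSE)
        max(r@dff, na.rm = TRUE) > config@dffSdMult * r@backgroundSd
    }, logical(1L))
}

#' Summary metrics of a delta-F/F0 trace
#'
#' Slopes are OLS slopes of dF/F0 against frame index over the configured
#' during-train (data points 6-13 by default) and post-train (14-20)
#' windows, counted 1-based over the whole acquired series; maxDff is taken
#' over all frames.
#'
#' @param roiTrace a \linkS4class{RoiTrace}.
#' @param config an \linkS4class{AnalysisConfig}.
#' @return A \linkS4class{DffMetrics}.
#' @export
dffMetrics <- function(roiTrace, config = analysisConfig()) {
    v <- roiTrace@dff
    need <- max(config@slopeHfsPoints[2L], config@slopePostPoints[2L])
    if (length(v) < need)
        stop(sprintf("need at least %d frames for the slope windows", need))
    slopeOf <- function(pts) {
        idx <- pts[1L]:pts[2L]
        olsLine(idx, v[idx])$slope
    }
    new("DffMetrics", maxDff = max(v, na.rm = TRUE),
        slopeHfs = slopeOf(config@slopeHfsPoints),
        slopePost = slopeOf(config@slopePostPoints),
        responsive = detectResponsive(list(roiTrace), config))
}

#' Pair imaging metrics with train metrics by cell
#'
#' Joins per-cell dF/F0 slope metrics with per-cell electrophysiological
#' train metrics on the cell identifier and reports the Spearman rank
#' correlation between the during-train dF/F0 slope and the replenishment
#' rate as a descriptive summary.
#'
#' @param imaging data.frame with columns \code{cellId} and
#'   \code{slopeHfs} (and any further metric columns).
#' @param train data.frame with columns \code{cellId} and
#'   \code{replenishmentRate}.
#' @return list with \code{table} (the joined data.frame),
#'   \code{rankCorrelation} and \code{unmatched} (cell ids present in only
#'   one input; these are excluded).
#' @export
pairWithTrain <- function(imaging, train) {
    common <- intersect(imaging$cellId, train$cellId)
    unmatched <- union(setdiff(imaging$cellId, common),
        setdiff(train$cellId, common))
    if (!length(common)) {
        warning("no matching cell identifiers")
        return(list(table = data.frame(), rankCorrelation = NA_real_,
            unmatched = unmatched))
    }
    tab <- merge(imaging[imaging$cellId %in% common, , drop = FALSE],
        train[train$cellId %in% common, , drop = FALSE], by = "cellId")
    rc <- if (nrow(tab) >= 2L)
        stats::cor(tab$slopeHfs, tab$replenishmentRate,
            method = "spearman") else NA_real_
    list(table = tab, rankCorrelation = rc, unmatched = unmatched)
}
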