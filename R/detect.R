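# Variance-based fish detection.
#
# The detector exploits the rig's imaging premise: the tank bottom is
# uniformly bright and the fish is dark, so within a small region of
# interest the pixel-intensity variance is near zero when the region is
# empty and jumps when the fish enters. Global illumination changes
# (auto-exposure, shadows, ripples at the scale of an ROI) are approximately
# uniform additive offsets and leave the variance unchanged, which is why
# variance is used instead of background subtraction.

# Extract ROI pixels from a frame matrix, validating bounds.
roiPixels <- function(frame, roi) {
  if (!is.matrix(frame)) stop("frame must be a numeric matrix")
  r <- roi@rect
  if (r[3] > nrow(frame) || r[4] > ncol(frame))
    stop(sprintf("invalid region '%s': rect exceeds %d x %d frame",
                 roi@name, nrow(frame), ncol(frame)))
  frame[(r[1] + 1L):r[3], (r[2] + 1L):r[4], drop = FALSE]
}

#' Population variance of pixel intensities inside an ROI
#'
#' Computes the variance (divide-by-N convention) of the pixel intensities
#' inside \code{roi}'s rectangle for one frame. This is the per-frame
#' detection statistic: exactly 0 for a constant (empty, uniformly lit)
#' region, and large when the dark fish streak overlaps the region. Adding
#' a uniform offset to every pixel leaves the value unchanged, which makes
#' the statistic robust to global illumination fluctuations.
#'
#' @param frame numeric matrix of intensities in [0, 255].
#' @param roi a \linkS4class{RegionOfInterest} lying inside the frame with at
#'   least 2 pixels.
#' @return the population variance (nonnegative scalar).
#' @examples
#' f <- matrix(200, 10, 10)
#' roiVariance(f, RegionOfInterest("mag", c(0, 0, 10, 10), 1))  # 0
#' @export
roiVariance <- function(frame, roi) {
  px <- as.vector(roiPixels(frame, roi))
  n <- length(px)
  stats::var(px) * (n - 1) / n
}

#' Per-frame variance trace of one ROI over a frame sequence
#'
#' @param frames a 3-D array \code{[rows, cols, frames]} or a list of frame
#'   matrices with identical dimensions.
#' @param roi a \linkS4class{RegionOfInterest}.
#' @return numeric vector, one population variance per frame.
#' @export
varianceTrace <- function(frames, roi) {
  r <- roi@rect
  if (is.array(frames) && length(dim(frames)) == 3L) {
    d <- dim(frames)
    if (r[3] > d[1] || r[4] > d[2])
      stop(sprintf("invalid region '%s': rect exceeds %d x %d frame",
                   roi@name, d[1], d[2]))
    sub <- frames[(r[1] + 1L):r[3], (r[2] + 1L):r[4], , drop = FALSE]
    npx <- prod(dim(sub)[1:2])
    if (npx < 2L) stop("region must contain at least 2 pixels")
    m <- matrix(sub, nrow = npx)
    mu <- colMeans(m)
    colMeans((m - rep(mu, each = npx))^2)  # two-pass, per frame
  } else if (is.list(frames)) {
    vapply(frames, roiVariance, 0, roi = roi)
  } else stop("frames must be a [rows, cols, frames] array or list of matrices")
}

#' One step of the Schmitt-trigger hysteresis rule
#'
#' Pure transition function of the detector state machine. A VACANT region
#' becomes OCCUPIED (edge "ONSET") when the variance strictly exceeds the
#' threshold; an OCCUPIED region becomes VACANT (edge "OFFSET") only when
#' the variance falls strictly below \code{hysteresis * threshold} (80\% by
#' default). Values inside the hysteresis band change nothing, and no new
#' onset can fire while the region is OCCUPIED, which suppresses chatter
#' when the variance hovers near the threshold.
#'
#' @param roi a \linkS4class{RegionOfInterest} carrying the current state.
#' @param variance the current per-frame ROI variance.
#' @return list with elements \code{roi} (updated state) and \code{edge}
#'   ("NONE", "ONSET" or "OFFSET").
#' @export
schmittUpdate <- function(roi, variance) {
  edge <- "NONE"
  if (roi@state == "VACANT") {
    if (variance > roi@threshold) {
      roi@state <- "OCCUPIED"
      edge <- "ONSET"
    }
  } else {
    if (variance < roi@hysteresis * roi@threshold) {
      roi@state <- "VACANT"
      edge <- "OFFSET"
    }
  }
  list(roi = roi, edge = edge)
}

# Run the Schmitt machine over a variance trace; returns integer vectors of
# 0-based onset/offset frame indices (offsets NA while still open at the end).
schmittEdges <- function(trace, roi) {
  onsets <- integer(0); offsets <- integer(0)
  state <- roi@state
  lo <- roi@hysteresis * roi@threshold
  hi <- roi@threshold
  for (i in seq_along(trace)) {
    v <- trace[i]
    if (state == "VACANT") {
      if (v > hi) { state <- "OCCUPIED"; onsets <- c(onsets, i - 1L) }
    } else if (v < lo) {
      state <- "VACANT"; offsets <- c(offsets, i - 1L)
    }
  }
  if (length(onsets) > length(offsets)) offsets <- c(offsets, NA_integer_)
  list(onsets = onsets, offsets = offsets)
}

#' Detect fish presence events over a frame stream
#'
#' Runs the per-frame variance statistic and the Schmitt-trigger state
#' machine for every region, emitting one detection event per completed
#' occupancy. Every region starts VACANT. An event still open at the end of
#' the stream has \code{NA} offset.
#'
#' @param frames 3-D array \code{[rows, cols, frames]} or list of matrices.
#' @param rois list of \linkS4class{RegionOfInterest}.
#' @param fps frames per second; converts frame indices to seconds.
#' @return data.frame with columns \code{region}, \code{onset_frame},
#'   \code{offset_frame} (0-based), \code{onset_time_s}, \code{offset_time_s},
#'   ordered by onset frame. Events of one region never overlap.
#' @export
processStream <- function(frames, rois, fps = 50) {
  nFrames <- if (is.array(frames)) dim(frames)[3] else length(frames)
  if (is.null(nFrames) || nFrames == 0L) return(emptyEvents())
  rows <- lapply(rois, function(roi) {
    e <- schmittEdges(varianceTrace(frames, roi), roi)
    if (!length(e$onsets)) return(NULL)
    data.frame(region = roi@name,
               onset_frame = e$onsets, offset_frame = e$offsets,
               stringsAsFactors = FALSE)
  })
  ev <- do.call(rbind, rows)
  if (is.null(ev) || !nrow(ev)) return(emptyEvents())
  ev <- ev[order(ev$onset_frame, ev$region), , drop = FALSE]
  rownames(ev) <- NULL
  ev$onset_time_s <- ev$onset_frame / fps
  ev$offset_time_s <- ev$offset_frame / fps
  ev[, c("region", "onset_frame", "offset_frame",
         "onset_time_s", "offset_time_s")]
}

emptyEvents <- function() {
  data.frame(region = character(0), onset_frame = integer(0),
             offset_frame = integer(0), onset_time_s = numeric(0),
             offset_time_s = numeric(0), stringsAsFactors = FALSE)
}

#' Suggest a variance threshold from a recorded trace
#'
#' Offline replacement for the interactive threshold-setting step: given a
#' variance trace recorded while the region was mostly vacant, place the
#' threshold halfway between the \code{vacantFraction} quantile (the top of
#' the empty-region noise floor) and the trace maximum (fish present).
#' Deterministic for a fixed trace.
#'
#' @param varianceTrace numeric vector of per-frame ROI variances.
#' @param vacantFraction fraction of the trace assumed fish-free, in (0, 1);
#'   default 0.9.
#' @return a threshold strictly above the \code{vacantFraction} quantile.
#' @export
suggestThreshold <- function(varianceTrace, vacantFraction = 0.9) {
  if (!length(varianceTrace)) stop("empty variance trace")
  if (vacantFraction <= 0 || vacantFraction >= 1)
    stop("vacantFraction must lie in (0, 1)")
  lo <- min(varianceTrace); hi <- max(varianceTrace)
  if (hi - lo < .Machine$double.eps * max(1, abs(hi)))
    stop("degenerate constant variance trace: set the threshold manually")
  q <- as.numeric(stats::quantile(varianceTrace, vacantFraction, names = FALSE))
  thr <- q + 0.5 * (hi - q)
  if (thr <= q)
    stop("trace not separable above the vacant quantile: set the threshold manually")
  thr
}

#' Read an image sequence as a frame stream
#'
#' Pluggable frame input for pre-recorded video exported as numbered PNG or
#' TIFF images (one grayscale image per frame). Color images are converted
#' by unweighted channel mean. Requires the \pkg{png} or \pkg{tiff} package.
#'
#' @param paths character vector of image files, in frame order.
#' @return a 3-D array \code{[rows, cols, frames]} with intensities in
#'   [0, 255].
#' @export
readFrameImages <- function(paths) {
  if (!length(paths)) stop("no image paths given")
  readOne <- function(p) {
    img <- if (grepl("\\.png$", p, ignore.case = TRUE)) {
      if (!requireNamespace("png", quietly = TRUE))
        stop("package 'png' required to read PNG frames")
      png::readPNG(p)
    } else if (grepl("\\.tiff?$", p, ignore.case = TRUE)) {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("package 'tiff' required to read TIFF frames")
      tiff::readTIFF(p)
    } else stop("unsupported image format: ", p)
    if (length(dim(img)) == 3L) img <- rowMeans(img, dims = 2L)
    img * 255
  }
  first <- readOne(paths[1])
  out <- array(NA_real_, c(dim(first), length(paths)))
  out[, , 1] <- first
  for (i in seq_along(paths)[-1]) {
    f <- readOne(paths[i])
    if (!identical(dim(f), dim(first)))
      stop("inconsistent frame dimensions at ", paths[i])
    out[, , i] <- f
  }
  out
}
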