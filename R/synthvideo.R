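# Synthetic tank video: a reproducible fixture generator emulating the rig
# camera. Real footage shows a uniformly bright tank bottom, global
# illumination fluctuations (camera auto-exposure reacting to the stimulus
# LEDs, room shadows), water-ripple noise, and the fish as a dark streak of
# roughly 30 x 5 pixels with no internal detail. The generator reproduces
# exactly those ingredients and nothing more.

#' Construct a SyntheticScene
#'
#' @param dims frame size c(nrow, ncol); default c(100, 300) keeps test
#'   videos small (the physical camera was 360 x 640).
#' @param backgroundLevel mean background intensity; default 220 (bright
#'   white tank bottom).
#' @param illuminationDrift numeric vector of per-frame uniform additive
#'   offsets, recycled over the stream; default 0.
#' @param rippleSigma pixel-noise standard deviation; default 2.
#' @param fishLengthPx,fishWidthPx streak size; defaults 30 x 5.
#' @param fishIntensity streak intensity; default 40 (dark fish); must be
#'   below \code{backgroundLevel}.
#' @param trajectory data.frame(frame, row, col) of 0-based frame indices
#'   and 0-based streak-center positions; frames not listed have no fish.
#' @param seed integer RNG seed; the same scene renders bit-identically.
#' @return a \linkS4class{SyntheticScene}.
#' @export
SyntheticScene <- function(dims = c(100L, 300L), backgroundLevel = 220,
                           illuminationDrift = 0, rippleSigma = 2,
                           fishLengthPx = 30L, fishWidthPx = 5L,
                           fishIntensity = 40,
                           trajectory = data.frame(frame = integer(0),
                                                   row = numeric(0),
                                                   col = numeric(0)),
                           seed = 1L) {
  new("SyntheticScene", dims = as.integer(dims),
      backgroundLevel = backgroundLevel,
      illuminationDrift = as.numeric(illuminationDrift),
      rippleSigma = rippleSigma, fishLengthPx = as.integer(fishLengthPx),
      fishWidthPx = as.integer(fishWidthPx), fishIntensity = fishIntensity,
      trajectory = trajectory, seed = as.integer(seed))
}

# 0-based pixel block covered by the streak centred at (row, col);
# errors if any part falls outside the frame.
fishBlock <- function(scene, row, col) {
  h <- scene@fishWidthPx; w <- scene@fishLengthPx
  r0 <- as.integer(floor(row - (h - 1) / 2))
  c0 <- as.integer(floor(col - (w - 1) / 2))
  r1 <- r0 + h; c1 <- c0 + w
  if (r0 < 0L || c0 < 0L || r1 > scene@dims[1] || c1 > scene@dims[2])
    stop(sprintf("trajectory places fish outside frame bounds at (%.1f, %.1f)",
                 row, col))
  c(r0, c0, r1, c1)
}

#' Render a synthetic video
#'
#' For each frame: paint the background, paint the fish streak at its
#' scripted position (if present this frame), add the global illumination
#' offset uniformly, add i.i.d. Gaussian ripple noise, and clip to
#' [0, 255]. The whole sequence is a deterministic function of the scene
#' (including its seed).
#'
#' @param scene a \linkS4class{SyntheticScene}.
#' @param nFrames number of frames to render (>= 1).
#' @return 3-D array \code{[rows, cols, frames]} of intensities in [0, 255].
#' @export
makeSyntheticVideo <- function(scene, nFrames) {
  stopifnot(is(scene, "SyntheticScene"), nFrames >= 1)
  nFrames <- as.integer(nFrames)
  d <- scene@dims
  drift <- rep_len(scene@illuminationDrift, nFrames)
  tr <- scene@trajectory
  trIdx <- if (nrow(tr)) split(seq_len(nrow(tr)), tr$frame) else list()
  out <- array(0, c(d[1], d[2], nFrames))
  withSeed(scene@seed, {
    for (f in seq_len(nFrames)) {
      frame <- matrix(scene@backgroundLevel, d[1], d[2])
      rows <- trIdx[[as.character(f - 1L)]]
      if (!is.null(rows)) {
        for (i in rows) {
          b <- fishBlock(scene, tr$row[i], tr$col[i])
          frame[(b[1] + 1L):b[3], (b[2] + 1L):b[4]] <- scene@fishIntensity
        }
      }
      frame <- frame + drift[f]
      if (scene@rippleSigma > 0)
        frame <- frame + matrix(stats::rnorm(d[1] * d[2], 0, scene@rippleSigma),
                                d[1], d[2])
      out[, , f] <- pmin(pmax(frame, 0), 255)
    }
  })
  out
}

#' Write a synthetic video as a PNG image sequence
#'
#' Companion to \code{\link{readFrameImages}}; one grayscale PNG per frame,
#' named \code{frame_000000.png} onwards. Requires the \pkg{png} package.
#'
#' @param frames 3-D array from \code{\link{makeSyntheticVideo}}.
#' @param dir output directory (created if absent).
#' @return character vector of written paths, invisibly.
#' @export
writeFrameImages <- function(frames, dir) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("package 'png' required to write PNG frames")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- dim(frames)[3]
  paths <- file.path(dir, sprintf("frame_%06d.png", seq_len(n) - 1L))
  for (i in seq_len(n)) png::writePNG(frames[, , i] / 255, paths[i])
  invisible(paths)
}
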