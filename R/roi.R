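#' Construct a RegionOfInterest
#'
#' @param name region identifier; the conventional names are
#'   \code{apertureNames()} ("ap1".."ap5") and \code{magazineName()} ("mag").
#' @param rect numeric/integer(4) \code{c(row0, col0, row1, col1)}, 0-based,
#'   half-open.
#' @param threshold variance threshold (> 0).
#' @param hysteresis release fraction of the threshold; default 0.8.
#' @param state initial detector state; "VACANT" at stream start.
#' @return a \linkS4class{RegionOfInterest}.
#' @examples
#' RegionOfInterest("mag", c(10, 20, 30, 50), threshold = 120)
#' @export
RegionOfInterest <- function(name, rect, threshold, hysteresis = 0.8,
                             state = "VACANT") {
  new("RegionOfInterest", name = as.character(name), rect = as.integer(rect),
      threshold = as.numeric(threshold), hysteresis = as.numeric(hysteresis),
      state = state)
}

#' @rdname roiAccessors
#' @param roi a \linkS4class{RegionOfInterest}.
#' @export
roiName <- function(roi) roi@name

#' ROI accessors
#'
#' Read the name, rectangle, threshold and current Schmitt state of a region.
#' @name roiAccessors
#' @return the corresponding slot value.
#' @export
roiRect <- function(roi) roi@rect

#' @rdname roiAccessors
#' @export
roiThreshold <- function(roi) roi@threshold

#' @rdname roiAccessors
#' @export
roiState <- function(roi) roi@state

#' Read an ROI configuration file
#'
#' The configuration is a JSON or YAML array of objects with fields
#' \code{name}, \code{rect} (\code{[row0, col0, row1, col1]}, 0-based
#' half-open), \code{threshold} and optional \code{hysteresis}.
#'
#' @param path file path; format chosen by extension (.yaml/.yml vs .json).
#' @return a named list of \linkS4class{RegionOfInterest} objects.
#' @export
readRoiConfig <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  }
  rois <- lapply(raw, function(x) {
    if (is.null(x$name) || is.null(x$rect) || is.null(x$threshold))
      stop("ROI config entries need name, rect and threshold")
    RegionOfInterest(x$name, unlist(x$rect), x$threshold,
                     hysteresis = if (is.null(x$hysteresis)) 0.8 else x$hysteresis)
  })
  names(rois) <- vapply(rois, roiName, "")
  if (anyDuplicated(names(rois))) stop("duplicate ROI names in config")
  rois
}

#' Write an ROI configuration file
#'
#' Inverse of \code{\link{readRoiConfig}}; \code{readRoiConfig(writeRoiConfig(...))}
#' reproduces the regions.
#'
#' @param rois list of \linkS4class{RegionOfInterest}.
#' @param path output path (.json, .yaml or .yml).
#' @return \code{path}, invisibly.
#' @export
writeRoiConfig <- function(rois, path) {
  lst <- lapply(rois, function(r) {
    list(name = r@name, rect = as.integer(r@rect),
         threshold = r@threshold, hysteresis = r@hysteresis)
  })
  names(lst) <- NULL
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(lst, path)
  } else {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' A standard rig geometry for synthetic scenes
#'
#' Lays out five stimulus-aperture ROIs along the top (curved stimulus wall)
#' and the food-magazine ROI near the bottom of the frame, scaled to the
#' frame size. Used by tests, demos and the end-to-end pipeline; real rigs
#' supply their own measured rectangles via \code{\link{readRoiConfig}}.
#'
#' @param dims frame size c(nrow, ncol).
#' @param threshold variance threshold applied to every region.
#' @param roiRows height of each ROI in pixels.
#' @param roiCols width of each ROI in pixels.
#' @return named list of six \linkS4class{RegionOfInterest} objects
#'   ("ap1".."ap5", "mag").
#' @export
standardRigRois <- function(dims = c(100L, 300L), threshold = 100,
                            roiRows = 30L, roiCols = 40L) {
  nr <- dims[1]; nc <- dims[2]
  gap <- (nc - 5 * roiCols) %/% 6
  if (gap < 1L) stop("frame too narrow for five apertures of that width")
  rois <- vector("list", 6L)
  for (i in 1:5) {
    c0 <- gap * i + roiCols * (i - 1L)
    rois[[i]] <- RegionOfInterest(apertureNames()[i],
                                  c(4L, c0, 4L + roiRows, c0 + roiCols),
                                  threshold)
  }
  magR0 <- nr - roiRows - 4L
  magC0 <- (nc - roiCols) %/% 2L
  rois[[6]] <- RegionOfInterest(magazineName(),
                                c(magR0, magC0, magR0 + roiRows, magC0 + roiCols),
                                threshold)
  names(rois) <- vapply(rois, roiName, "")
  rois
}
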