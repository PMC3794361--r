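# Internal helpers shared across modules.

#' Snap a time to the frame clock
#'
#' Event and command times in a session are quantized to the camera frame
#' clock (1/fps seconds). Flooring (rather than rounding) guarantees that a
#' time strictly before a grid-aligned boundary never lands on the boundary
#' frame, which keeps window classification consistent between the simulator
#' and the controller.
#'
#' @param t time in seconds (vectorized).
#' @param fps frames per second of the acquisition clock.
#' @return time snapped down to the frame grid, in seconds.
#' @keywords internal
quantizeTime <- function(t, fps) {
  # small epsilon absorbs representation error of grid-aligned inputs
  floor(t * fps + 1e-9) / fps
}

#' Derive a reproducible child seed from a global seed and string labels
#'
#' Stable fan-out of one global seed so that, e.g., adding a fish to a cohort
#' does not perturb the random streams of the others.
#'
#' @param seed integer global seed.
#' @param ... labels (coerced to character) identifying the consumer.
#' @return an integer in [1, 2^31 - 2].
#' @export
deriveSeed <- function(seed, ...) {
  lab <- paste(c(as.character(seed), vapply(list(...), as.character, "")),
               collapse = "/")
  h <- 0
  for (code in utf8ToInt(lab)) h <- (h * 31 + code) %% 2147483629
  as.integer(h %% 2147483646 + 1)
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

# Full-precision numeric formatting for bit-exact CSV round trips.
fmtNum <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) NA_character_ else sprintf("%.17g", v)
  }, "")
  out
}

# Region naming conventions: five stimulus apertures and the food magazine.

#' Names of the five stimulus-aperture regions
#' @return character vector "ap1".."ap5".
#' @export
apertureNames <- function() paste0("ap", 1:5)

#' Name of the food-magazine region
#' @return the string "mag".
#' @export
magazineName <- function() "mag"

# Aperture name -> position index (1..5); NA for non-aperture regions.
aperturePosition <- function(region) {
  m <- match(region, apertureNames())
  as.integer(m)
}
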