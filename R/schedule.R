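#' Construct a SessionSchedule
#'
#' Defaults follow the validated training protocol: 30-min sessions, 5-s
#' PSI, 30-s stimulus, 20-s timeout/ITI, 60-s initial hold, magazine light
#' up to 10 s with a 30-s gap, habituation food no more often than every
#' 30 s, 50-fps time base.
#'
#' @param phase "HABITUATION", "MAGAZINE", "STIMULUS_LIGHT" or "FIVE_CSRTT".
#' @param sessionLengthS,psiS,stimulusDurationS,timeoutS,itiS durations (s).
#' @param initialHoldS,magazineLightMaxS,magazineGapS,habituationFoodIntervalS
#'   durations (s).
#' @param feederSteps stepper-motor steps per delivery.
#' @param gateLatencyS gate travel time (s).
#' @param fps camera frame rate (frames per second).
#' @param rngSeed seed for stimulus-position selection.
#' @return a \linkS4class{SessionSchedule}.
#' @examples
#' SessionSchedule("FIVE_CSRTT", psiS = 10)
#' @export
SessionSchedule <- function(phase = "FIVE_CSRTT", sessionLengthS = 1800,
                            psiS = 5, stimulusDurationS = 30, timeoutS = 20,
                            itiS = 20, initialHoldS = 60,
                            magazineLightMaxS = 10, magazineGapS = 30,
                            habituationFoodIntervalS = 30, feederSteps = 40L,
                            gateLatencyS = 0.5, fps = 50, rngSeed = 1L) {
  new("SessionSchedule", phase = phase, sessionLengthS = sessionLengthS,
      psiS = psiS, stimulusDurationS = stimulusDurationS, timeoutS = timeoutS,
      itiS = itiS, initialHoldS = initialHoldS,
      magazineLightMaxS = magazineLightMaxS, magazineGapS = magazineGapS,
      habituationFoodIntervalS = habituationFoodIntervalS,
      feederSteps = as.integer(feederSteps), gateLatencyS = gateLatencyS,
      fps = fps, rngSeed = as.integer(rngSeed))
}

scheduleFields <- function() {
  c("phase", "sessionLengthS", "psiS", "stimulusDurationS", "timeoutS",
    "itiS", "initialHoldS", "magazineLightMaxS", "magazineGapS",
    "habituationFoodIntervalS", "feederSteps", "gateLatencyS", "fps",
    "rngSeed")
}

scheduleToList <- function(schedule) {
  out <- lapply(scheduleFields(), function(f) slot(schedule, f))
  names(out) <- scheduleFields()
  out
}

scheduleFromList <- function(lst) {
  known <- intersect(names(lst), scheduleFields())
  unknown <- setdiff(names(lst), scheduleFields())
  if (length(unknown))
    stop("unknown schedule fields: ", paste(unknown, collapse = ", "))
  do.call(SessionSchedule, lst[known])
}

#' Read a session-schedule configuration file
#'
#' JSON or YAML object whose fields mirror \code{\link{SessionSchedule}}
#' arguments; omitted fields take the protocol defaults.
#'
#' @param path file path (.json, .yaml or .yml).
#' @return a \linkS4class{SessionSchedule}.
#' @export
readSchedule <- function(path) {
  lst <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  }
  scheduleFromList(lst)
}

#' Write a session-schedule configuration file
#'
#' @param schedule a \linkS4class{SessionSchedule}.
#' @param path output path (.json, .yaml or .yml).
#' @return \code{path}, invisibly.
#' @export
writeSchedule <- function(schedule, path) {
  lst <- scheduleToList(schedule)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(lst, path)
  } else {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
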