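# S4 classes for the virtual rig: detection geometry, synthetic scenes,
# session schedules, behavioral agents and session logs.

ROI_STATES <- c("VACANT", "OCCUPIED")
SESSION_PHASES <- c("HABITUATION", "MAGAZINE", "STIMULUS_LIGHT", "FIVE_CSRTT")
TRIAL_OUTCOMES <- c("CORRECT", "INCORRECT", "ANTICIPATORY", "OMISSION")

#' RegionOfInterest: a named pixel region with a detection threshold
#'
#' A small axis-aligned rectangle of the camera image covering one stimulus
#' aperture or the food magazine. Presence of a fish is declared when the
#' population variance of pixel intensities inside the rectangle exceeds
#' \code{threshold}, and released when it falls below
#' \code{hysteresis * threshold} (Schmitt trigger).
#'
#' The rectangle is stored as \code{c(row0, col0, row1, col1)}, 0-based,
#' half-open (rows \code{row0 <= r < row1}, columns \code{col0 <= c < col1}).
#'
#' @slot name region identifier (e.g. "ap1".."ap5" or "mag").
#' @slot rect integer(4), 0-based half-open pixel rectangle.
#' @slot threshold variance threshold T (> 0).
#' @slot hysteresis release fraction of T (default 0.8).
#' @slot state current detector state, "VACANT" or "OCCUPIED".
#' @exportClass RegionOfInterest
setClass("RegionOfInterest",
  representation(name = "character", rect = "integer",
                 threshold = "numeric", hysteresis = "numeric",
                 state = "character"),
  prototype(hysteresis = 0.8, state = "VACANT"))

setValidity("RegionOfInterest", function(object) {
  r <- object@rect
  if (length(object@name) != 1L || !nzchar(object@name))
    return("name must be a single non-empty string")
  if (length(r) != 4L || anyNA(r))
    return("rect must be integer(4): c(row0, col0, row1, col1)")
  if (any(r[1:2] < 0L) || r[3] <= r[1] || r[4] <= r[2])
    return("rect must be non-empty with row1 > row0, col1 > col0, origin >= 0")
  if ((r[3] - r[1]) * (r[4] - r[2]) < 2L)
    return("rect must contain at least 2 pixels")
  if (length(object@threshold) != 1L || is.na(object@threshold) ||
      object@threshold <= 0)
    return("threshold must be a single positive number")
  if (length(object@hysteresis) != 1L || object@hysteresis <= 0 ||
      object@hysteresis >= 1)
    return("hysteresis must lie strictly inside (0, 1)")
  if (!object@state %in% ROI_STATES)
    return("state must be VACANT or OCCUPIED")
  TRUE
})

#' SyntheticScene: parameters of the synthetic tank video generator
#'
#' Emulates the imaging conditions of the rig camera: a uniformly bright tank
#' background, global (spatially uniform) illumination fluctuations, ripple
#' pixel noise, and the fish rendered as a dark streak (~30 x 5 px by
#' default) moving along a scripted trajectory.
#'
#' @slot dims integer(2) frame size c(nrow, ncol); nominal camera is 360 x 640.
#' @slot backgroundLevel mean background intensity (0..255).
#' @slot illuminationDrift per-frame additive offset, recycled over frames.
#' @slot rippleSigma standard deviation of i.i.d. pixel noise.
#' @slot fishLengthPx,fishWidthPx streak size in pixels (columns x rows).
#' @slot fishIntensity intensity of the streak; must be darker than background.
#' @slot trajectory data.frame(frame, row, col): 0-based frame index and
#'   0-based streak-center coordinates; frames absent from the table have no
#'   fish in view.
#' @slot seed RNG seed fixing the whole frame sequence.
#' @exportClass SyntheticScene
setClass("SyntheticScene",
  representation(dims = "integer", backgroundLevel = "numeric",
                 illuminationDrift = "numeric", rippleSigma = "numeric",
                 fishLengthPx = "integer", fishWidthPx = "integer",
                 fishIntensity = "numeric", trajectory = "data.frame",
                 seed = "integer"))

setValidity("SyntheticScene", function(object) {
  if (length(object@dims) != 2L || any(object@dims < 4L))
    return("dims must be two integers >= 4")
  if (object@fishIntensity >= object@backgroundLevel)
    return("fish must be darker than the background")
  if (object@rippleSigma < 0) return("rippleSigma must be >= 0")
  if (object@fishLengthPx < 1L || object@fishWidthPx < 1L)
    return("fish streak dimensions must be >= 1 px")
  tr <- object@trajectory
  if (nrow(tr) && !all(c("frame", "row", "col") %in% names(tr)))
    return("trajectory needs columns frame, row, col")
  TRUE
})

#' SessionSchedule: protocol parameters for one training session
#'
#' Durations are in seconds. Defaults follow the validated protocol: 30-min
#' sessions, 5-s pre-stimulus interval (PSI), 30-s stimulus presentation,
#' 20-s timeout and inter-trial interval, 60-s initial hold behind the gate,
#' magazine light up to 10 s with 30-s gaps, food every 30 s in habituation.
#'
#' @slot phase one of HABITUATION, MAGAZINE, STIMULUS_LIGHT, FIVE_CSRTT.
#' @slot sessionLengthS total session length (default 1800).
#' @slot psiS pre-stimulus interval (5 or 10 in the validated protocol).
#' @slot stimulusDurationS stimulus light duration (default 30).
#' @slot timeoutS confinement after failed trials (default 20).
#' @slot itiS inter-trial interval after a rewarded trial (default 20).
#' @slot initialHoldS hold in the food area at session start (default 60).
#' @slot magazineLightMaxS maximum magazine-light illumination (default 10).
#' @slot magazineGapS dark gap between illuminations (default 30).
#' @slot habituationFoodIntervalS minimum spacing of habituation deliveries.
#' @slot feederSteps stepper-motor steps per food delivery.
#' @slot gateLatencyS time for the pneumatic gate to raise/lower (< 1 s on
#'   the physical rig; default 0.5).
#' @slot fps camera frame rate defining the time base (default 50).
#' @slot rngSeed seed for stimulus-position selection.
#' @exportClass SessionSchedule
setClass("SessionSchedule",
  representation(phase = "character", sessionLengthS = "numeric",
                 psiS = "numeric", stimulusDurationS = "numeric",
                 timeoutS = "numeric", itiS = "numeric",
                 initialHoldS = "numeric", magazineLightMaxS = "numeric",
                 magazineGapS = "numeric", habituationFoodIntervalS = "numeric",
                 feederSteps = "integer", gateLatencyS = "numeric",
                 fps = "numeric", rngSeed = "integer"))

setValidity("SessionSchedule", function(object) {
  if (!object@phase %in% SESSION_PHASES)
    return(paste("phase must be one of:", paste(SESSION_PHASES, collapse = ", ")))
  durs <- c(object@sessionLengthS, object@psiS, object@stimulusDurationS,
            object@timeoutS, object@itiS, object@initialHoldS,
            object@magazineLightMaxS, object@magazineGapS,
            object@habituationFoodIntervalS)
  if (any(!is.finite(durs)) || any(durs <= 0))
    return("all durations must be positive")
  if (object@gateLatencyS < 0) return("gateLatencyS must be >= 0")
  if (object@fps <= 0) return("fps must be positive")
  if (object@feederSteps < 1L) return("feederSteps must be >= 1")
  TRUE
})

#' AgentParams: stochastic behavioral parameters of the simulated fish
#'
#' The agent model: during the PSI, premature aperture entries arise from a
#' homogeneous Poisson hazard \code{prematureHazard} (per second), so a trial
#' is anticipatory with probability \code{1 - exp(-hazard * psi)}. Given no
#' premature entry, the fish responds within the stimulus window with
#' probability \code{pRespond}; response latency is log-normal truncated to
#' the window; the lit aperture is chosen with probability \code{pCorrect},
#' otherwise uniformly among the other four. After a correct response the
#' fish returns to the magazine after a log-normal delay.
#'
#' @slot prematureHazard premature-entry hazard per second (>= 0).
#' @slot pCorrect probability a response targets the lit aperture.
#' @slot pRespond probability of responding within the stimulus window.
#' @slot latencyMeanlog,latencySdlog log-normal response-latency parameters
#'   (seconds); \code{latencySdlog = 0} gives a deterministic latency.
#' @slot magReturnMeanlog,magReturnSdlog log-normal magazine-return delay.
#' @slot dwellS how long a visit keeps the region occupied (default 0.5 s).
#' @slot speedAccuracy if TRUE, pCorrect becomes an increasing logistic
#'   function of the sampled log-latency (speed-accuracy trade-off).
#' @slot saSlope,saMid logistic slope and midpoint (log seconds) of the
#'   trade-off; at latency exp(saMid) accuracy equals pCorrect.
#' @slot seed RNG seed for the agent's behavioral stream.
#' @exportClass AgentParams
setClass("AgentParams",
  representation(prematureHazard = "numeric", pCorrect = "numeric",
                 pRespond = "numeric", latencyMeanlog = "numeric",
                 latencySdlog = "numeric", magReturnMeanlog = "numeric",
                 magReturnSdlog = "numeric", dwellS = "numeric",
                 speedAccuracy = "logical", saSlope = "numeric",
                 saMid = "numeric", seed = "integer"))

setValidity("AgentParams", function(object) {
  if (object@prematureHazard < 0) return("prematureHazard must be >= 0")
  if (object@pCorrect < 0 || object@pCorrect > 1)
    return("pCorrect must lie in [0, 1]")
  if (object@pRespond < 0 || object@pRespond > 1)
    return("pRespond must lie in [0, 1]")
  if (object@latencySdlog < 0 || object@magReturnSdlog < 0)
    return("log-normal sd parameters must be >= 0")
  if (object@dwellS <= 0) return("dwellS must be positive")
  TRUE
})

#' EventLog: the complete record of one session
#'
#' Bundles session metadata (fish id, session id, phase, schedule), per-trial
#' records, the raw detection-event stream and the apparatus command stream.
#'
#' @slot meta named list: fishId, sessionId, phase, schedule (a
#'   \linkS4class{SessionSchedule}), plus free-form entries.
#' @slot trials data.frame, one row per completed trial (empty outside the
#'   5-CSRTT phase): trial, stimulusPos, outcome, respondedPos, latencyS and
#'   the timestamp columns tTrialStart, tPsiStart, tStimOnset, tStimOff,
#'   tResponse, tFeed.
#' @slot events data.frame of detection events (region, onset_frame,
#'   offset_frame, onset_time_s, offset_time_s).
#' @slot commands data.frame of apparatus commands (time_s, kind, arg).
#' @exportClass EventLog
setClass("EventLog",
  representation(meta = "list", trials = "data.frame",
                 events = "data.frame", commands = "data.frame"))

setValidity("EventLog", function(object) {
  need <- c("fishId", "sessionId", "phase")
  if (!all(need %in% names(object@meta)))
    return("meta must contain fishId, sessionId, phase")
  if (!object@meta$phase %in% SESSION_PHASES)
    return("meta$phase invalid")
  if (nrow(object@trials) &&
      !all(object@trials$outcome %in% TRIAL_OUTCOMES))
    return("trial outcomes must be CORRECT/INCORRECT/ANTICIPATORY/OMISSION")
  if (nrow(object@commands) && is.unsorted(object@commands$time_s))
    return("commands must be time-ordered")
  TRUE
})

setMethod("show", "RegionOfInterest", function(object) {
  cat(sprintf("RegionOfInterest '%s' rows [%d,%d) cols [%d,%d) T=%g (release %g) %s\n",
              object@name, object@rect[1], object@rect[3], object@rect[2],
              object@rect[4], object@threshold,
              object@hysteresis * object@threshold, object@state))
})

setMethod("show", "SessionSchedule", function(object) {
  cat(sprintf("SessionSchedule phase=%s length=%gs psi=%gs stim=%gs fps=%g seed=%d\n",
              object@phase, object@sessionLengthS, object@psiS,
              object@stimulusDurationS, object@fps, object@rngSeed))
})

setMethod("show", "AgentParams", function(object) {
  cat(sprintf("AgentParams hazard=%g/s pCorrect=%g pRespond=%g latency~LN(%g,%g) seed=%d\n",
              object@prematureHazard, object@pCorrect, object@pRespond,
              object@latencyMeanlog, object@latencySdlog, object@seed))
})

setMethod("show", "EventLog", function(object) {
  tr <- object@trials
  cat(sprintf("EventLog %s/%s phase=%s: %d trials, %d detection events, %d commands\n",
              object@meta$fishId, object@meta$sessionId, object@meta$phase,
              nrow(tr), nrow(object@events), nrow(object@commands)))
  if (nrow(tr)) {
    tab <- table(factor(tr$outcome, levels = TRIAL_OUTCOMES))
    cat("  outcomes:", paste(names(tab), as.integer(tab), sep = "=", collapse = " "), "\n")
  }
})
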