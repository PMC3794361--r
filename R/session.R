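# Session controllers: the finite-state machine a physical rig runs in its
# control software, re-implemented over an in-process event stream. Each
# controller consumes a SessionSchedule plus the detection events of one
# session and returns an EventLog with trial records and the apparatus
# command stream (gate, LEDs, feeder).
#
# Timing model: all times are quantized to the camera frame clock (1/fps s).
# The gate is modeled as instantaneous with a fixed travel latency; the PSI
# is counted from gate-up completion. An "entry" is the ONSET edge of a
# detection event - a fish already occupying a region when a window opens
# does not count until it re-enters (matching the Schmitt re-trigger rule).

validateEvents <- function(events) {
  need <- c("region", "onset_time_s")
  if (!all(need %in% names(events)))
    stop("event stream needs columns region and onset_time_s")
  bad <- which(!is.finite(events$onset_time_s))
  if (length(bad))
    stop("malformed event stream: invalid onset_time_s at row ", bad[1])
  if (nrow(events) && is.unsorted(events$onset_time_s))
    stop("malformed event log: detection events out of time order")
  events
}

#' Draw stimulus positions
#'
#' Uniform, independent draws over the five apertures with a seeded RNG
#' (the selection rule of the rig: any of the five lights, repeats allowed).
#' The caller's RNG state is left untouched.
#'
#' @param n number of draws.
#' @param seed integer seed; the same seed reproduces the same sequence.
#' @return integer vector of positions in 1..5.
#' @export
selectStimulus <- function(n, seed) {
  withSeed(as.integer(seed), sample.int(5L, n, replace = TRUE))
}

# Deterministic ordering for commands sharing a timestamp.
kindOrder <- function(kind) {
  match(kind, c("GATE_UP", "STIM_LED_ON", "STIM_LED_OFF", "MAG_LED_ON",
                "GATE_DOWN", "FEED", "MAG_LED_OFF"))
}

cmd <- function(time_s, kind, arg = NA_integer_) {
  data.frame(time_s = as.numeric(time_s), kind = kind,
             arg = as.integer(arg), stringsAsFactors = FALSE)
}

orderCommands <- function(cmds) {
  if (!nrow(cmds)) return(cmds)
  cmds <- cmds[order(cmds$time_s, kindOrder(cmds$kind), cmds$arg,
                     na.last = FALSE), , drop = FALSE]
  rownames(cmds) <- NULL
  cmds
}

trialRow <- function(trial, stimulusPos, outcome, respondedPos, latencyS,
                     tTrialStart, tPsiStart, tStimOnset, tStimOff,
                     tResponse, tFeed) {
  data.frame(trial = as.integer(trial), stimulusPos = as.integer(stimulusPos),
             outcome = outcome, respondedPos = as.integer(respondedPos),
             latencyS = as.numeric(latencyS),
             tTrialStart = as.numeric(tTrialStart),
             tPsiStart = as.numeric(tPsiStart),
             tStimOnset = as.numeric(tStimOnset),
             tStimOff = as.numeric(tStimOff),
             tResponse = as.numeric(tResponse), tFeed = as.numeric(tFeed),
             stringsAsFactors = FALSE)
}

# Classify one 5-CSRTT trial starting at tStart against the event stream.
# apT/apPos: aperture onset times and positions; magT: magazine onset times.
# Returns the trial row (without its index), the outcome-decision time and
# the next trial's start time (NA when the session cannot continue).
classifyTrial <- function(schedule, tStart, stimPos, apT, apPos, magT) {
  fps <- schedule@fps
  q <- function(t) quantizeTime(t, fps)
  L <- schedule@sessionLengthS
  psiStart <- q(tStart + schedule@gateLatencyS)
  stimOn <- q(psiStart + schedule@psiS)
  i <- which(apT >= psiStart & apT < stimOn)
  if (length(i)) {
    i <- i[1]
    # any aperture before light onset: anticipatory, no stimulus ever shown
    row <- trialRow(0L, NA, "ANTICIPATORY", apPos[i], NA, tStart, psiStart,
                    NA, NA, apT[i], NA)
    return(list(row = row, tOutcome = apT[i],
                tNext = q(apT[i] + schedule@timeoutS)))
  }
  stimEnd <- q(stimOn + schedule@stimulusDurationS)
  j <- which(apT >= stimOn & apT < stimEnd)
  if (!length(j)) {
    row <- trialRow(0L, stimPos, "OMISSION", NA, NA, tStart, psiStart,
                    stimOn, stimEnd, NA, NA)
    return(list(row = row, tOutcome = stimEnd,
                tNext = q(stimEnd + schedule@timeoutS)))
  }
  j <- j[1]
  tResp <- apT[j]
  if (apPos[j] == stimPos) {
    m <- magT[magT >= tResp]
    tFeed <- if (length(m) && m[1] <= L) m[1] else NA_real_
    row <- trialRow(0L, stimPos, "CORRECT", apPos[j], tResp - stimOn,
                    tStart, psiStart, stimOn, tResp, tResp, tFeed)
    list(row = row, tOutcome = tResp,
         tNext = if (is.na(tFeed)) NA_real_ else q(tFeed + schedule@itiS))
  } else {
    row <- trialRow(0L, stimPos, "INCORRECT", apPos[j], tResp - stimOn,
                    tStart, psiStart, stimOn, tResp, tResp, NA)
    list(row = row, tOutcome = tResp,
         tNext = q(tResp + schedule@timeoutS))
  }
}

# Apparatus commands implied by one trial record.
trialCommands <- function(schedule, row) {
  out <- cmd(row$tTrialStart, "GATE_UP")
  if (row$outcome == "ANTICIPATORY") {
    out <- rbind(out, cmd(row$tResponse, "GATE_DOWN"))
  } else {
    out <- rbind(out, cmd(row$tStimOnset, "STIM_LED_ON", row$stimulusPos),
                 cmd(row$tStimOff, "STIM_LED_OFF", row$stimulusPos))
    if (row$outcome == "CORRECT") {
      out <- rbind(out, cmd(row$tResponse, "MAG_LED_ON"))
      if (!is.na(row$tFeed))
        out <- rbind(out, cmd(row$tFeed, "GATE_DOWN"),
                     cmd(row$tFeed, "FEED", schedule@feederSteps),
                     cmd(row$tFeed, "MAG_LED_OFF"))
    } else if (row$outcome == "INCORRECT") {
      out <- rbind(out, cmd(row$tResponse, "GATE_DOWN"))
    } else {  # OMISSION
      out <- rbind(out, cmd(row$tStimOff, "GATE_DOWN"))
    }
  }
  orderCommands(out)
}

#' Run a 5-CSRTT session
#'
#' The full trial loop: initial hold, gate up, PSI wait, one of the five
#' stimulus lights on for the stimulus duration, classification of the first
#' aperture entry. Entry to the lit aperture is CORRECT (magazine light on,
#' gate closes as the fish passes, food on magazine entry, then the ITI);
#' entry to a wrong aperture during the stimulus is INCORRECT; entry to any
#' aperture before light onset is ANTICIPATORY; no entry within the stimulus
#' window is an OMISSION. Failed trials earn a timeout confinement with no
#' food. A trial still unresolved when the session clock expires is
#' discarded.
#'
#' @param schedule a \linkS4class{SessionSchedule} with phase "FIVE_CSRTT".
#' @param events detection-event data.frame (time-ordered), e.g. from
#'   \code{\link{processStream}} or \code{\link{simulateSession}}.
#' @param fishId,sessionId identifiers recorded in the log metadata.
#' @return an \linkS4class{EventLog} with one trial record per completed
#'   trial and the full apparatus command stream.
#' @export
run5CSRTT <- function(schedule, events, fishId = "fish1", sessionId = "s1") {
  stopifnot(is(schedule, "SessionSchedule"))
  if (schedule@phase != "FIVE_CSRTT")
    stop("schedule phase must be FIVE_CSRTT")
  ev <- validateEvents(events)
  pos <- aperturePosition(ev$region)
  apT <- ev$onset_time_s[!is.na(pos)]
  apPos <- pos[!is.na(pos)]
  magT <- ev$onset_time_s[ev$region == magazineName()]
  stimSeq <- selectStimulus(10000L, schedule@rngSeed)
  q <- function(t) quantizeTime(t, schedule@fps)
  L <- schedule@sessionLengthS
  trials <- vector("list", 0L)
  cmds <- vector("list", 0L)
  tStart <- q(schedule@initialHoldS)
  k <- 0L
  while (!is.na(tStart) && tStart < L) {
    k <- k + 1L
    res <- classifyTrial(schedule, tStart, stimSeq[k], apT, apPos, magT)
    if (res$tOutcome > L) break  # trial in progress at session expiry
    res$row$trial <- length(trials) + 1L
    trials[[length(trials) + 1L]] <- res$row
    cmds[[length(cmds) + 1L]] <- trialCommands(schedule, res$row)
    tStart <- res$tNext
  }
  trialDf <- if (length(trials)) do.call(rbind, trials) else trialSchema()
  rownames(trialDf) <- NULL
  cmdDf <- if (length(cmds)) orderCommands(do.call(rbind, cmds)) else commandSchema()
  EventLog(list(fishId = fishId, sessionId = sessionId, phase = "FIVE_CSRTT",
                schedule = schedule),
           trials = trialDf, events = ev, commands = cmdDf)
}

#' Run a habituation session
#'
#' Week-1 conditions: lights on throughout, no trials; food is delivered on
#' the first magazine entry at least \code{habituationFoodIntervalS} seconds
#' after the previous delivery (the very first entry is always rewarded).
#'
#' @inheritParams run5CSRTT
#' @return an \linkS4class{EventLog} with FEED commands and no trial
#'   records; \code{logMeta(log)$nDeliveries} counts deliveries.
#' @export
runHabituation <- function(schedule, events, fishId = "fish1",
                           sessionId = "s1") {
  stopifnot(is(schedule, "SessionSchedule"))
  if (schedule@phase != "HABITUATION")
    stop("schedule phase must be HABITUATION")
  ev <- validateEvents(events)
  magT <- ev$onset_time_s[ev$region == magazineName() &
                          ev$onset_time_s <= schedule@sessionLengthS]
  feeds <- numeric(0)
  last <- -Inf
  for (t in magT) {
    if (t >= last + schedule@habituationFoodIntervalS) {
      feeds <- c(feeds, t)
      last <- t
    }
  }
  cmds <- if (length(feeds)) {
    orderCommands(cmd(feeds, "FEED", schedule@feederSteps))
  } else commandSchema()
  EventLog(list(fishId = fishId, sessionId = sessionId, phase = "HABITUATION",
                schedule = schedule, nDeliveries = length(feeds)),
           events = ev, commands = cmds)
}

#' Run a magazine-training session
#'
#' Week-2 conditions: gate closed, fish confined to the food end. Cycles of
#' magazine-light illumination (up to \code{magazineLightMaxS}) separated by
#' \code{magazineGapS} dark gaps; the session opens with a gap. A magazine
#' entry during an illumination delivers food and ends the illumination; an
#' entry during a gap has no effect; with no entry the light times out after
#' its maximum duration.
#'
#' @inheritParams run5CSRTT
#' @return an \linkS4class{EventLog}; \code{logMeta(log)$nDeliveries} counts
#'   rewarded entries.
#' @export
runMagazineTraining <- function(schedule, events, fishId = "fish1",
                                sessionId = "s1") {
  stopifnot(is(schedule, "SessionSchedule"))
  if (schedule@phase != "MAGAZINE")
    stop("schedule phase must be MAGAZINE")
  ev <- validateEvents(events)
  q <- function(t) quantizeTime(t, schedule@fps)
  magT <- ev$onset_time_s[ev$region == magazineName()]
  L <- schedule@sessionLengthS
  cmds <- commandSchema()
  nDel <- 0L
  t <- 0
  repeat {
    lightOn <- q(t + schedule@magazineGapS)
    if (lightOn >= L) break
    lightMaxOff <- q(lightOn + schedule@magazineLightMaxS)
    cmds <- rbind(cmds, cmd(lightOn, "MAG_LED_ON"))
    entry <- magT[magT >= lightOn & magT < lightMaxOff]
    if (length(entry) && entry[1] <= L) {
      e <- entry[1]
      cmds <- rbind(cmds, cmd(e, "FEED", schedule@feederSteps),
                    cmd(e, "MAG_LED_OFF"))
      nDel <- nDel + 1L
      t <- e
    } else {
      cmds <- rbind(cmds, cmd(lightMaxOff, "MAG_LED_OFF"))
      t <- lightMaxOff
    }
  }
  EventLog(list(fishId = fishId, sessionId = sessionId, phase = "MAGAZINE",
                schedule = schedule, nDeliveries = nDel),
           events = ev, commands = orderCommands(cmds))
}

#' Run a stimulus-light-training session
#'
#' Week-3 conditions: after the initial hold the gate rises and all five
#' stimulus lights come on. Entry into any aperture extinguishes the
#' stimulus lights and lights the magazine; re-entry to the magazine lowers
#' the gate and delivers food. After the inter-trial pause the next cycle
#' begins.
#'
#' @inheritParams run5CSRTT
#' @return an \linkS4class{EventLog}; \code{logMeta(log)$nReinforcers}
#'   counts completed cycles.
#' @export
runStimulusLightTraining <- function(schedule, events, fishId = "fish1",
                                     sessionId = "s1") {
  stopifnot(is(schedule, "SessionSchedule"))
  if (schedule@phase != "STIMULUS_LIGHT")
    stop("schedule phase must be STIMULUS_LIGHT")
  ev <- validateEvents(events)
  q <- function(t) quantizeTime(t, schedule@fps)
  pos <- aperturePosition(ev$region)
  apT <- ev$onset_time_s[!is.na(pos)]
  magT <- ev$onset_time_s[ev$region == magazineName()]
  L <- schedule@sessionLengthS
  cmds <- commandSchema()
  nRe <- 0L
  tStart <- q(schedule@initialHoldS)
  while (tStart < L) {
    avail <- q(tStart + schedule@gateLatencyS)
    cmds <- rbind(cmds, cmd(tStart, "GATE_UP"),
                  cmd(avail, "STIM_LED_ON", 1:5))
    ap <- apT[apT >= avail]
    if (!length(ap) || ap[1] > L) break
    a <- ap[1]
    cmds <- rbind(cmds, cmd(a, "STIM_LED_OFF", 1:5), cmd(a, "MAG_LED_ON"))
    m <- magT[magT >= a]
    if (!length(m) || m[1] > L) break
    f <- m[1]
    cmds <- rbind(cmds, cmd(f, "GATE_DOWN"), cmd(f, "FEED", schedule@feederSteps),
                  cmd(f, "MAG_LED_OFF"))
    nRe <- nRe + 1L
    tStart <- q(f + schedule@itiS)
  }
  EventLog(list(fishId = fishId, sessionId = sessionId,
                phase = "STIMULUS_LIGHT", schedule = schedule,
                nReinforcers = nRe),
           events = ev, commands = orderCommands(cmds))
}

#' Reconstruct the apparatus command stream from a session log
#'
#' For a 5-CSRTT log the commands are rebuilt deterministically from the
#' trial records (gate, stimulus LEDs, magazine LED, one FEED per rewarded
#' trial); the log is validated first, and inconsistent records (e.g. a
#' CORRECT trial without a responded position, or a latency outside the
#' stimulus window) raise an error. For the pre-training phases the stored
#' command stream is returned after an ordering check.
#'
#' @param log an \linkS4class{EventLog}.
#' @return time-ordered command data.frame (time_s, kind, arg).
#' @export
driveApparatus <- function(log) {
  stopifnot(is(log, "EventLog"))
  schedule <- log@meta$schedule
  if (is.null(schedule)) stop("log metadata carries no schedule")
  if (log@meta$phase != "FIVE_CSRTT") {
    if (nrow(log@commands) && is.unsorted(log@commands$time_s))
      stop("inconsistent log: commands out of time order")
    return(log@commands)
  }
  tr <- log@trials
  for (i in seq_len(nrow(tr))) {
    row <- tr[i, ]
    ok <- switch(row$outcome,
      CORRECT = ,
      INCORRECT = !is.na(row$respondedPos) && !is.na(row$latencyS) &&
        row$latencyS >= 0 && row$latencyS <= schedule@stimulusDurationS,
      ANTICIPATORY = !is.na(row$tResponse) && is.na(row$latencyS),
      OMISSION = is.na(row$tResponse) && is.na(row$latencyS),
      FALSE)
    if (!isTRUE(ok))
      stop(sprintf("inconsistent log: trial %d violates its outcome contract",
                   row$trial))
  }
  cmds <- lapply(seq_len(nrow(tr)),
                 function(i) trialCommands(schedule, tr[i, ]))
  if (!length(cmds)) return(commandSchema())
  orderCommands(do.call(rbind, cmds))
}
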