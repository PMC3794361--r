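# Stochastic fish agent. The rig's validation data motivate the behavioral
# constructs (anticipatory responses, omissions, correct-response latency);
# the parametric forms here are modeling conventions of this package, chosen
# as the simplest mechanisms producing those constructs:
#   - premature aperture entries: homogeneous Poisson hazard during the PSI,
#     so P(anticipatory) = 1 - exp(-hazard * psi) and longer PSIs raise the
#     anticipatory rate;
#   - response latency: log-normal (positive, right-skewed), truncated to
#     the stimulus window so that pRespond alone governs omissions;
#   - choice: lit aperture with probability pCorrect, else uniform over the
#     other four; optionally pCorrect increases logistically with latency
#     (speed-accuracy trade-off).

#' Construct AgentParams
#'
#' @param prematureHazard premature-entry hazard (per second) during the
#'   PSI; default 0.05.
#' @param pCorrect probability a stimulus-window response targets the lit
#'   aperture; default 0.6 (typical adult-zebrafish choice accuracy).
#' @param pRespond probability of responding within the stimulus window;
#'   default 0.9 (omission rates are low on this task).
#' @param latencyMeanlog,latencySdlog log-normal response latency; defaults
#'   give a 4-s median, right-skewed. \code{latencySdlog = 0} makes the
#'   latency deterministic at \code{exp(latencyMeanlog)}.
#' @param magReturnMeanlog,magReturnSdlog log-normal magazine-return delay
#'   after a correct response; defaults give a 3-s median.
#' @param dwellS occupancy duration of a region visit (s).
#' @param speedAccuracy enable the latency-coupled accuracy trade-off.
#' @param saSlope,saMid trade-off slope and midpoint on the log-latency
#'   scale.
#' @param seed RNG seed for the agent's behavioral stream.
#' @return an \linkS4class{AgentParams}.
#' @export
AgentParams <- function(prematureHazard = 0.05, pCorrect = 0.6,
                        pRespond = 0.9, latencyMeanlog = log(4),
                        latencySdlog = 0.5, magReturnMeanlog = log(3),
                        magReturnSdlog = 0.4, dwellS = 0.5,
                        speedAccuracy = FALSE, saSlope = 1.5,
                        saMid = log(4), seed = 1L) {
  new("AgentParams", prematureHazard = prematureHazard, pCorrect = pCorrect,
      pRespond = pRespond, latencyMeanlog = latencyMeanlog,
      latencySdlog = latencySdlog, magReturnMeanlog = magReturnMeanlog,
      magReturnSdlog = magReturnSdlog, dwellS = dwellS,
      speedAccuracy = speedAccuracy, saSlope = saSlope, saMid = saMid,
      seed = as.integer(seed))
}

rlnormOr <- function(meanlog, sdlog) {
  if (sdlog == 0) exp(meanlog) else stats::rlnorm(1, meanlog, sdlog)
}

# Response latency truncated to the stimulus window (rejection sampling).
sampleLatency <- function(agent, maxS) {
  if (agent@latencySdlog == 0) {
    l <- exp(agent@latencyMeanlog)
    if (l >= maxS)
      stop("deterministic latency exceeds the stimulus window")
    return(l)
  }
  repeat {
    l <- stats::rlnorm(1, agent@latencyMeanlog, agent@latencySdlog)
    if (l < maxS) return(l)
  }
}

effectivePCorrect <- function(agent, latency) {
  if (!agent@speedAccuracy) return(agent@pCorrect)
  base <- stats::qlogis(min(max(agent@pCorrect, 1e-6), 1 - 1e-6))
  stats::plogis(base + agent@saSlope * (log(latency) - agent@saMid))
}

agentEventRow <- function(region, tOn, dwellS, fps) {
  f0 <- as.integer(round(tOn * fps))
  f1 <- as.integer(round((tOn + dwellS) * fps))
  data.frame(region = region, onset_frame = f0, offset_frame = f1,
             onset_time_s = f0 / fps, offset_time_s = f1 / fps,
             stringsAsFactors = FALSE)
}

#' Simulate one 5-CSRTT trial
#'
#' Draws one trial of agent behavior starting at \code{tStart}, using the
#' current RNG stream (callers seed it; \code{\link{simulateSession}} does
#' this for you). The expected outcome is computed with the same windowing
#' rules as the session controller, so feeding the emitted events back
#' through \code{\link{run5CSRTT}} reproduces it exactly.
#'
#' @param agent an \linkS4class{AgentParams}.
#' @param schedule a FIVE_CSRTT \linkS4class{SessionSchedule}.
#' @param stimPos the lit aperture for this trial (1..5).
#' @param tStart trial start time (gate-up command), seconds.
#' @return list with \code{events} (detection-event rows), \code{row} (the
#'   expected trial record), \code{tOutcome} (outcome-decision time) and
#'   \code{tNext} (next trial start, NA when the session cannot continue).
#' @export
simulateTrial <- function(agent, schedule, stimPos, tStart) {
  fps <- schedule@fps
  q <- function(t) quantizeTime(t, fps)
  L <- schedule@sessionLengthS
  psiStart <- q(tStart + schedule@gateLatencyS)
  stimOn <- q(psiStart + schedule@psiS)
  w <- if (agent@prematureHazard > 0) {
    stats::rexp(1, agent@prematureHazard)
  } else Inf
  if (w < schedule@psiS) {
    pos <- sample.int(5L, 1L)
    tResp <- round(min(q(psiStart + w), stimOn - 1 / fps) * fps) / fps
    row <- trialRow(0L, NA, "ANTICIPATORY", pos, NA, tStart, psiStart,
                    NA, NA, tResp, NA)
    return(list(events = agentEventRow(apertureNames()[pos], tResp,
                                       agent@dwellS, fps),
                row = row, tOutcome = tResp,
                tNext = q(tResp + schedule@timeoutS)))
  }
  stimEnd <- q(stimOn + schedule@stimulusDurationS)
  if (stats::runif(1) >= agent@pRespond) {
    row <- trialRow(0L, stimPos, "OMISSION", NA, NA, tStart, psiStart,
                    stimOn, stimEnd, NA, NA)
    return(list(events = emptyEvents(), row = row, tOutcome = stimEnd,
                tNext = q(stimEnd + schedule@timeoutS)))
  }
  lat <- sampleLatency(agent, schedule@stimulusDurationS)
  # snap to the frame grid so the recorded time is bit-identical to the
  # event timestamp the controller will see
  tResp <- round(min(q(stimOn + lat), stimEnd - 1 / fps) * fps) / fps
  pEff <- effectivePCorrect(agent, lat)
  chosen <- if (stats::runif(1) < pEff) stimPos else
    sample((1:5)[-stimPos], 1L)
  evs <- agentEventRow(apertureNames()[chosen], tResp, agent@dwellS, fps)
  if (chosen == stimPos) {
    tMag <- q(tResp + agent@dwellS +
                rlnormOr(agent@magReturnMeanlog, agent@magReturnSdlog))
    evs <- rbind(evs, agentEventRow(magazineName(), tMag, agent@dwellS, fps))
    tFeed <- if (tMag <= L) tMag else NA_real_
    row <- trialRow(0L, stimPos, "CORRECT", chosen, tResp - stimOn,
                    tStart, psiStart, stimOn, tResp, tResp, tFeed)
    list(events = evs, row = row, tOutcome = tResp,
         tNext = if (is.na(tFeed)) NA_real_ else q(tFeed + schedule@itiS))
  } else {
    row <- trialRow(0L, stimPos, "INCORRECT", chosen, tResp - stimOn,
                    tStart, psiStart, stimOn, tResp, tResp, NA)
    list(events = evs, row = row, tOutcome = tResp,
         tNext = q(tResp + schedule@timeoutS))
  }
}

#' Simulate a full session of agent behavior
#'
#' Chains trials through the session clock for the FIVE_CSRTT phase, or
#' generates phase-appropriate magazine/aperture visits for the pre-training
#' phases, and returns the agent's own expected \linkS4class{EventLog}. For
#' FIVE_CSRTT the log's event stream, fed to \code{\link{run5CSRTT}} with
#' the same schedule, reproduces the expected trial records exactly (the
#' closed-loop identity used throughout the test-suite).
#'
#' @param agent an \linkS4class{AgentParams}.
#' @param schedule a \linkS4class{SessionSchedule} (any phase).
#' @param fishId,sessionId identifiers for the log metadata.
#' @return an \linkS4class{EventLog}.
#' @export
simulateSession <- function(agent, schedule, fishId = "fish1",
                            sessionId = "s1") {
  stopifnot(is(agent, "AgentParams"), is(schedule, "SessionSchedule"))
  switch(schedule@phase,
         FIVE_CSRTT = simulate5CSRTT(agent, schedule, fishId, sessionId),
         HABITUATION = ,
         MAGAZINE = ,
         STIMULUS_LIGHT = simulatePretraining(agent, schedule, fishId,
                                              sessionId))
}

simulate5CSRTT <- function(agent, schedule, fishId, sessionId) {
  stimSeq <- selectStimulus(10000L, schedule@rngSeed)
  q <- function(t) quantizeTime(t, schedule@fps)
  L <- schedule@sessionLengthS
  withSeed(agent@seed, {
    trials <- list(); evs <- list(); cmds <- list()
    tStart <- q(schedule@initialHoldS)
    k <- 0L
    while (!is.na(tStart) && tStart < L) {
      k <- k + 1L
      res <- simulateTrial(agent, schedule, stimSeq[k], tStart)
      if (res$tOutcome > L) break
      res$row$trial <- length(trials) + 1L
      trials[[length(trials) + 1L]] <- res$row
      if (nrow(res$events)) evs[[length(evs) + 1L]] <- res$events
      cmds[[length(cmds) + 1L]] <- trialCommands(schedule, res$row)
      tStart <- res$tNext
    }
    trialDf <- if (length(trials)) do.call(rbind, trials) else trialSchema()
    rownames(trialDf) <- NULL
    evDf <- if (length(evs)) do.call(rbind, evs) else emptyEvents()
    evDf <- evDf[order(evDf$onset_time_s), , drop = FALSE]
    rownames(evDf) <- NULL
    cmdDf <- if (length(cmds)) orderCommands(do.call(rbind, cmds)) else
      commandSchema()
    EventLog(list(fishId = fishId, sessionId = sessionId,
                  phase = "FIVE_CSRTT", schedule = schedule,
                  agentSeed = agent@seed),
             trials = trialDf, events = evDf, commands = cmdDf)
  })
}

# Pre-training phases: emit plausible visit streams and run the matching
# controller on them, so the returned log carries the controller's command
# stream and delivery counts.
simulatePretraining <- function(agent, schedule, fishId, sessionId) {
  q <- function(t) quantizeTime(t, schedule@fps)
  L <- schedule@sessionLengthS
  fps <- schedule@fps
  evs <- withSeed(agent@seed, {
    rows <- list()
    if (schedule@phase == "HABITUATION") {
      # magazine visits as a renewal process; mean gap = 4x median return
      t <- 0
      meanGap <- 4 * exp(agent@magReturnMeanlog)
      repeat {
        t <- t + stats::rexp(1, 1 / meanGap)
        if (t > L) break
        rows[[length(rows) + 1L]] <-
          agentEventRow(magazineName(), q(t), agent@dwellS, fps)
      }
    } else if (schedule@phase == "MAGAZINE") {
      t <- 0
      repeat {
        lightOn <- q(t + schedule@magazineGapS)
        if (lightOn >= L) break
        if (stats::runif(1) < agent@pRespond) {
          repeat {
            lat <- rlnormOr(agent@magReturnMeanlog, agent@magReturnSdlog)
            if (lat < schedule@magazineLightMaxS) break
          }
          e <- q(lightOn + lat)
          rows[[length(rows) + 1L]] <-
            agentEventRow(magazineName(), e, agent@dwellS, fps)
          t <- e
        } else t <- q(lightOn + schedule@magazineLightMaxS)
      }
    } else {  # STIMULUS_LIGHT
      tStart <- q(schedule@initialHoldS)
      repeat {
        avail <- q(tStart + schedule@gateLatencyS)
        a <- q(avail + rlnormOr(agent@latencyMeanlog, agent@latencySdlog))
        if (a > L) break
        pos <- sample.int(5L, 1L)
        rows[[length(rows) + 1L]] <-
          agentEventRow(apertureNames()[pos], a, agent@dwellS, fps)
        m <- q(a + agent@dwellS +
                 rlnormOr(agent@magReturnMeanlog, agent@magReturnSdlog))
        if (m > L) break
        rows[[length(rows) + 1L]] <-
          agentEventRow(magazineName(), m, agent@dwellS, fps)
        tStart <- q(m + schedule@itiS)
      }
    }
    if (length(rows)) do.call(rbind, rows) else emptyEvents()
  })
  evs <- evs[order(evs$onset_time_s), , drop = FALSE]
  rownames(evs) <- NULL
  runner <- switch(schedule@phase, HABITUATION = runHabituation,
                   MAGAZINE = runMagazineTraining,
                   STIMULUS_LIGHT = runStimulusLightTraining)
  log <- runner(schedule, evs, fishId = fishId, sessionId = sessionId)
  log@meta$agentSeed <- agent@seed
  log
}

#' Fast trial-outcome simulation (no session clock)
#'
#' Vectorized draw of independent trial outcomes under the agent model:
#' anticipatory with probability \code{1 - exp(-hazard * psi)}, otherwise
#' omission with probability \code{1 - pRespond}, otherwise a response at a
#' truncated log-normal latency hitting the lit aperture with probability
#' \code{pCorrect}. Used for parameter-recovery and rate studies where the
#' session timeline is irrelevant.
#'
#' @param agent an \linkS4class{AgentParams}.
#' @param schedule a \linkS4class{SessionSchedule} supplying psi and
#'   stimulus duration.
#' @param nTrials number of trials to draw.
#' @param seed optional seed; defaults to the agent's.
#' @return data.frame(outcome, latencyS) with \code{NA} latency for
#'   anticipatory and omitted trials.
#' @export
simulateTrialOutcomes <- function(agent, schedule, nTrials,
                                  seed = agent@seed) {
  withSeed(as.integer(seed), {
    n <- as.integer(nTrials)
    pAnt <- 1 - exp(-agent@prematureHazard * schedule@psiS)
    ant <- stats::runif(n) < pAnt
    omit <- !ant & (stats::runif(n) >= agent@pRespond)
    resp <- !ant & !omit
    lat <- rep(NA_real_, n)
    nr <- sum(resp)
    if (nr) {
      draws <- numeric(nr)
      for (i in seq_len(nr)) draws[i] <-
          sampleLatency(agent, schedule@stimulusDurationS)
      lat[resp] <- draws
    }
    correct <- rep(FALSE, n)
    if (nr) {
      pEff <- vapply(lat[resp], function(l) effectivePCorrect(agent, l), 0)
      correct[resp] <- stats::runif(nr) < pEff
    }
    outcome <- rep("OMISSION", n)
    outcome[ant] <- "ANTICIPATORY"
    outcome[resp & correct] <- "CORRECT"
    outcome[resp & !correct] <- "INCORRECT"
    data.frame(outcome = outcome, latencyS = lat, stringsAsFactors = FALSE)
  })
}

#' Maximum-likelihood recovery of the premature-entry hazard
#'
#' Under the agent model a trial at pre-stimulus interval \eqn{t} is
#' anticipatory with probability \eqn{1 - e^{-\lambda t}}. Given anticipatory
#' counts at one or more PSIs this computes the maximum-likelihood estimate
#' of \eqn{\lambda}, the operational impulsivity parameter. With data at two
#' PSIs (e.g. 5 s and 10 s) the estimate is identified by the rise in
#' anticipatory responding at the longer interval.
#'
#' @param data either a data.frame with columns \code{psi}, \code{nTrials},
#'   \code{nAnticipatory}, or a list of FIVE_CSRTT \linkS4class{EventLog}s
#'   (aggregated by their schedules' psi).
#' @return the estimate \eqn{\hat\lambda} (per second). Zero anticipatory
#'   responses everywhere give the boundary estimate 0 with a warning.
#' @export
recoverHazard <- function(data) {
  if (is.list(data) && !is.data.frame(data)) {
    agg <- lapply(data, function(log) {
      stopifnot(is(log, "EventLog"))
      data.frame(psi = log@meta$schedule@psiS,
                 nTrials = nrow(log@trials),
                 nAnticipatory = sum(log@trials$outcome == "ANTICIPATORY"))
    })
    data <- do.call(rbind, agg)
    data <- stats::aggregate(cbind(nTrials, nAnticipatory) ~ psi, data, sum)
  }
  stopifnot(all(c("psi", "nTrials", "nAnticipatory") %in% names(data)))
  t <- data$psi; n <- data$nTrials; a <- data$nAnticipatory
  if (any(a > n) || any(t <= 0)) stop("invalid anticipatory counts")
  if (sum(a) == 0) {
    warning("no anticipatory responses at any PSI: boundary estimate 0")
    return(0)
  }
  ll <- function(lam) sum(a * log(1 - exp(-lam * t)) - lam * t * (n - a))
  pHat <- pmin(a / pmax(n, 1), 0.999)
  upper <- 10 * max(-log(1 - pHat) / t, 1e-3)
  stats::optimize(ll, c(1e-10, upper), maximum = TRUE)$maximum
}

#' Draw a simulated cohort of fish
#'
#' Per-fish impulsivity hazards are drawn from a gamma distribution (giving
#' the right-skewed anticipatory-rate histograms typical of mutagenized
#' cohorts); choice accuracy and response propensity from beta
#' distributions. Each fish receives a child seed derived stably from the
#' cohort seed and its id, so enlarging the cohort never perturbs existing
#' fish.
#'
#' @param nFish cohort size.
#' @param seed cohort seed.
#' @param hazardShape,hazardMean gamma shape and mean of the premature
#'   hazard (defaults 2 and 0.05/s).
#' @param pCorrectShape1,pCorrectShape2 beta parameters for pCorrect
#'   (defaults 6, 4: mean 0.6).
#' @param pRespondShape1,pRespondShape2 beta parameters for pRespond
#'   (defaults 9, 1: mean 0.9).
#' @return named list of \linkS4class{AgentParams}, names "fish001", ...
#' @export
simulateCohort <- function(nFish, seed = 1L, hazardShape = 2,
                           hazardMean = 0.05, pCorrectShape1 = 6,
                           pCorrectShape2 = 4, pRespondShape1 = 9,
                           pRespondShape2 = 1) {
  ids <- sprintf("fish%03d", seq_len(nFish))
  # one derived RNG stream per fish: enlarging the cohort leaves every
  # existing fish's parameters and seed untouched
  out <- lapply(ids, function(id) {
    withSeed(deriveSeed(seed, id, "params"), {
      AgentParams(
        prematureHazard = stats::rgamma(1, shape = hazardShape,
                                        scale = hazardMean / hazardShape),
        pCorrect = stats::rbeta(1, pCorrectShape1, pCorrectShape2),
        pRespond = stats::rbeta(1, pRespondShape1, pRespondShape2),
        seed = deriveSeed(seed, id))
    })
  })
  names(out) <- ids
  out
}

#' Standard rig geometry for trajectory synthesis
#'
#' @param dims frame size c(nrow, ncol).
#' @param threshold variance threshold for the generated ROIs.
#' @return list with \code{rois} (named ROI list from
#'   \code{\link{standardRigRois}}) and \code{home}, an idle fish position
#'   outside every ROI.
#' @export
standardRigGeometry <- function(dims = c(100L, 300L), threshold = 100) {
  rois <- standardRigRois(dims, threshold)
  apBottom <- max(vapply(rois[apertureNames()], function(r) r@rect[3], 0L))
  magTop <- rois[[magazineName()]]@rect[1]
  list(rois = rois, home = c((apBottom + magTop) / 2, dims[2] / 2))
}

#' Convert a session's detection events to a scripted fish trajectory
#'
#' Produces a per-frame trajectory that is inside region R's ROI exactly
#' during R's detection events (at the ROI center) and at the idle
#' \code{home} position otherwise, suitable for rendering with
#' \code{\link{makeSyntheticVideo}} and re-detecting with
#' \code{\link{processStream}} (the end-to-end vision round trip).
#' Overlapping events in different regions are physically infeasible for a
#' single fish and raise an error.
#'
#' @param log an \linkS4class{EventLog} or a detection-event data.frame.
#' @param geometry list with \code{rois} (named ROI list) and \code{home}
#'   (c(row, col)); see \code{\link{standardRigGeometry}}.
#' @param padFrames vacant frames appended after the last offset so the
#'   final event closes; default 10.
#' @return data.frame(frame, row, col) covering every frame from 0 to the
#'   end of the session.
#' @export
eventsToTrajectory <- function(log, geometry, padFrames = 10L) {
  ev <- if (is(log, "EventLog")) log@events else log
  if (!nrow(ev)) {
    return(data.frame(frame = 0:max(1L, padFrames),
                      row = geometry$home[1], col = geometry$home[2]))
  }
  unknown <- setdiff(unique(ev$region), names(geometry$rois))
  if (length(unknown))
    stop("geometry has no ROI for region(s): ",
         paste(unknown, collapse = ", "))
  off <- ev$offset_frame
  off[is.na(off)] <- max(ev$onset_frame, stats::na.omit(off), 0L) + 25L
  o <- order(ev$onset_frame)
  on <- ev$onset_frame[o]; offo <- off[o]
  if (any(utils::head(offo, -1) > utils::tail(on, -1)))
    stop("infeasible path: overlapping events in disjoint regions")
  nFrames <- max(offo) + padFrames + 1L
  row <- rep(geometry$home[1], nFrames)
  col <- rep(geometry$home[2], nFrames)
  for (i in seq_len(nrow(ev))) {
    r <- geometry$rois[[ev$region[i]]]@rect
    idx <- (ev$onset_frame[i] + 1L):off[i]  # occupied frames, 1-based
    row[idx] <- (r[1] + r[3]) / 2
    col[idx] <- (r[2] + r[4]) / 2
  }
  data.frame(frame = seq_len(nFrames) - 1L, row = row, col = col)
}
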