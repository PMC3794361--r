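# Behavioral analysis layer: session-level performance parameters,
# attrition screening, learning slopes, and long-format exports ready for
# external mixed-model analysis.

#' Summarize one 5-CSRTT session
#'
#' Computes the standard performance parameters from the trial records:
#' \deqn{accuracy = correct / (correct + incorrect)}
#' \deqn{anticipatory = early / (correct + incorrect + early)}
#' \deqn{omissions = omissions / (correct + incorrect + early + omissions)}
#' plus the mean correct-response latency (latencies run from stimulus
#' onset; CORRECT trials only). Proportions with a zero denominator are
#' reported as \code{NA}, never 0, to avoid silently biasing cohort means.
#'
#' @param log an \linkS4class{EventLog} (FIVE_CSRTT) or a trial-record
#'   data.frame with columns \code{outcome} and \code{latencyS}.
#' @return one-row data.frame: nCorrect, nIncorrect, nAnticipatory,
#'   nOmission, nTrials, accuracy, anticipatoryProp, omissionProp,
#'   meanCorrectLatencyS.
#' @export
summarizeSession <- function(log) {
  tr <- if (is(log, "EventLog")) log@trials else log
  nC <- sum(tr$outcome == "CORRECT")
  nI <- sum(tr$outcome == "INCORRECT")
  nA <- sum(tr$outcome == "ANTICIPATORY")
  nO <- sum(tr$outcome == "OMISSION")
  prop <- function(num, den) if (den > 0) num / den else NA_real_
  lat <- tr$latencyS[tr$outcome == "CORRECT"]
  data.frame(nCorrect = nC, nIncorrect = nI, nAnticipatory = nA,
             nOmission = nO, nTrials = nC + nI + nA + nO,
             accuracy = prop(nC, nC + nI),
             anticipatoryProp = prop(nA, nC + nI + nA),
             omissionProp = prop(nO, nC + nI + nA + nO),
             meanCorrectLatencyS = if (nC > 0) mean(lat) else NA_real_)
}

#' Per-session metrics table for a set of logs
#'
#' @param logs list of FIVE_CSRTT \linkS4class{EventLog}s.
#' @return data.frame with fishId, sessionId and the
#'   \code{\link{summarizeSession}} columns, one row per log.
#' @export
sessionMetricsTable <- function(logs) {
  rows <- lapply(logs, function(log) {
    cbind(data.frame(fishId = log@meta$fishId,
                     sessionId = log@meta$sessionId,
                     stringsAsFactors = FALSE),
          summarizeSession(log))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Attrition screen of a training cohort
#'
#' Fish are excluded if they died or if their mean number of trials per
#' session during training is not strictly greater than
#' \code{minMeanTrials} (default 10, the performance criterion of the
#' validated protocol; a mean of exactly 10 is rejected).
#'
#' @param summaries data.frame with columns \code{fishId} and
#'   \code{meanTrialsPerSession}, one row per fish.
#' @param deaths character vector of fish ids that died during training.
#' @param minMeanTrials the performance criterion (strict inequality).
#' @return list with \code{retained} (character vector of ids),
#'   \code{rejected} (data.frame fishId, reason in "dead"/"below_criterion")
#'   and the counts \code{nRetained}, \code{nRejected}.
#' @export
attritionScreen <- function(summaries, deaths = character(0),
                            minMeanTrials = 10) {
  stopifnot(all(c("fishId", "meanTrialsPerSession") %in% names(summaries)))
  if (anyDuplicated(summaries$fishId))
    stop("duplicate fish ids in summaries")
  dead <- summaries$fishId %in% deaths
  low <- !dead & summaries$meanTrialsPerSession <= minMeanTrials
  rejected <- data.frame(
    fishId = summaries$fishId[dead | low],
    reason = c(rep("dead", sum(dead)), rep("below_criterion", sum(low)))[
      order(c(which(dead), which(low)))],
    stringsAsFactors = FALSE)
  retained <- summaries$fishId[!dead & !low]
  list(retained = retained, rejected = rejected,
       nRetained = length(retained), nRejected = nrow(rejected))
}

#' Least-squares learning slope
#'
#' Ordinary least-squares slope of a per-session reinforcer count against
#' the session index (1-based), the acquisition measure used for the
#' pre-training phases.
#'
#' @param counts numeric vector of per-session counts (length >= 2).
#' @return the OLS slope (counts per session).
#' @examples
#' learningSlope(c(1, 2, 3, 4, 5))  # 1
#' @export
learningSlope <- function(counts) {
  if (length(counts) < 2L) stop("learning slope needs at least 2 sessions")
  x <- seq_along(counts)
  unname(stats::coef(stats::lm(counts ~ x))[2])
}

#' Paired phase contrast of a session metric
#'
#' For each fish, the mean of a session metric over the last
#' \code{phase1LastK} sessions of phase 1 and the first \code{phase2FirstK}
#' sessions of phase 2 (the windows used when comparing the 5-s and 10-s
#' PSI phases), their difference, and the cohort mean difference. Fish with
#' too few sessions in either phase are flagged and excluded with a
#' warning. The long-format table is suitable for external mixed-model
#' fitting; no model is fitted here.
#'
#' @param metrics data.frame with columns \code{fishId}, \code{phase}
#'   (1 or 2), \code{sessionIndex} (within phase) and \code{value}.
#' @param phase1LastK,phase2FirstK window sizes (default 4 and 4).
#' @return list with \code{perFish} (fishId, mean1, mean2, diff),
#'   \code{cohortMeanDiff}, \code{excluded} (ids) and \code{long}
#'   (fishId, phase, sessionIndex, value restricted to the windows).
#' @export
phaseContrast <- function(metrics, phase1LastK = 4L, phase2FirstK = 4L) {
  stopifnot(all(c("fishId", "phase", "sessionIndex", "value") %in%
                  names(metrics)))
  perFish <- list(); longRows <- list(); excluded <- character(0)
  for (id in unique(metrics$fishId)) {
    m1 <- metrics[metrics$fishId == id & metrics$phase == 1, ]
    m2 <- metrics[metrics$fishId == id & metrics$phase == 2, ]
    if (nrow(m1) < phase1LastK || nrow(m2) < phase2FirstK) {
      excluded <- c(excluded, id)
      next
    }
    w1 <- m1[order(m1$sessionIndex), ]
    w1 <- w1[(nrow(w1) - phase1LastK + 1L):nrow(w1), ]
    w2 <- m2[order(m2$sessionIndex), ][seq_len(phase2FirstK), ]
    perFish[[id]] <- data.frame(fishId = id, mean1 = mean(w1$value),
                                mean2 = mean(w2$value),
                                diff = mean(w2$value) - mean(w1$value),
                                stringsAsFactors = FALSE)
    longRows[[id]] <- rbind(w1, w2)
  }
  if (length(excluded))
    warning("excluded fish with insufficient sessions: ",
            paste(excluded, collapse = ", "))
  perFishDf <- if (length(perFish)) do.call(rbind, perFish) else
    data.frame(fishId = character(0), mean1 = numeric(0),
               mean2 = numeric(0), diff = numeric(0))
  rownames(perFishDf) <- NULL
  longDf <- if (length(longRows)) do.call(rbind, longRows) else
    metrics[0, ]
  rownames(longDf) <- NULL
  list(perFish = perFishDf,
       cohortMeanDiff = if (nrow(perFishDf)) mean(perFishDf$diff) else
         NA_real_,
       excluded = excluded, long = longDf)
}

#' Per-trial speed-accuracy table
#'
#' One row per responded trial (CORRECT or INCORRECT): latency and whether
#' the choice was correct, with fish and session identifiers. Anticipatory
#' and omitted trials carry no choice latency and are excluded. This is the
#' long-format export for speed-accuracy trade-off analysis; the trade-off
#' model itself is fitted externally.
#'
#' @param logs a single \linkS4class{EventLog} or a list of them.
#' @return data.frame(fishId, sessionId, trial, latencyS, correct).
#' @export
speedAccuracyTable <- function(logs) {
  if (is(logs, "EventLog")) logs <- list(logs)
  rows <- lapply(logs, function(log) {
    tr <- log@trials
    tr <- tr[tr$outcome %in% c("CORRECT", "INCORRECT"), , drop = FALSE]
    if (!nrow(tr)) return(NULL)
    data.frame(fishId = log@meta$fishId, sessionId = log@meta$sessionId,
               trial = tr$trial, latencyS = tr$latencyS,
               correct = tr$outcome == "CORRECT", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(fishId = character(0), sessionId = character(0),
                      trial = integer(0), latencyS = numeric(0),
                      correct = logical(0))
  rownames(out) <- NULL
  out
}
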