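mkTrials <- function(nC, nI, nA, nO, latency = 3) {
  data.frame(
    outcome = rep(c("CORRECT", "INCORRECT", "ANTICIPATORY", "OMISSION"),
                  c(nC, nI, nA, nO)),
    latencyS = c(rep(latency, nC), rep(latency, nI),
                 rep(NA_real_, nA + nO)),
    stringsAsFactors = FALSE)
}

test_that("session proportions follow the defining formulas", {
  m <- summarizeSession(mkTrials(6, 2, 2, 2))
  expect_equal(m$accuracy, 0.75)           # 6 / (6 + 2)
  expect_equal(m$anticipatoryProp, 0.2)    # 2 / (6 + 2 + 2)
  expect_equal(m$omissionProp, 2 / 12)
  expect_identical(m$nTrials, 12L)
  # all-omission session: accuracy undefined, omission proportion 1
  mo <- summarizeSession(mkTrials(0, 0, 0, 5))
  expect_true(is.na(mo$accuracy))
  expect_true(is.na(mo$anticipatoryProp))
  expect_equal(mo$omissionProp, 1)
  # empty session: everything undefined, zero trials
  me <- summarizeSession(mkTrials(0, 0, 0, 0))
  expect_identical(me$nTrials, 0L)
  expect_true(all(is.na(c(me$accuracy, me$anticipatoryProp, me$omissionProp,
                          me$meanCorrectLatencyS))))
})

test_that("counts are recoverable from proportions and are scale-free", {
  set.seed(41)
  for (i in 1:50) {
    n <- sample(0:40, 4, replace = TRUE)
    m <- summarizeSession(mkTrials(n[1], n[2], n[3], n[4]))
    if (!is.na(m$accuracy)) {
      expect_equal(round(m$accuracy * (n[1] + n[2])), n[1])
      expect_lt(abs(m$accuracy * (n[1] + n[2]) - n[1]), 1e-9)
    }
    # duplicating every trial leaves all proportions unchanged
    d <- summarizeSession(mkTrials(2 * n[1], 2 * n[2], 2 * n[3], 2 * n[4]))
    expect_identical(d$accuracy, m$accuracy)
    expect_identical(d$anticipatoryProp, m$anticipatoryProp)
    expect_identical(d$omissionProp, m$omissionProp)
  }
})

test_that("mean correct latency uses CORRECT trials only", {
  tr <- rbind(data.frame(outcome = "CORRECT", latencyS = c(2, 4)),
              data.frame(outcome = "INCORRECT", latencyS = 20))
  expect_equal(summarizeSession(tr)$meanCorrectLatencyS, 3)
})

test_that("attrition screen reproduces the cohort bookkeeping", {
  ids <- sprintf("f%02d", 1:90)
  summaries <- data.frame(
    fishId = ids,
    meanTrialsPerSession = c(rep(15, 60), rep(8, 25), rep(15, 5)))
  deaths <- ids[86:90]
  res <- attritionScreen(summaries, deaths)
  expect_identical(res$nRetained, 60L)
  expect_identical(res$nRejected, 30L)
  expect_identical(sum(res$rejected$reason == "dead"), 5L)
  # partition: retained and rejected are disjoint and exhaustive
  expect_length(intersect(res$retained, res$rejected$fishId), 0)
  expect_setequal(c(res$retained, res$rejected$fishId), ids)
  # the criterion is strict: a mean of exactly 10 is rejected
  b <- attritionScreen(data.frame(fishId = "x", meanTrialsPerSession = 10))
  expect_identical(b$nRetained, 0L)
  # empty cohort, duplicate ids
  e <- attritionScreen(data.frame(fishId = character(0),
                                  meanTrialsPerSession = numeric(0)))
  expect_length(e$retained, 0)
  expect_error(attritionScreen(data.frame(fishId = c("a", "a"),
                                          meanTrialsPerSession = c(1, 2))),
               "duplicate")
})

test_that("learning slope equals the closed-form least-squares solution", {
  expect_equal(learningSlope(1:5), 1)
  expect_equal(learningSlope(rep(7, 6)), 0)
  # closed-form oracle: slope = (n*Sxy - Sx*Sy) / (n*Sxx - Sx^2)
  set.seed(17)
  for (i in 1:20) {
    y <- rpois(sample(3:12, 1), 5)
    x <- seq_along(y)
    n <- length(y)
    oracle <- (n * sum(x * y) - sum(x) * sum(y)) /
      (n * sum(x^2) - sum(x)^2)
    expect_equal(learningSlope(y), oracle, tolerance = 1e-9)
    expect_equal(learningSlope(y + 11), learningSlope(y), tolerance = 1e-9)
  }
  expect_error(learningSlope(3), "at least 2")
})

test_that("phase contrast averages the boundary windows per fish", {
  mk <- function(id, v1, v2) rbind(
    data.frame(fishId = id, phase = 1, sessionIndex = 1:5, value = v1),
    data.frame(fishId = id, phase = 2, sessionIndex = 1:4, value = v2))
  # identical windows: difference zero
  same <- phaseContrast(mk("a", 0.3, 0.3))
  expect_equal(same$perFish$diff, 0)
  # constant +0.1 shift in phase 2
  up <- phaseContrast(mk("b", 0.2, 0.3))
  expect_equal(up$perFish$diff, 0.1)
  expect_equal(up$cohortMeanDiff, 0.1)
  # phase-1 window takes the LAST four sessions
  ramp <- phaseContrast(mk("c", c(0, 10, 10, 10, 10), 10))
  expect_equal(ramp$perFish$diff, 0)
  # insufficient sessions: flagged and excluded
  short <- rbind(mk("d", 0.1, 0.2),
                 data.frame(fishId = "e", phase = 1, sessionIndex = 1:2,
                            value = 0.5),
                 data.frame(fishId = "e", phase = 2, sessionIndex = 1:4,
                            value = 0.5))
  expect_warning(res <- phaseContrast(short), "insufficient")
  expect_identical(res$excluded, "e")
  expect_identical(res$perFish$fishId, "d")
})

test_that("raising the PSI raises the cohort anticipatory contrast", {
  rows <- list()
  for (i in 1:6) {
    ag <- AgentParams(prematureHazard = 0.05, seed = 100L + i)
    for (phase in 1:2) for (s in 1:4) {
      out <- simulateTrialOutcomes(
        ag, SessionSchedule("FIVE_CSRTT", psiS = c(5, 10)[phase]), 60L,
        seed = deriveSeed(100L + i, phase, s))
      m <- summarizeSession(
        data.frame(outcome = out$outcome, latencyS = out$latencyS))
      rows[[length(rows) + 1L]] <-
        data.frame(fishId = sprintf("f%d", i), phase = phase,
                   sessionIndex = s, value = m$anticipatoryProp)
    }
  }
  res <- phaseContrast(do.call(rbind, rows))
  expect_gt(res$cohortMeanDiff, 0)
})

test_that("speed-accuracy table keeps one row per responded trial", {
  log <- EventLog(list(fishId = "f1", sessionId = "s1",
                       phase = "FIVE_CSRTT"),
                  trials = cbind(trial = 1:5, mkTrials(2, 1, 1, 1),
                                 stringsAsFactors = FALSE))
  tab <- speedAccuracyTable(log)
  expect_identical(nrow(tab), 3L)
  expect_identical(sum(tab$correct), 2L)
})

test_that("latency-coupled accuracy shows a positive trade-off", {
  ag <- AgentParams(prematureHazard = 0, pRespond = 1, pCorrect = 0.6,
                    speedAccuracy = TRUE, saSlope = 2, seed = 88L)
  out <- simulateTrialOutcomes(ag, SessionSchedule("FIVE_CSRTT"), 4000L)
  resp <- out[out$outcome %in% c("CORRECT", "INCORRECT"), ]
  r <- cor(resp$latencyS, as.numeric(resp$outcome == "CORRECT"))
  expect_gt(r, 0.1)
})
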