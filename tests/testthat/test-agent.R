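test_that("degenerate agent parameters produce pure outcome types", {
  sched <- SessionSchedule("FIVE_CSRTT", sessionLengthS = 600, rngSeed = 5L)
  allCorrect <- simulateSession(
    AgentParams(prematureHazard = 0, pRespond = 1, pCorrect = 1, seed = 1L),
    sched)
  expect_gt(nrow(trialRecords(allCorrect)), 0)
  expect_true(all(trialRecords(allCorrect)$outcome == "CORRECT"))
  allOmit <- simulateSession(
    AgentParams(prematureHazard = 0, pRespond = 0, seed = 2L), sched)
  expect_true(all(trialRecords(allOmit)$outcome == "OMISSION"))
  allAnt <- simulateSession(AgentParams(prematureHazard = 50, seed = 3L),
                            sched)
  expect_true(all(trialRecords(allAnt)$outcome == "ANTICIPATORY"))
})

test_that("controller classification matches simulator ground truth", {
  for (seed in 1:30) {
    sched <- SessionSchedule("FIVE_CSRTT", sessionLengthS = 480,
                             psiS = if (seed %% 2) 5 else 10,
                             rngSeed = seed + 1000L)
    ag <- AgentParams(prematureHazard = 0.08, pCorrect = 0.6,
                      pRespond = 0.85, seed = seed)
    sim <- simulateSession(ag, sched)
    ctl <- run5CSRTT(sched, detectionEvents(sim))
    expect_identical(trialRecords(ctl), trialRecords(sim))
    tr <- trialRecords(ctl)
    counts <- table(factor(tr$outcome, levels = c("CORRECT", "INCORRECT",
                                                  "ANTICIPATORY", "OMISSION")))
    expect_identical(sum(counts), nrow(tr))  # conservation
  }
})

test_that("deterministic latency is recorded to within one frame", {
  sched <- SessionSchedule("FIVE_CSRTT", sessionLengthS = 400, rngSeed = 9L)
  ag <- AgentParams(prematureHazard = 0, pRespond = 1, pCorrect = 1,
                    latencyMeanlog = log(2), latencySdlog = 0, seed = 4L)
  tr <- trialRecords(simulateSession(ag, sched))
  expect_gt(nrow(tr), 0)
  expect_true(all(abs(tr$latencyS - 2) <= 1 / 50))
})

test_that("a fixed seed reproduces the session exactly", {
  sched <- SessionSchedule("FIVE_CSRTT", sessionLengthS = 400, rngSeed = 2L)
  ag <- AgentParams(seed = 77L)
  expect_equal(simulateSession(ag, sched), simulateSession(ag, sched))
})

test_that("anticipatory rate follows the exponential-hazard closed form", {
  ag <- AgentParams(prematureHazard = 0.1, seed = 12L)
  sched <- SessionSchedule("FIVE_CSRTT", psiS = 5)
  out <- simulateTrialOutcomes(ag, sched, 10000L)
  p <- mean(out$outcome == "ANTICIPATORY")
  expected <- 1 - exp(-0.1 * 5)  # 0.3935
  se <- sqrt(expected * (1 - expected) / 10000)
  expect_lt(abs(p - expected), 3 * se)
})

test_that("anticipatory proportion rises with the PSI", {
  ag <- AgentParams(prematureHazard = 0.05, seed = 13L)
  p5 <- mean(simulateTrialOutcomes(
    ag, SessionSchedule("FIVE_CSRTT", psiS = 5), 4000L,
    seed = 101L)$outcome == "ANTICIPATORY")
  p10 <- mean(simulateTrialOutcomes(
    ag, SessionSchedule("FIVE_CSRTT", psiS = 10), 4000L,
    seed = 102L)$outcome == "ANTICIPATORY")
  expect_gt(p10, p5)
})

test_that("hazard recovery is consistent and handles the zero boundary", {
  expect_warning(
    est0 <- recoverHazard(data.frame(psi = c(5, 10), nTrials = c(100, 100),
                                     nAnticipatory = c(0, 0))),
    "boundary")
  expect_identical(est0, 0)
  ag <- AgentParams(prematureHazard = 0.05, seed = 55L)
  counts <- do.call(rbind, lapply(c(5, 10), function(psi) {
    out <- simulateTrialOutcomes(ag, SessionSchedule("FIVE_CSRTT", psiS = psi),
                                 2000L, seed = deriveSeed(55L, psi))
    data.frame(psi = psi, nTrials = 2000L,
               nAnticipatory = sum(out$outcome == "ANTICIPATORY"))
  }))
  est <- recoverHazard(counts)
  expect_lt(abs(est - 0.05) / 0.05, 0.10)
})

test_that("hazard recovery accepts event logs directly", {
  sched5 <- SessionSchedule("FIVE_CSRTT", sessionLengthS = 600, psiS = 5,
                            rngSeed = 6L)
  sched10 <- SessionSchedule("FIVE_CSRTT", sessionLengthS = 600, psiS = 10,
                             rngSeed = 7L)
  ag <- AgentParams(prematureHazard = 0.06, seed = 14L)
  logs <- list(simulateSession(ag, sched5), simulateSession(ag, sched10))
  est <- recoverHazard(logs)
  expect_gt(est, 0)
  expect_lt(est, 1)
})

test_that("trajectories place the fish in a region exactly during its events", {
  geo <- standardRigGeometry()
  ev <- data.frame(region = "mag", onset_frame = 10L, offset_frame = 20L,
                   onset_time_s = 0.2, offset_time_s = 0.4)
  tra <- eventsToTrajectory(ev, geo)
  rect <- roiRect(geo$rois$mag)
  inMag <- tra$row >= rect[1] & tra$row < rect[3] &
    tra$col >= rect[2] & tra$col < rect[4]
  expect_identical(which(inMag) - 1L, 10:19)  # 0-based occupied frames
  # empty log: stationary at home, outside every ROI
  traEmpty <- eventsToTrajectory(ev[0, ], geo)
  expect_identical(unique(traEmpty$row), geo$home[1])
  # simultaneous events in two regions are infeasible for one fish
  bad <- rbind(ev, data.frame(region = "ap1", onset_frame = 15L,
                              offset_frame = 25L, onset_time_s = 0.3,
                              offset_time_s = 0.5))
  expect_error(eventsToTrajectory(bad, geo), "infeasible")
})

test_that("full simulated session round-trips through synthetic video", {
  sched <- SessionSchedule("FIVE_CSRTT", sessionLengthS = 90, fps = 10,
                           rngSeed = 11L)
  ag <- AgentParams(prematureHazard = 0.05, seed = 19L)
  sim <- simulateSession(ag, sched)
  ev <- detectionEvents(sim)
  expect_gt(nrow(ev), 0)
  geo <- standardRigGeometry()
  tra <- eventsToTrajectory(sim, geo)
  scene <- SyntheticScene(backgroundLevel = 140, fishIntensity = 60,
                          rippleSigma = 1.5, trajectory = tra, seed = 23L)
  video <- makeSyntheticVideo(scene, nrow(tra))
  got <- processStream(video, geo$rois, fps = 10)
  expect_identical(nrow(got), nrow(ev))
  expect_true(all(abs(got$onset_frame - ev$onset_frame) <= 1))
})

test_that("cohort draws are reproducible and stable under enlargement", {
  c5 <- simulateCohort(5, seed = 33L)
  c8 <- simulateCohort(8, seed = 33L)
  expect_identical(names(c5), names(c8)[1:5])
  for (id in names(c5))
    expect_equal(c5[[id]], c8[[id]])
  expect_equal(simulateCohort(5, seed = 33L), c5)
  lam <- vapply(simulateCohort(200, seed = 1L),
                function(a) a@prematureHazard, 0)
  expect_gt(mean(lam), 0.03)
  expect_lt(mean(lam), 0.07)
  # gamma-distributed hazards are right-skewed
  expect_gt(mean((lam - mean(lam))^3) / sd(lam)^3, 0.5)
})
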