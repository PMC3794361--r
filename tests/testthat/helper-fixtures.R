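# Shared fixtures and independent oracles.

# Independent brute-force two-pass population variance (explicit loops, no
# calls into the package or stats::var).
twoPassVariance <- function(px) {
  n <- length(px)
  m <- 0
  for (v in px) m <- m + v
  m <- m / n
  s <- 0
  for (v in px) s <- s + (v - m)^2
  s / n
}

# High-contrast scripted scene: known zone entries rendered as synthetic
# video over the standard rig geometry. Background/fish intensities leave
# +/-50 of headroom so uniform offsets never clip.
..fixtureCache <- new.env(parent = emptyenv())

highContrastFixture <- function(seed = 42, rippleSigma = 1.5,
                                events = NULL) {
  cacheable <- is.null(events)
  key <- sprintf("fx_%d_%g", seed, rippleSigma)
  if (cacheable && !is.null(..fixtureCache[[key]]))
    return(..fixtureCache[[key]])
  geo <- standardRigGeometry()
  if (is.null(events)) {
    events <- data.frame(
      region = c("mag", "ap1", "ap3", "mag", "ap5", "ap2"),
      onset_frame = c(100L, 200L, 300L, 420L, 500L, 590L),
      offset_frame = c(180L, 260L, 380L, 470L, 560L, 640L),
      stringsAsFactors = FALSE)
    events$onset_time_s <- events$onset_frame / 50
    events$offset_time_s <- events$offset_frame / 50
  }
  tra <- eventsToTrajectory(events, geo)
  scene <- SyntheticScene(backgroundLevel = 140, fishIntensity = 60,
                          rippleSigma = rippleSigma, trajectory = tra,
                          seed = seed)
  fx <- list(geo = geo, events = events, scene = scene,
             video = makeSyntheticVideo(scene, nrow(tra)))
  if (cacheable) ..fixtureCache[[key]] <- fx
  fx
}

# A short hand-computed 5-CSRTT scripted stream with one trial of each
# outcome class. Timeline (fps 50, hold 60, gate 0.5 s, psi 5, stim 30,
# timeout/iti 20):
#   trial 1 start 60.0, stim on 65.5 -> CORRECT at 68.0 (latency 2.5),
#           magazine 71.0, next start 91.0
#   trial 2 start 91.0, stim on 96.5 -> ANTICIPATORY at 93.0, next 113.0
#   trial 3 start 113.0, stim on 118.5, stim end 148.5 -> OMISSION,
#           next 168.5
#   trial 4 start 168.5, stim on 174.0 -> INCORRECT at 180.0 (latency 6.0)
# Session length 230 s discards the unresolved 5th trial.
scripted5CSRTT <- function(rngSeed = 101L) {
  schedule <- SessionSchedule("FIVE_CSRTT", sessionLengthS = 230,
                              rngSeed = rngSeed)
  stim <- selectStimulus(5L, rngSeed)
  wrong <- function(p) if (p == 1L) 2L else 1L
  mkEv <- function(region, t) {
    f <- as.integer(round(t * 50))
    data.frame(region = region, onset_frame = f,
               offset_frame = f + 25L, onset_time_s = f / 50,
               offset_time_s = (f + 25L) / 50, stringsAsFactors = FALSE)
  }
  events <- rbind(
    mkEv(apertureNames()[stim[1]], 68), mkEv("mag", 71),
    mkEv(apertureNames()[3], 93),
    mkEv(apertureNames()[wrong(stim[4])], 180))
  list(schedule = schedule, events = events, stim = stim,
       expected = data.frame(
         outcome = c("CORRECT", "ANTICIPATORY", "OMISSION", "INCORRECT"),
         latencyS = c(2.5, NA, NA, 6.0)))
}
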