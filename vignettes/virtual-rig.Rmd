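---
title: "The zfrig virtual rig: detection, control and analysis of a zebrafish 5-CSRTT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The zfrig virtual rig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zfrig)
```

## What this package models

The 5-choice serial reaction time task (5-CSRTT) is a continuous-performance
assay of attention and impulse control: the subject must respond to a briefly
lit one-of-five location to earn food, and responses made *before* the light
comes on (anticipatory responses) operationalize impulsivity. Automated rigs
for adult zebrafish implement the task with a camera watching a shallow tank,
five stimulus LEDs behind apertures at one end, a food magazine with its own
LED at the other, and a pneumatic gate between them.

`zfrig` is a software re-creation of such a rig — a *virtual rig*. It contains
the four layers a physical installation needs, each usable on its own:

1. **Detection** (`roiVariance`, `schmittUpdate`, `processStream`): declaring
   when a fish is inside a region of interest, from grayscale frames.
2. **Session control** (`run5CSRTT` and the three pre-training controllers):
   the closed-loop state machine that turns detection events into trial
   outcomes and apparatus commands.
3. **Behavior** (`AgentParams`, `simulateSession`, `recoverHazard`): a
   stochastic fish agent that generates event streams with controllable
   impulsivity, standing in for live animals.
4. **Analysis** (`summarizeSession`, `attritionScreen`, `phaseContrast`,
   `speedAccuracyTable`): the session-level performance parameters and
   long-format exports.

A synthetic-video generator (`SyntheticScene`, `makeSyntheticVideo`) closes
the loop for end-to-end testing: scripted behavior can be rendered to video,
re-detected, re-classified and compared with ground truth.

## The detection model

Tracking a 30 × 5-pixel fish against water ripples, shadows and camera
auto-exposure is unreliable with background subtraction. The rig's premise is
simpler: the tank bottom is uniformly bright, the fish is dark, and detection
is only needed inside small regions (the five apertures and the magazine).
Within such a region, illumination changes are approximately *uniform*, so the
**variance** of pixel intensities is near zero when the region is empty and
jumps when the dark streak enters — and a uniform additive offset leaves the
variance exactly unchanged. `roiVariance` therefore computes the population
variance (divide by *N*) of the intensities in the region; the divide-by-*N*
convention is immaterial to thresholding (thresholds are operator-set) and was
chosen for its exact additive-shift invariance and simplicity.

Raw thresholding chatters when the variance hovers near the threshold, so the
detector is a Schmitt trigger: a VACANT region becomes OCCUPIED when the
variance strictly exceeds the threshold *T*, and is released only when it
falls strictly below 0.8 *T*. No new onset can fire while OCCUPIED. The 80 %
release fraction is the rig's figure; it is exposed as the `hysteresis`
parameter (default 0.8) since per-region tuning is plausible. Values exactly
at either boundary do not transition ("exceeds" / "decreases to below" read
as strict inequalities). Every region starts VACANT at stream start.

Thresholds on a real rig are set by eye from a live variance graph. The
offline replacement, `suggestThreshold`, places the threshold halfway between
the `vacantFraction` quantile of a recorded variance trace (the top of the
empty-region noise floor) and the trace maximum, and refuses degenerate
constant traces.

## The synthetic scene

`SyntheticScene` reproduces exactly the imaging ingredients the detector is
designed around, and nothing more: a uniform background (default intensity
220 of 255), a global per-frame illumination offset (`illuminationDrift`),
i.i.d. Gaussian pixel noise (`rippleSigma`, default 2), and the fish as a
solid dark streak (defaults 30 × 5 px at intensity 40) placed by a scripted
trajectory. The default frame is 100 × 300 rather than the camera's
360 × 640, which keeps test videos small without changing any geometry that
matters (ROI sizes comfortably exceed the streak).

What the generator does *not* emulate — and what passing its tests therefore
cannot show about real footage: spatially structured ripple patterns,
reflections and moving shadows (non-uniform within an ROI), motion blur of
the tail, partial occlusions, gradual ROI entry (the synthetic fish enters a
region between two frames), and auto-exposure dynamics that correlate with
the stimulus LEDs. The uniform-offset invariance tests verify the detector's
design premise, not the premise's validity in any particular tank.

## The session state machine

Durations follow the validated protocol and are all configurable in
`SessionSchedule` (seconds): 1800-s sessions, 5- or 10-s pre-stimulus
interval (PSI), 30-s stimulus presentation, 20-s timeout and inter-trial
interval, 60-s initial hold, magazine light up to 10 s with 30-s gaps,
habituation food at most every 30 s. The camera clock (default 50 fps) is the
time base: every event and command time is quantized to 1/fps.

A 5-CSRTT trial runs: gate up → PSI wait → stimulus LED *i* on → classify
the first aperture entry. The outcome rules:

* **CORRECT** — entry to the lit aperture during the stimulus window; the
  magazine light comes on, the gate closes as the fish passes back, food
  arrives on magazine entry, then the ITI.
* **INCORRECT** — entry to a wrong aperture during the window.
* **ANTICIPATORY** — entry to *any* aperture during the PSI; anticipatory
  classification takes priority over position, and the stimulus is never
  shown (the scheduled position draw is still consumed, keeping the stimulus
  sequence aligned across re-runs).
* **OMISSION** — no entry within the stimulus window.

Failed trials earn the timeout confinement with no food. Latency is defined
only for CORRECT/INCORRECT, measured from stimulus onset, and bounded by the
stimulus duration.

Where the protocol description is silent, this package makes the following
choices (each is a documented convention, not a claim about the original
rig):

* **Entry semantics.** An "entry" is the ONSET edge of a detection event. A
  fish already occupying an aperture when the window opens does not count
  until it re-enters — the natural reading under the Schmitt re-trigger rule.
* **Initial hold.** The 1-minute hold applies once at session start;
  subsequent trials use the 20-s ITI.
* **Stimulus selection.** Uniform over the five positions with a seeded RNG,
  repeats allowed.
* **Gate.** Motion is instantaneous after a configurable travel latency
  (default 0.5 s; the physical gate took under a second); the PSI is counted
  from gate-up completion.
* **Magazine-training cycle.** The session opens with the 30-s dark gap, and
  an illumination with no entry times out after its 10-s maximum before the
  next gap. With an entry 3 s into every illumination this yields the
  33-s cycle arithmetic (54 deliveries in 1800 s) used in the tests.
* **Correct-trial food timing.** Food fires on the first magazine onset after
  the correct response; if the fish never returns before session end there is
  no delivery and the trial remains CORRECT.
* **Termination.** The session ends by clock; a trial still unresolved at
  expiry is discarded, not recorded.
* **Hold-period anticipation.** Aperture entries cannot occur while the gate
  is down (the apertures are physically inaccessible), so the anticipatory
  window opens at gate-up completion.

`driveApparatus` rebuilds the full command stream (gate, LEDs, feeder) from
the trial records deterministically, validating the outcome contracts; it is
the conservation check that every CORRECT trial has exactly one FEED and no
stimulus LED is lit outside its window.

## The fish agent

No quantitative behavioral model of zebrafish 5-CSRTT performance exists; the
agent's parametric forms are conventions of this package, chosen as the
simplest mechanisms that produce the task's outcome classes:

* **Premature entries** follow a homogeneous Poisson hazard λ (per second)
  during the PSI, so a trial is anticipatory with probability
  1 − e^(−λ·PSI). This is the simplest model in which lengthening the PSI
  raises anticipatory responding, the task's core manipulation. The default
  λ = 0.05/s gives anticipatory proportions of ≈ 0.22 at a 5-s and ≈ 0.39 at
  a 10-s PSI.
* **Response latency** is log-normal (median 4 s, σ_log = 0.5 by default),
  truncated to the stimulus window by rejection so that `pRespond` alone
  governs omissions; without truncation the tail of the latency distribution
  would leak into the omission rate and the degenerate corners (`pRespond` of
  0 or 1) would not be pure.
* **Choice** hits the lit aperture with probability `pCorrect` (default 0.6,
  a typical adult-zebrafish discrimination accuracy), else uniformly among
  the other four. Optionally (`speedAccuracy = TRUE`) accuracy becomes an
  increasing logistic function of log-latency, inducing a speed–accuracy
  trade-off; this is off by default.
* **Cohorts** draw per-fish hazards from a gamma distribution (shape 2,
  mean 0.05/s), giving the right-skewed between-fish distribution of
  anticipatory rates expected of a mutagenized population, and accuracy and
  response propensity from beta distributions.

The simulator advances the *same* clocked timeline as the controller and
snaps every emitted event to the frame grid by flooring, which makes the
closed-loop identity exact rather than approximate: an entry sampled strictly
before stimulus onset can never quantize onto the onset frame. The test-suite
verifies outcome-by-outcome equality between simulator ground truth and
controller classification over 100+ seeded sessions.

`recoverHazard` inverts the anticipatory model: given anticipatory counts at
one or more PSIs it maximizes the Bernoulli likelihood with
p(t) = 1 − e^(−λt) (one-dimensional search; closed form at a single PSI).
At 2000 trials per PSI condition the estimate is within 10 % of truth, the
scale at which the package's own recovery checks run. Zero anticipatory
responses everywhere sit on the boundary and return 0 with a warning.

## Metrics and screening

Session metrics follow the task's standard formulas exactly:
accuracy = correct/(correct+incorrect),
anticipatory = early/(correct+incorrect+early),
omissions = omissions/(correct+incorrect+early+omissions), with mean correct
latency over CORRECT trials only. Proportions with a zero denominator are
reported as `NA`, never 0 — an all-omission session has *undefined* accuracy,
and coercing it to 0 would silently bias cohort means.

`attritionScreen` applies the protocol's retention criterion: a fish is kept
only if it did not die and its mean trials per session is *strictly* greater
than 10 (a mean of exactly 10 is rejected). The mean is taken over all
5-CSRTT sessions attempted; the averaging window is configurable. Note the
screen computes retention from the counts it is given; a cohort of 90 with
5 deaths and 25 sub-criterion fish yields exactly 60 retained, i.e. a 33.3 %
attrition rate by construction.

`phaseContrast` compares, per fish, the mean of a metric over the last *k*
sessions of one phase and the first *k* of the next (default 4 and 4, the
windows used when a PSI change is introduced), and returns the long-format
table for external mixed-model analysis. Mixed-effects modeling itself
(REML, Poisson GLMMs, Satterthwaite degrees of freedom, post-hoc tests) is
deliberately out of scope: those are routine fits for `lme4`-class packages
on the exported tables, not part of the rig.

## Numerical choices

* Population variance is computed two-pass (mean, then squared deviations);
  the test-suite checks agreement with an independent brute-force loop to
  1e-9 relative error on random regions.
* Threshold comparisons are strict on both edges of the hysteresis band.
* Times are quantized by *flooring* onto the frame grid with a 1e-9 s guard
  against representation error of grid-aligned values; flooring (rather than
  rounding) preserves strict "before-onset" relations under quantization.
* Event CSVs round-trip bit-exactly: doubles are written with 17 significant
  digits and re-parsed, and the reader enforces the column schema.
* The single experiment seed is fanned out through a stable string-keyed
  derivation (`deriveSeed`), so adding a fish or session to a design never
  perturbs the random streams of existing ones.
* Degenerate inputs fail loudly: ROIs outside the frame or under 2 pixels,
  non-positive thresholds, constant variance traces, out-of-order or
  non-finite event times, trajectories leaving the frame, and overlapping
  events in disjoint regions (infeasible for one fish) all raise specific
  errors.

## Problem sizes in the shipped checks

The package's own verification runs at deliberately modest scale, chosen to
exercise every code path while staying quick on one core: synthetic videos of
a few hundred 100 × 300 frames at high contrast; 100 seeded closed-loop
sessions of 420–600 s; 2000 simulated trials per PSI condition (20 seeds for
hazard recovery); a 90-fish synthetic screening cohort. Detection accuracy on
the synthetic fixtures is exact (onsets recovered to the frame); on real
footage it is bounded by the scene properties discussed above.

## Known limitations

* The detector reports region occupancy only — no tank-wide trajectory,
  no identity maintenance, no multi-fish support.
* The agent has no learning dynamics: acquisition curves across sessions
  arise only if the caller varies parameters between sessions.
* The virtual gate is binary with a fixed latency; partial occlusions of ROIs
  by the moving gate are not rendered.
* Live camera capture and the interactive threshold GUI of the original
  installation are out of scope; configuration files and
  `suggestThreshold` replace them.

## A minimal end-to-end run

```{r, eval = FALSE}
res <- runExperiment(list(seed = 1L, nFish = 4L, sessionsPsi5 = 3L,
                          sessionsPsi10 = 3L, sessionLengthS = 600),
                     outDir = "screen-demo")
head(res$sessions)
```

This simulates the cohort, classifies every event stream with the session
controller, and writes `sessions.csv`, `fish.csv`, `trials.csv` and a
manifest tying every output to the seed and configuration.
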