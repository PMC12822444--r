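# Seeded generators of synthetic physiological inputs: breathing airflow,
# speech airflow bursts, cough trains, PPG-like heartbeat traces, and
# labelled multi-source datasets.  Every generator is a pure function of
# (parameters, seed): the RNG is scoped via .withSeed and child seeds are
# derived deterministically from the root seed.

# Additive velocity noise (m/s) and slow baseline drift shared by the
# airflow generators.
.flowNoiseSd <- 0.02
.flowDriftAmp <- 0.01

.noiseAndDrift <- function(n, fs) {
  t <- (seq_len(n) - 1L) / fs
  phase <- runif(1L, 0, 2 * pi)
  rnorm(n, 0, .flowNoiseSd) + .flowDriftAmp * sin(2 * pi * 0.05 * t + phase)
}

# Sharp cough transient sampled at offsets tau >= 0: fast rise to `peak`
# at tau = tr, then exponential-like decay (gamma pulse).
.coughPulse <- function(tau, peak, tr = 0.06) {
  out <- numeric(length(tau))
  ok <- tau >= 0 & tau <= 0.35
  out[ok] <- peak * (tau[ok] / tr) * exp(1 - tau[ok] / tr)
  out
}

.coughPeak <- c(mild = 1.2, moderate = 3, severe = 8)

#' Generate a breathing airflow signal
#'
#' Half-sinusoid exhale lobes (`v = peak * sin`, `Tair = exhaleT`) alternate
#' with slightly weaker inhale lobes (`Tair = ambientT`) at the pattern's
#' breathing rate, with seeded Gaussian amplitude noise and a slow baseline
#' drift.  `weightless` cycles start with a ~0.5 s near-zero-flow gap
#' followed by an exhale transient; `cough` superimposes moderate cough
#' transients on tidal breathing.  Velocities are clipped to be
#' non-negative, and for the `normal` kind to the measured 2.5 m/s ceiling.
#'
#' @param pattern a [BreathPattern-class].
#' @param duration signal length, s (> 0).
#' @param fs sampling rate, Hz (>= 20).
#' @param seed integer seed; the same seed reproduces the signal exactly.
#' @return a [FlowSignal-class].
#' @examples
#' fl <- genBreathFlow(breathPattern("normal"), duration = 20, seed = 7)
#' max(velocity(fl)) <= 2.5
#' @export
genBreathFlow <- function(pattern, duration, fs = 100, seed = 1L) {
  stopifnot(is(pattern, "BreathPattern"))
  .assertScalar(duration, "duration", positive = TRUE)
  if (!is.numeric(fs) || length(fs) != 1L || fs < 20)
    stop("'fs' must be >= 20 Hz", call. = FALSE)
  .withSeed(seed, {
    n <- floor(duration * fs)
    t <- (seq_len(n) - 1L) / fs
    period <- 60 / pattern@rate
    half <- period / 2
    phase <- t %% period
    exhale <- phase < half
    v <- numeric(n)
    Tair <- ifelse(exhale, pattern@exhaleT, pattern@ambientT)
    if (pattern@kind == "weightless") {
      # per cycle: 0.5 s near-zero gap, 0.4 s exhale transient, then a
      # reduced tidal remainder
      gap <- 0.5
      tw <- 0.4
      inGap <- phase < gap
      inTrans <- phase >= gap & phase < gap + tw
      rest <- !inGap & !inTrans
      v[inTrans] <- pattern@peakExhaleV *
        sin(pi * (phase[inTrans] - gap) / tw)
      restPhase <- phase[rest] - (gap + tw)
      restLen <- period - gap - tw
      v[rest] <- 0.15 * pattern@peakExhaleV *
        abs(sin(pi * restPhase / (restLen / 2)))
      Tair[inGap] <- pattern@ambientT
      Tair[inTrans] <- pattern@exhaleT
      Tair[rest] <- ifelse(restPhase < restLen / 2, pattern@ambientT,
                           pattern@exhaleT)
    } else {
      v[exhale] <- pattern@peakExhaleV * sin(pi * phase[exhale] / half)
      v[!exhale] <- 0.8 * pattern@peakExhaleV *
        sin(pi * (phase[!exhale] - half) / half)
    }
    if (pattern@kind == "cough" && duration > 2) {
      onsets <- seq(1.5, duration - 0.5, by = 4)
      onsets <- onsets + rnorm(length(onsets), 0, 0.1)
      for (o in onsets) {
        pulse <- .coughPulse(t - o, .coughPeak[["moderate"]])
        v <- v + pulse
        Tair[pulse > 0.05] <- pattern@exhaleT
      }
    }
    v <- v + .noiseAndDrift(n, fs)
    v <- pmax(v, 0)
    if (pattern@kind == "normal") v <- pmin(v, 2.5)
    flowSignal(t, v, Tair)
  })
}

#' Generate a speech airflow signal
#'
#' Superposes half-sinusoid airflow bursts (one per syllable group of the
#' template) on a quiet baseline.  Per-burst onset and peak receive small
#' seeded jitter, so repeated samples of a phrase vary while phrases remain
#' separable.  Air is at exhale temperature during bursts and ambient
#' otherwise.
#'
#' @param template a [SpeechTemplate-class].
#' @param fs sampling rate, Hz.
#' @param seed integer seed.
#' @param duration total signal length, s (default 3 s, covering every
#'   built-in template).
#' @param exhaleT,ambientT air temperatures, K.
#' @return a [FlowSignal-class].
#' @examples
#' fl <- genSpeechFlow(speechTemplate("HELP"), seed = 3)
#' @export
genSpeechFlow <- function(template, fs = 100, seed = 1L, duration = 3,
                          exhaleT = celsiusToKelvin(38),
                          ambientT = celsiusToKelvin(20)) {
  stopifnot(is(template, "SpeechTemplate"))
  b <- template@bursts
  if (max(b$onset + b$duration) > duration)
    stop("'duration' too short for the template's bursts", call. = FALSE)
  .withSeed(seed, {
    n <- floor(duration * fs)
    t <- (seq_len(n) - 1L) / fs
    v <- rep(0.05, n)
    env <- numeric(n)
    for (k in seq_len(nrow(b))) {
      onset <- max(0, b$onset[k] + rnorm(1L, 0, 0.02))
      peak <- b$peak[k] * (1 + rnorm(1L, 0, 0.05))
      dur <- b$duration[k]
      inB <- t >= onset & t < onset + dur
      env[inB] <- env[inB] + peak * sin(pi * (t[inB] - onset) / dur)
    }
    v <- v + pmax(env, 0) + .noiseAndDrift(n, fs)
    Tair <- ifelse(env > 0.1, exhaleT, ambientT)
    flowSignal(t, pmax(v, 0), Tair)
  })
}

#' Generate a cough airflow train
#'
#' Places `count` sharp high-velocity transients inside `[0, window]` s on a
#' quiet-breathing baseline (ambient-temperature air, so it leaves the
#' device voltage flat).  Peak velocities are ordered
#' mild < moderate < severe (1.2, 3, 8 m/s) so that severity survives the
#' square-root compression of the convective forward model.  Event centres
#' are evenly spaced with seeded jitter and a minimum spacing of 0.6 s.
#'
#' @param intensity `"mild"`, `"moderate"` or `"severe"`.
#' @param count number of cough events (>= 0).
#' @param window train length, s (> 0).
#' @param fs sampling rate, Hz.
#' @param seed integer seed.
#' @param exhaleT,ambientT air temperatures, K.
#' @return a [FlowSignal-class] of length `window`.
#' @examples
#' fl <- genCoughTrain("severe", count = 3, window = 5, seed = 2)
#' @export
genCoughTrain <- function(intensity = c("mild", "moderate", "severe"),
                          count, window, fs = 100, seed = 1L,
                          exhaleT = celsiusToKelvin(38),
                          ambientT = celsiusToKelvin(20)) {
  intensity <- match.arg(intensity)
  count <- .assertCount(count, "count")
  .assertScalar(window, "window", positive = TRUE)
  minSpacing <- 0.6
  if (count * minSpacing > window)
    stop(sprintf("cannot place %d coughs with %.2g s spacing in a %.2g s window",
                 count, minSpacing, window), call. = FALSE)
  .withSeed(seed, {
    n <- floor(window * fs)
    t <- (seq_len(n) - 1L) / fs
    # quiet baseline breathing
    v <- 0.3 * abs(sin(2 * pi * t / 4)) + .noiseAndDrift(n, fs)
    Tair <- rep(ambientT, n)
    if (count > 0L) {
      slots <- seq(0.3, window - 0.45, length.out = max(count, 2L))[seq_len(count)]
      jit <- runif(count, -0.1, 0.1)
      centres <- pmin(pmax(slots + jit, 0.1), window - 0.4)
      peak <- .coughPeak[[intensity]] * (1 + rnorm(count, 0, 0.03))
      for (k in seq_len(count)) {
        pulse <- .coughPulse(t - centres[k], peak[k])
        v <- v + pulse
        Tair[pulse > 0.05] <- exhaleT
      }
    }
    flowSignal(t, pmax(v, 0), Tair)
  })
}

#' Generate a PPG-like heartbeat trace
#'
#' Sums per-beat two-Gaussian pulses (systolic peak plus dicrotic wave) at
#' jittered beat times.  The `abnormal` kind (pain-stimulus surrogate)
#' additionally halves the pulse amplitude over the middle third of the
#' trace and carries strongly elevated beat-interval jitter.
#'
#' @param pattern a [HeartbeatPattern-class].
#' @param duration trace length, s (> 0).
#' @param fs sampling rate, Hz.
#' @param seed integer seed.
#' @return data.frame with columns `time_s`, `value`.
#' @examples
#' hb <- genHeartbeat(heartbeatPattern("resting"), duration = 10, seed = 4)
#' @export
genHeartbeat <- function(pattern, duration, fs = 100, seed = 1L) {
  stopifnot(is(pattern, "HeartbeatPattern"))
  .assertScalar(duration, "duration", positive = TRUE)
  .withSeed(seed, {
    n <- floor(duration * fs)
    t <- (seq_len(n) - 1L) / fs
    base <- 60 / pattern@rate
    nBeats <- ceiling(duration / base) + 3L
    intervals <- base * pmax(1 + rnorm(nBeats, 0, pattern@jitter), 0.4)
    beats <- cumsum(c(runif(1L, 0, 0.3 * base), intervals))
    beats <- beats[beats < duration + 0.5]
    amp <- rep(1, length(beats))
    if (pattern@kind == "abnormal") {
      dip <- beats > duration / 3 & beats < 2 * duration / 3
      amp[dip] <- 0.45
    }
    value <- numeric(n)
    for (k in seq_along(beats)) {
      tb <- beats[k]
      value <- value + amp[k] * (
        pattern@systolicAmp * exp(-(t - tb)^2 / (2 * pattern@systolicWidth^2)) +
        pattern@dicroticAmp *
          exp(-(t - tb - 0.25 * base)^2 / (2 * pattern@dicroticWidth^2)))
    }
    value <- value + rnorm(n, 0, 0.02)
    data.frame(time_s = t, value = value)
  })
}

# Sources of abnormal airflow-channel recordings: distress speech, feeble
# respiration, weightless respiration.
.abnormalTedSources <- c("Help:speech:Help me", "Ah:speech:Ah",
                         "Oy:speech:Oy", "feeble:breath:feeble",
                         "weightless:breath:weightless")
.normalTedSources <- c("YES:speech:YES", "NO:speech:NO",
                       "HowAreYou:speech:How are you",
                       "NoPains:speech:no pains no gains",
                       "breath:breath:normal")

# Airflow for one recording.  A spoken phrase is repeated over the
# recording (people speak in repetitions; distress calls especially), each
# repetition re-jittered from a derived seed.
.genTedFlow <- function(source, fs, seed, duration) {
  parts <- strsplit(source, ":", fixed = TRUE)[[1L]]
  if (parts[2L] == "speech") {
    nRep <- max(1L, floor(duration / 2.5))
    # whole number of samples per repetition keeps the grid uniform;
    # each repetition is >= 2.5 s, enough for any built-in template
    mSeg <- floor(floor(duration * fs) / nRep)
    segDur <- mSeg / fs
    repSeeds <- .spawnSeeds(seed, nRep)
    segs <- lapply(seq_len(nRep), function(k) {
      genSpeechFlow(speechTemplate(parts[3L]), fs = fs, seed = repSeeds[k],
                    duration = segDur)
    })
    t <- (seq_len(nRep * mSeg) - 1L) / fs
    flowSignal(t, unlist(lapply(segs, velocity)),
               unlist(lapply(segs, airTemperature)))
  } else {
    genBreathFlow(breathPattern(parts[3L]), duration = duration, fs = fs,
                  seed = seed)
  }
}

#' Generate a labelled multi-source fusion dataset
#'
#' Produces `4 * nPerCombo` recordings balanced over the four
#' (airflow state, heartbeat state) combinations.  Abnormal airflow
#' (`A-TEDS`) recordings draw from distress speech ("Help", "Ah", "Oy"),
#' feeble respiration or weightless respiration; normal recordings from
#' ordinary speech or tidal breathing.  Abnormal heartbeat (`A-HBS`) uses
#' the pain-stimulus pattern; normal draws from resting or exercising.
#' Airflow is run through [simulateResponse()] so every TED trace satisfies
#' the Seebeck identity, and the fused label applies the conjunction rule:
#' abnormal iff `A-TEDS` and `A-HBS`.
#'
#' @param nPerCombo recordings per combination (>= 1).
#' @param fs sampling rate, Hz.
#' @param seed root seed; per-recording child seeds are derived from it.
#' @param duration per-recording length, s.
#' @param plate a [DevicePlate-class] for the forward model.
#' @param fluid a [FluidProperties-class].
#' @return list of [LabeledRecording-class] objects.
#' @examples
#' ds <- genFusionDataset(2, seed = 11)
#' table(vapply(ds, fusedLabel, ""))
#' @export
genFusionDataset <- function(nPerCombo, fs = 100, seed = 1L, duration = 8,
                             plate = devicePlate(),
                             fluid = fluidProperties()) {
  nPerCombo <- .assertCount(nPerCombo, "nPerCombo", min = 1L)
  combos <- expand.grid(ted = c("normal", "A-TEDS"),
                        hb = c("normal", "A-HBS"),
                        stringsAsFactors = FALSE)
  total <- 4L * nPerCombo
  seeds <- .spawnSeeds(seed, 3L * total)
  recs <- vector("list", total)
  idx <- 0L
  for (ci in seq_len(nrow(combos))) {
    for (k in seq_len(nPerCombo)) {
      idx <- idx + 1L
      sFlow <- seeds[3L * idx - 2L]
      sPick <- seeds[3L * idx - 1L]
      sHb <- seeds[3L * idx]
      tedState <- combos$ted[ci]
      hbState <- combos$hb[ci]
      src <- .withSeed(sPick, {
        if (tedState == "A-TEDS") sample(.abnormalTedSources, 1L)
        else sample(.normalTedSources, 1L)
      })
      hbKind <- .withSeed(sPick + 1L, {
        if (hbState == "A-HBS") "abnormal"
        else sample(c("resting", "exercising"), 1L)
      })
      flow <- .genTedFlow(src, fs, sFlow, duration)
      ted <- simulateResponse(plate, fluid, flow,
                              Tupper0 = celsiusToKelvin(27))
      hb <- genHeartbeat(heartbeatPattern(hbKind), duration = duration,
                         fs = fs, seed = sHb)
      recs[[idx]] <- new("LabeledRecording", ted = ted, hb = hb,
                         tedState = tedState, hbState = hbState,
                         fusedLabel = fusionLabel(tedState, hbState),
                         meta = list(source = src, hbKind = hbKind,
                                     seeds = c(flow = sFlow, hb = sHb)))
    }
  }
  recs
}
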