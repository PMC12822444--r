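# Spectral feature extraction, cough detection and the alarm rule.

#' Short-time Fourier spectral features
#'
#' Computes a magnitude spectrogram (Hann window, one-sided spectrum) of a
#' uniformly sampled trace and a fixed-length log-magnitude feature vector
#' obtained by averaging the spectrogram onto an `nFreqBins x nTimeBins`
#' grid.  The fixed grid makes feature vectors comparable across traces of
#' different lengths.
#'
#' `voltageSpectrum(trace, ...)` is the [VoltageTrace-class] entry point;
#' `spectralFeatures()` also accepts a bare numeric series with `fs`.
#'
#' @param x a [VoltageTrace-class] or numeric vector.
#' @param fs sampling rate, Hz (ignored for a `VoltageTrace`, whose grid is
#'   used).
#' @param frameLen frame length, s (must exceed `hop`).
#' @param hop hop between frames, s (> 0).
#' @param nFreqBins,nTimeBins feature-grid size.
#' @param maxFreq upper edge of the pooled frequency axis, Hz; frequencies
#'   above it are excluded from the feature vector (the full spectrogram is
#'   kept in the magnitude slot).  Physiological airflow and PPG content
#'   sits well below 20 Hz.
#' @return a [SpectralFeatures-class].
#' @examples
#' x <- sin(2 * pi * 2 * seq(0, 5, by = 0.01))
#' sf <- spectralFeatures(x, fs = 100)
#' @export
setGeneric("spectralFeatures",
  function(x, fs = NULL, frameLen = 0.5, hop = 0.25, nFreqBins = 12L,
           nTimeBins = 8L, maxFreq = 20) standardGeneric("spectralFeatures"))

.stftFeatures <- function(x, fs, frameLen, hop, nFreqBins, nTimeBins,
                          maxFreq = 20) {
  if (!(frameLen > hop && hop > 0))
    stop("need frameLen > hop > 0", call. = FALSE)
  nWin <- round(frameLen * fs)
  nHop <- round(hop * fs)
  if (length(x) < nWin)
    stop("trace shorter than one frame", call. = FALSE)
  sg <- signal::specgram(x, n = nWin, Fs = fs,
                         window = signal::hanning(nWin),
                         overlap = nWin - nHop)
  mag <- abs(sg$S)
  # average-pool onto the fixed feature grid, frequency axis capped at
  # maxFreq (content-bearing band)
  keep <- which(sg$f <= maxFreq)
  if (length(keep) < nFreqBins) keep <- seq_len(min(nrow(mag), nFreqBins))
  sub <- mag[keep, , drop = FALSE]
  fIdx <- cut(seq_along(keep), nFreqBins, labels = FALSE)
  tIdx <- cut(seq_len(ncol(sub)), min(nTimeBins, ncol(sub)), labels = FALSE)
  pooled <- matrix(0, nFreqBins, nTimeBins)
  for (i in seq_len(nFreqBins)) {
    for (j in seq_len(nTimeBins)) {
      cols <- which(tIdx == j)
      if (length(cols))
        pooled[i, j] <- mean(sub[fIdx == i, cols, drop = FALSE])
    }
  }
  new("SpectralFeatures", frameTimes = as.numeric(sg$t),
      freqs = as.numeric(sg$f), magnitude = mag,
      vector = as.numeric(log10(pooled + 1e-12)))
}

#' @rdname spectralFeatures
setMethod("spectralFeatures", "numeric",
  function(x, fs, frameLen, hop, nFreqBins, nTimeBins, maxFreq) {
    .assertScalar(fs, "fs", positive = TRUE)
    .stftFeatures(x, fs, frameLen, hop, nFreqBins, nTimeBins, maxFreq)
  })

#' @rdname spectralFeatures
setMethod("spectralFeatures", "VoltageTrace",
  function(x, fs, frameLen, hop, nFreqBins, nTimeBins, maxFreq) {
    dt <- diff(x@t)
    if (max(dt) - min(dt) > 1e-9)
      stop("trace must be uniformly sampled", call. = FALSE)
    .stftFeatures(x@V, 1 / dt[1L], frameLen, hop, nFreqBins, nTimeBins,
                  maxFreq)
  })

#' @rdname spectralFeatures
#' @param trace a [VoltageTrace-class].
#' @export
voltageSpectrum <- function(trace, frameLen = 0.5, hop = 0.25,
                            nFreqBins = 12L, nTimeBins = 8L, maxFreq = 20) {
  stopifnot(is(trace, "VoltageTrace"))
  spectralFeatures(trace, frameLen = frameLen, hop = hop,
                   nFreqBins = nFreqBins, nTimeBins = nTimeBins,
                   maxFreq = maxFreq)
}

#' Cough detection thresholds
#'
#' Configuration for [detectCoughs()].  A cough's voltage rise scales with
#' the air--surface temperature contrast available when it strikes, so
#' intensity is banded on the \emph{normalized} rise
#' \eqn{\Delta V / (\alpha (T_{exh} - T_{pre}))} -- the fraction of the
#' available contrast the event converts -- which isolates the flow-speed
#' effect from the thermal state the event happens to start from.
#' `moderate` and `severe` are the lower band edges on that dimensionless
#' scale; `detect` is the minimum normalized rise that counts as an event
#' at all.  Defaults were calibrated once against the synthetic cough
#' generator's three intensity levels run through the default device model
#' and live here as configuration, not logic.
#'
#' @param detect minimum normalized rise to count as a cough event.
#' @param moderate lower edge of the moderate band (normalized).
#' @param severe lower edge of the severe band (normalized).
#' @param minSpacing minimum spacing between events, s.
#' @param exhaleT assumed exhaled-air temperature, K (human exhale is
#'   close to 38 C).
#' @return named list of thresholds.
#' @export
coughThresholds <- function(detect = 0.10, moderate = 0.245,
                            severe = 0.335, minSpacing = 0.45,
                            exhaleT = celsiusToKelvin(38)) {
  if (!(detect > 0 && moderate > detect && severe > moderate))
    stop("need 0 < detect < moderate < severe", call. = FALSE)
  list(detect = detect, moderate = moderate, severe = severe,
       minSpacing = minSpacing, exhaleT = exhaleT)
}

#' Detect cough events on a voltage trace
#'
#' A cough appears as a sharp voltage transient: a fast rise over a fraction
#' of a second followed by a slower convective decay.  Detection picks local
#' maxima of the voltage whose \emph{prominence} -- the rise above the
#' minimum over the preceding `lookback` seconds -- exceeds the detection
#' threshold, enforcing a minimum inter-event spacing; prominence rather
#' than a global baseline keeps the slowly decaying tail of one cough from
#' biasing the amplitude of the next.  Intensity is assigned to each event
#' by fixed amplitude bands from the thresholds configuration.
#'
#' @param trace a uniformly sampled [VoltageTrace-class] with a non-zero
#'   device Seebeck coefficient.
#' @param thresholds list from [coughThresholds()].
#' @param lookback prominence window, s.
#' @return data.frame with columns `time` (s), `peak_voltage` (V, rise
#'   above the preceding minimum), `norm_rise` (the dimensionless banded
#'   quantity) and `intensity` (factor mild/moderate/severe); zero rows
#'   when nothing exceeds the detection threshold.
#' @examples
#' fl <- genCoughTrain("severe", 3, window = 5, seed = 1)
#' tr <- simulateResponse(devicePlate(), fluidProperties(), fl, 293.15)
#' detectCoughs(tr)
#' @export
detectCoughs <- function(trace, thresholds = coughThresholds(),
                         lookback = 0.6) {
  stopifnot(is(trace, "VoltageTrace"))
  if (trace@alphaDevice == 0)
    stop("trace has a zero Seebeck coefficient; nothing to detect",
         call. = FALSE)
  dt <- diff(trace@t)
  if (length(dt) && max(dt) - min(dt) > 1e-9)
    stop("trace must be uniformly sampled", call. = FALSE)
  fs <- 1 / dt[1L]
  V <- trace@V
  nb <- max(1L, round(lookback * fs))
  idx <- seq_along(V)
  preMin <- vapply(idx, function(i) min(V[max(1L, i - nb):i]), 1.0)
  prom <- V - preMin
  # available contrast when the event started: alpha * (Texh - Tpre)
  Tpre <- preMin / trace@alphaDevice + trace@Tlower
  avail <- trace@alphaDevice * (thresholds$exhaleT - Tpre)
  norm <- ifelse(abs(avail) > 1e-12, prom / avail, 0)
  peaks <- .findPeaks(V, threshold = -Inf,
                      minGap = max(1L, round(thresholds$minSpacing * fs)))
  peaks <- peaks[norm[peaks] >= thresholds$detect]
  if (!length(peaks))
    return(data.frame(time = numeric(0), peak_voltage = numeric(0),
                      norm_rise = numeric(0),
                      intensity = factor(character(0),
                        levels = c("mild", "moderate", "severe"))))
  nv <- norm[peaks]
  intensity <- cut(nv, c(thresholds$detect, thresholds$moderate,
                         thresholds$severe, Inf),
                   labels = c("mild", "moderate", "severe"),
                   include.lowest = TRUE, right = FALSE)
  data.frame(time = trace@t[peaks], peak_voltage = prom[peaks],
             norm_rise = nv, intensity = intensity)
}

#' Severe-cough alarm rule
#'
#' The alarm fires when at least `minCount` \emph{severe} cough events fall
#' within any closed window of `window` seconds; non-severe events never
#' contribute.  Windows are anchored at each severe event.  The trigger
#' time is the timestamp of the `minCount`-th event of the first qualifying
#' window.
#'
#' @param events data.frame with columns `time` and `intensity` (as
#'   returned by [detectCoughs()]), time-sorted.
#' @param window window length, s.
#' @param minCount minimum number of severe events (default 3).
#' @return an [AlarmState-class].
#' @examples
#' ev <- data.frame(time = c(0.5, 2, 4.5),
#'                  intensity = rep("severe", 3))
#' alarmRule(ev)
#' @export
alarmRule <- function(events, window = 5, minCount = 3L) {
  minCount <- .assertCount(minCount, "minCount", min = 1L)
  .assertScalar(window, "window", positive = TRUE)
  if (!all(c("time", "intensity") %in% names(events)))
    stop("'events' needs columns time, intensity", call. = FALSE)
  if (is.unsorted(events$time))
    stop("'events' must be time-sorted", call. = FALSE)
  sev <- events[as.character(events$intensity) == "severe", , drop = FALSE]
  n <- nrow(sev)
  if (n >= minCount) {
    for (i in seq_len(n - minCount + 1L)) {
      jEnd <- i + minCount - 1L
      if (sev$time[jEnd] - sev$time[i] <= window) {
        contrib <- sev[sev$time >= sev$time[i] &
                       sev$time <= sev$time[i] + window, , drop = FALSE]
        return(new("AlarmState", active = TRUE,
                   triggerTime = sev$time[jEnd], events = contrib,
                   window = window, minCount = minCount))
      }
    }
  }
  new("AlarmState", active = FALSE, triggerTime = NA_real_,
      events = sev[0, , drop = FALSE], window = window, minCount = minCount)
}

#' Fused two-channel state label
#'
#' Applies the conjunction rule: the fused state is `"abnormal"` if and
#' only if the airflow channel is `"A-TEDS"` \emph{and} the heartbeat
#' channel is `"A-HBS"`; every other combination is `"normal"`.
#'
#' @param tedState `"normal"` or `"A-TEDS"`.
#' @param hbState `"normal"` or `"A-HBS"`.
#' @return `"normal"` or `"abnormal"`.
#' @examples
#' fusionLabel("A-TEDS", "A-HBS")  # "abnormal"
#' fusionLabel("normal", "A-HBS")  # "normal"
#' @export
fusionLabel <- function(tedState, hbState) {
  if (!tedState %in% c("normal", "A-TEDS"))
    stop("unknown tedState '", tedState, "'", call. = FALSE)
  if (!hbState %in% c("normal", "A-HBS"))
    stop("unknown hbState '", hbState, "'", call. = FALSE)
  if (tedState == "A-TEDS" && hbState == "A-HBS") "abnormal" else "normal"
}
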