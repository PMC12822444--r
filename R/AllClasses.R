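# S4 containers for the forward model, the leg solver, the synthetic
# generators and the classifiers.  Validity methods enforce the physical
# invariants (positivity, grid monotonicity, the Seebeck identity) so that
# malformed objects cannot circulate.

#' Thermophysical properties of the working fluid (air)
#'
#' Holds the constants entering the laminar flat-plate Nusselt correlation:
#' thermal conductivity \eqn{\kappa} (W/(m K)), density \eqn{\rho}
#' (kg/m\eqn{^3}), dynamic viscosity \eqn{\mu} (Pa s) and Prandtl number.
#'
#' @slot kappa thermal conductivity, W/(m K).
#' @slot rhoAir density, kg/m^3.
#' @slot mu dynamic viscosity, Pa s.
#' @slot Pr Prandtl number (dimensionless).
#' @seealso [fluidProperties()], [convectiveCoefficient()]
#' @export
setClass("FluidProperties",
  slots = c(kappa = "numeric", rhoAir = "numeric", mu = "numeric",
            Pr = "numeric"),
  validity = function(object) {
    for (s in c("kappa", "rhoAir", "mu", "Pr")) {
      v <- slot(object, s)
      if (length(v) != 1L || !is.finite(v) || v <= 0)
        return(sprintf("slot '%s' must be a single positive number", s))
    }
    TRUE
  })

#' Lumped model of the device's fluid-contact end
#'
#' The air-facing end of the thermoelectric device is treated as a lumped
#' thermal mass: characteristic length `L` sets the convective coefficient,
#' area `A` collects the flux, and `m * cp` is the heat capacity that turns
#' flux into a temperature rate.  `alphaDevice` is the effective Seebeck
#' coefficient of the series-connected device (V/K) and `Tlower` the fixed
#' skin-side temperature (K).
#'
#' @slot L characteristic length along the flow, m.
#' @slot A fluid-contact area, m^2.
#' @slot m contact-end mass, kg.
#' @slot cp specific heat of the contact end, J/(kg K).
#' @slot alphaDevice effective Seebeck coefficient of the device, V/K.
#' @slot Tlower lower (skin-side) surface temperature, K.
#' @seealso [devicePlate()], [simulateResponse()]
#' @export
setClass("DevicePlate",
  slots = c(L = "numeric", A = "numeric", m = "numeric", cp = "numeric",
            alphaDevice = "numeric", Tlower = "numeric"),
  validity = function(object) {
    for (s in c("L", "A", "m", "cp", "Tlower")) {
      v <- slot(object, s)
      if (length(v) != 1L || !is.finite(v) || v <= 0)
        return(sprintf("slot '%s' must be a single positive number", s))
    }
    if (length(object@alphaDevice) != 1L || !is.finite(object@alphaDevice))
      return("slot 'alphaDevice' must be a single finite number")
    TRUE
  })

#' Airflow signal: velocity and temperature versus time
#'
#' @slot t sample times, s (strictly increasing).
#' @slot v airflow speed normal to the plate at each sample, m/s (>= 0).
#' @slot Tair airflow temperature at each sample, K.
#' @seealso [flowSignal()], [genBreathFlow()], [simulateResponse()]
#' @export
setClass("FlowSignal",
  slots = c(t = "numeric", v = "numeric", Tair = "numeric"),
  validity = function(object) {
    n <- length(object@t)
    if (length(object@v) != n || length(object@Tair) != n)
      return("t, v and Tair must have equal length")
    if (n == 0L) return("signal must be non-empty")
    if (anyNA(object@t) || anyNA(object@v) || anyNA(object@Tair))
      return("NA values are not allowed")
    if (n > 1L && any(diff(object@t) <= 0))
      return("t must be strictly increasing")
    if (any(object@v < 0)) return("v must be >= 0 everywhere")
    TRUE
  })

#' Thermoelectric voltage trace
#'
#' Output of the forward model: upper-surface temperature, temperature
#' difference across the device and Seebeck voltage, sampled on the input
#' time grid.  Validity enforces the defining identities
#' `dT = Tupper - Tlower` and `V = alphaDevice * dT` exactly.
#'
#' @slot t sample times, s.
#' @slot Tupper upper-surface temperature, K.
#' @slot dT `Tupper - Tlower`, K.
#' @slot V output voltage, V.
#' @slot alphaDevice effective Seebeck coefficient used, V/K.
#' @slot Tlower lower-surface temperature used, K.
#' @seealso [stepResponse()], [simulateResponse()], [voltageSpectrum()]
#' @export
setClass("VoltageTrace",
  slots = c(t = "numeric", Tupper = "numeric", dT = "numeric", V = "numeric",
            alphaDevice = "numeric", Tlower = "numeric"),
  validity = function(object) {
    n <- length(object@t)
    if (length(object@Tupper) != n || length(object@dT) != n ||
        length(object@V) != n)
      return("t, Tupper, dT and V must have equal length")
    if (n == 0L) return("trace must be non-empty")
    if (n > 1L && any(diff(object@t) <= 0))
      return("t must be strictly increasing")
    if (!identical(object@dT, object@Tupper - object@Tlower))
      return("dT must equal Tupper - Tlower exactly")
    if (!identical(object@V, object@alphaDevice * object@dT))
      return("V must equal alphaDevice * dT exactly")
    TRUE
  })

#' Thermoelectric leg material constants
#'
#' @slot alpha Seebeck coefficient, V/K (negative for n-type).
#' @slot sigma electrical conductivity, S/m.
#' @slot kappa thermal conductivity of the leg, W/(m K).
#' @seealso [legMaterial()], [solveOpenCircuit()]
#' @export
setClass("LegMaterial",
  slots = c(alpha = "numeric", sigma = "numeric", kappa = "numeric"),
  validity = function(object) {
    if (length(object@alpha) != 1L || !is.finite(object@alpha))
      return("alpha must be a single finite number")
    if (length(object@sigma) != 1L || object@sigma <= 0)
      return("sigma must be a single positive number")
    if (length(object@kappa) != 1L || object@kappa <= 0)
      return("kappa must be a single positive number")
    TRUE
  })

#' Thermoelectric leg geometry and discretization
#'
#' @slot length leg length (hot-to-cold), m.
#' @slot crossSection cross-sectional area, m^2.
#' @slot nNodes number of finite-difference nodes (>= 3).
#' @seealso [legGeometry()]
#' @export
setClass("LegGeometry",
  slots = c(length = "numeric", crossSection = "numeric", nNodes = "integer"),
  validity = function(object) {
    if (length(object@length) != 1L || object@length <= 0)
      return("length must be a single positive number")
    if (length(object@crossSection) != 1L || object@crossSection <= 0)
      return("crossSection must be a single positive number")
    if (length(object@nNodes) != 1L || object@nNodes < 3L)
      return("nNodes must be an integer >= 3")
    TRUE
  })

#' Solved one-dimensional thermoelectric leg state
#'
#' @slot x node positions from the lower (skin) face, m.
#' @slot T temperature profile, K.
#' @slot E electric potential profile, V (zero at x = 0).
#' @slot j current density, A/m^2 (uniform in 1-D steady state).
#' @slot Vleg terminal voltage, V.
#' @slot iterations fixed-point iterations used (0 for open circuit).
#' @export
setClass("LegSolution",
  slots = c(x = "numeric", T = "numeric", E = "numeric", j = "numeric",
            Vleg = "numeric", iterations = "integer"),
  validity = function(object) {
    n <- length(object@x)
    if (length(object@T) != n || length(object@E) != n)
      return("x, T and E must have equal length")
    if (length(object@j) != 1L || length(object@Vleg) != 1L)
      return("j and Vleg must be scalars")
    TRUE
  })

#' Breathing pattern parameters
#'
#' `kind` selects a physiological regime: `normal` tidal breathing (peak
#' exhale velocity within the measured 0.5--2.5 m/s range), `feeble`
#' (flow-restricted, strongly reduced peak velocity), `weightless` (a brief
#' near-zero-flow gap followed by an exhale transient each cycle, emulating a
#' short free-fall) and `cough` (tidal breathing with superimposed cough
#' transients).
#'
#' @slot kind one of `"normal"`, `"feeble"`, `"weightless"`, `"cough"`.
#' @slot rate breaths per minute.
#' @slot peakExhaleV peak exhale velocity, m/s.
#' @slot exhaleT exhaled-air temperature, K (default 311.15 K = 38 C).
#' @slot ambientT ambient/inhaled-air temperature, K.
#' @seealso [breathPattern()], [genBreathFlow()]
#' @export
setClass("BreathPattern",
  slots = c(kind = "character", rate = "numeric", peakExhaleV = "numeric",
            exhaleT = "numeric", ambientT = "numeric"),
  validity = function(object) {
    if (!object@kind %in% c("normal", "feeble", "weightless", "cough"))
      return("kind must be one of normal/feeble/weightless/cough")
    if (object@rate <= 0) return("rate must be > 0")
    if (object@peakExhaleV <= 0) return("peakExhaleV must be > 0")
    if (object@kind == "normal" &&
        (object@peakExhaleV < 0.5 || object@peakExhaleV > 2.5))
      return("normal breathing peak velocity must lie in [0.5, 2.5] m/s")
    if (object@exhaleT <= 0 || object@ambientT <= 0)
      return("temperatures must be positive (kelvin)")
    TRUE
  })

#' Speech airflow template
#'
#' A phrase is a time-ordered, non-overlapping set of airflow bursts, one per
#' syllable group; `bursts` is a data.frame with columns `onset` (s),
#' `duration` (s) and `peak` (m/s).
#'
#' @slot label phrase label.
#' @slot bursts data.frame of burst parameters.
#' @seealso [speechTemplate()], [genSpeechFlow()]
#' @export
setClass("SpeechTemplate",
  slots = c(label = "character", bursts = "data.frame"),
  validity = function(object) {
    b <- object@bursts
    if (!all(c("onset", "duration", "peak") %in% names(b)))
      return("bursts needs columns onset, duration, peak")
    if (nrow(b) < 1L) return("template needs at least one burst")
    if (any(b$duration <= 0) || any(b$peak <= 0) || any(b$onset < 0))
      return("burst onsets must be >= 0, durations and peaks > 0")
    if (is.unsorted(b$onset, strictly = TRUE))
      return("bursts must be time-ordered")
    if (nrow(b) > 1L &&
        any(b$onset[-1L] < (b$onset + b$duration)[-nrow(b)]))
      return("bursts must not overlap")
    TRUE
  })

#' Heartbeat (PPG-like) pattern parameters
#'
#' @slot kind one of `"resting"`, `"exercising"`, `"abnormal"`.
#' @slot rate beats per minute.
#' @slot systolicAmp systolic peak amplitude (arbitrary PPG units).
#' @slot dicroticAmp dicrotic-wave amplitude.
#' @slot systolicWidth,dicroticWidth Gaussian pulse widths, s.
#' @slot jitter beat-interval coefficient of variation.
#' @seealso [heartbeatPattern()], [genHeartbeat()]
#' @export
setClass("HeartbeatPattern",
  slots = c(kind = "character", rate = "numeric", systolicAmp = "numeric",
            dicroticAmp = "numeric", systolicWidth = "numeric",
            dicroticWidth = "numeric", jitter = "numeric"),
  validity = function(object) {
    if (!object@kind %in% c("resting", "exercising", "abnormal"))
      return("kind must be one of resting/exercising/abnormal")
    if (object@rate <= 0) return("rate must be > 0")
    if (object@systolicAmp <= 0 || object@dicroticAmp <= 0)
      return("amplitudes must be > 0")
    if (object@jitter < 0) return("jitter must be >= 0")
    TRUE
  })

#' Labelled multi-source recording
#'
#' Pairs a device voltage trace with a PPG-like heartbeat trace and carries
#' the per-channel states and the fused label.  The fused label follows the
#' conjunction rule: `abnormal` if and only if the airflow channel is
#' `A-TEDS` and the heartbeat channel is `A-HBS`.
#'
#' @slot ted [VoltageTrace-class] from the airflow channel.
#' @slot hb data.frame with columns `time_s`, `value` (PPG-like amplitude).
#' @slot tedState `"normal"` or `"A-TEDS"`.
#' @slot hbState `"normal"` or `"A-HBS"`.
#' @slot fusedLabel `"normal"` or `"abnormal"`.
#' @slot meta list of generator provenance (source kind, seed).
#' @seealso [genFusionDataset()], [fusionLabel()]
#' @export
setClass("LabeledRecording",
  slots = c(ted = "VoltageTrace", hb = "data.frame", tedState = "character",
            hbState = "character", fusedLabel = "character", meta = "list"),
  validity = function(object) {
    if (!object@tedState %in% c("normal", "A-TEDS"))
      return("tedState must be 'normal' or 'A-TEDS'")
    if (!object@hbState %in% c("normal", "A-HBS"))
      return("hbState must be 'normal' or 'A-HBS'")
    want <- if (object@tedState == "A-TEDS" && object@hbState == "A-HBS")
      "abnormal" else "normal"
    if (!identical(object@fusedLabel, want))
      return("fusedLabel must follow the A-TEDS & A-HBS conjunction rule")
    if (!all(c("time_s", "value") %in% names(object@hb)))
      return("hb needs columns time_s, value")
    TRUE
  })

#' Short-time spectral features of a trace
#'
#' @slot frameTimes frame centre times, s.
#' @slot freqs frequency bins, Hz.
#' @slot magnitude frequency x time non-negative magnitude matrix.
#' @slot vector fixed-length log-magnitude feature vector.
#' @seealso [voltageSpectrum()]
#' @export
setClass("SpectralFeatures",
  slots = c(frameTimes = "numeric", freqs = "numeric",
            magnitude = "matrix", vector = "numeric"),
  validity = function(object) {
    if (any(object@magnitude < 0)) return("magnitude must be >= 0")
    if (nrow(object@magnitude) != length(object@freqs))
      return("magnitude rows must match freqs")
    if (ncol(object@magnitude) != length(object@frameTimes))
      return("magnitude columns must match frameTimes")
    TRUE
  })

#' Cough alarm state
#'
#' @slot active whether the alarm fired.
#' @slot triggerTime time of the triggering severe event, s; `NA` when
#'   inactive.
#' @slot events data.frame of the contributing severe cough events.
#' @slot window,minCount the rule parameters (default 5 s, 3 events).
#' @seealso [alarmRule()]
#' @export
setClass("AlarmState",
  slots = c(active = "logical", triggerTime = "numeric",
            events = "data.frame", window = "numeric", minCount = "integer"),
  validity = function(object) {
    if (length(object@active) != 1L) return("active must be a single logical")
    if (object@active && nrow(object@events) < object@minCount)
      return("an active alarm needs >= minCount contributing severe events")
    if (object@active &&
        diff(range(object@events$time)) > object@window + 1e-9)
      return("contributing events must span <= the rule window")
    TRUE
  })

#' Classifier evaluation report
#'
#' @slot accuracy held-out accuracy (fraction).
#' @slot confusion label x label count matrix (rows = truth).
#' @slot perClassRecall named vector of per-class recalls.
#' @slot meta list: seed, hyperparameters, split sizes.
#' @export
setClass("ClassifierReport",
  slots = c(accuracy = "numeric", confusion = "matrix",
            perClassRecall = "numeric", meta = "list"),
  validity = function(object) {
    if (object@accuracy < 0 || object@accuracy > 1)
      return("accuracy must be in [0, 1]")
    tot <- sum(object@confusion)
    if (tot > 0 &&
        abs(sum(diag(object@confusion)) / tot - object@accuracy) > 1e-12)
      return("accuracy must equal trace(confusion)/total")
    TRUE
  })
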