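# User-facing constructors.  Defaults encode the study conditions: air at
# roughly 20 C, the published p/n leg constants, and a mask-scale contact end.

#' Construct air (fluid) properties
#'
#' Defaults describe air near 20 C: conductivity 0.0257 W/(m K), density
#' 1.2 kg/m^3, viscosity 1.8e-5 Pa s, Prandtl number 0.71.
#'
#' @param kappa thermal conductivity, W/(m K).
#' @param rhoAir density, kg/m^3.
#' @param mu dynamic viscosity, Pa s.
#' @param Pr Prandtl number.
#' @return a [FluidProperties-class] object.
#' @examples
#' air <- fluidProperties()
#' convectiveCoefficient(air, L = 0.01, v = 1)
#' @export
fluidProperties <- function(kappa = 0.0257, rhoAir = 1.2, mu = 1.8e-5,
                            Pr = 0.71) {
  new("FluidProperties", kappa = kappa, rhoAir = rhoAir, mu = mu, Pr = Pr)
}

#' Construct the lumped fluid-contact end of the device
#'
#' Defaults describe a mask-mounted device: a 1 cm characteristic length,
#' 1 cm^2 contact area, a 10 mg effective contact-end mass at
#' c_p = 500 J/(kg K) (thin fabric-electrode layer), a 100-couple effective
#' Seebeck coefficient of 41.25 mV/K and a skin-side temperature of 32 C.
#' All are overridable; none is tied to the published hardware, whose couple
#' count is not public.
#'
#' @param L characteristic length, m.
#' @param A fluid-contact area, m^2.
#' @param m contact-end mass, kg.
#' @param cp specific heat, J/(kg K).
#' @param alphaDevice effective device Seebeck coefficient, V/K.
#' @param Tlower lower-surface temperature, K.
#' @return a [DevicePlate-class] object.
#' @export
devicePlate <- function(L = 0.01, A = 1e-4, m = 1e-5, cp = 500,
                        alphaDevice = 100 * 412.5e-6,
                        Tlower = celsiusToKelvin(32)) {
  new("DevicePlate", L = L, A = A, m = m, cp = cp,
      alphaDevice = alphaDevice, Tlower = Tlower)
}

#' Construct an airflow signal
#'
#' @param t sample times, s (strictly increasing).
#' @param v airflow speed, m/s (recycled if scalar).
#' @param Tair airflow temperature, K (recycled if scalar).
#' @return a [FlowSignal-class] object.
#' @examples
#' flowSignal(t = seq(0, 1, 0.01), v = 1, Tair = 311.15)
#' @export
flowSignal <- function(t, v, Tair) {
  n <- length(t)
  if (length(v) == 1L) v <- rep(v, n)
  if (length(Tair) == 1L) Tair <- rep(Tair, n)
  new("FlowSignal", t = as.numeric(t), v = as.numeric(v),
      Tair = as.numeric(Tair))
}

#' Construct a voltage trace from an upper-surface temperature series
#'
#' Derives `dT = Tupper - Tlower` and `V = alphaDevice * dT` from the
#' plate's constants so the class invariants hold by construction.
#'
#' @param t sample times, s.
#' @param Tupper upper-surface temperatures, K.
#' @param plate a [DevicePlate-class] supplying `alphaDevice` and `Tlower`.
#' @return a [VoltageTrace-class].
#' @export
voltageTrace <- function(t, Tupper, plate) {
  stopifnot(is(plate, "DevicePlate"))
  dT <- Tupper - plate@Tlower
  new("VoltageTrace", t = as.numeric(t), Tupper = as.numeric(Tupper),
      dT = as.numeric(dT), V = as.numeric(plate@alphaDevice * dT),
      alphaDevice = plate@alphaDevice, Tlower = plate@Tlower)
}

.makeVoltageTrace <- voltageTrace

#' Construct thermoelectric leg material constants
#'
#' Defaults are the published p-type constants; use `legMaterialN()` for the
#' n-type leg.
#'
#' @param alpha Seebeck coefficient, V/K.
#' @param sigma electrical conductivity, S/m.
#' @param kappa thermal conductivity, W/(m K).
#' @return a [LegMaterial-class] object.
#' @export
legMaterial <- function(alpha = 202.5e-6, sigma = 9.25e5, kappa = 0.927) {
  new("LegMaterial", alpha = alpha, sigma = sigma, kappa = kappa)
}

#' @rdname legMaterial
#' @export
legMaterialN <- function(alpha = -210e-6, sigma = 10e5, kappa = 0.965) {
  new("LegMaterial", alpha = alpha, sigma = sigma, kappa = kappa)
}

#' Construct leg geometry
#'
#' Defaults are a 1.4 mm x 1.4 mm x 2.5 mm cuboid leg.
#'
#' @param length leg length, m.
#' @param crossSection cross-sectional area, m^2.
#' @param nNodes finite-difference nodes (>= 3).
#' @return a [LegGeometry-class] object.
#' @export
legGeometry <- function(length = 2.5e-3, crossSection = 1.4e-3 * 1.4e-3,
                        nNodes = 101L) {
  new("LegGeometry", length = length, crossSection = crossSection,
      nNodes = as.integer(nNodes))
}

#' Construct a breathing pattern
#'
#' Kind-specific defaults: `normal` 15 breaths/min at 1.8 m/s peak exhale
#' (within the measured 0.5--2.5 m/s range); `feeble` 20 breaths/min at
#' 0.35 m/s (flow restriction); `weightless` 15 breaths/min with a 0.5 s
#' near-zero-flow gap then an exhale transient; `cough` tidal breathing with
#' cough transients.  Exhaled air is 38 C, ambient 20 C.
#'
#' @param kind `"normal"`, `"feeble"`, `"weightless"` or `"cough"`.
#' @param rate breaths per minute (default per kind).
#' @param peakExhaleV peak exhale velocity, m/s (default per kind).
#' @param exhaleT exhaled-air temperature, K.
#' @param ambientT ambient temperature, K.
#' @return a [BreathPattern-class] object.
#' @export
breathPattern <- function(kind = c("normal", "feeble", "weightless", "cough"),
                          rate = NULL, peakExhaleV = NULL,
                          exhaleT = celsiusToKelvin(38),
                          ambientT = celsiusToKelvin(20)) {
  kind <- match.arg(kind)
  defRate <- c(normal = 15, feeble = 20, weightless = 15, cough = 12)[[kind]]
  defPeak <- c(normal = 1.8, feeble = 0.35, weightless = 1.2,
               cough = 1.5)[[kind]]
  new("BreathPattern", kind = kind,
      rate = if (is.null(rate)) defRate else rate,
      peakExhaleV = if (is.null(peakExhaleV)) defPeak else peakExhaleV,
      exhaleT = exhaleT, ambientT = ambientT)
}

# Burst tables for the built-in phrases.  The five canonical classes carry
# distinct burst counts and timings (one airflow burst per syllable group);
# the extra phrases are available as additional templates.
.speechBursts <- list(
  "HELP" = data.frame(onset = 0.40, duration = 0.45, peak = 2.3),
  "YES"  = data.frame(onset = 0.40, duration = 0.30, peak = 1.5),
  "NO"   = data.frame(onset = 0.40, duration = 0.20, peak = 1.0),
  "no pains no gains" = data.frame(
    onset = c(0.20, 0.75, 1.35, 1.90),
    duration = c(0.28, 0.30, 0.28, 0.32),
    peak = c(1.4, 1.6, 1.3, 1.5)),
  "How are you" = data.frame(
    onset = c(0.30, 0.85, 1.45),
    duration = c(0.25, 0.22, 0.30),
    peak = c(1.1, 1.5, 1.3)),
  # extra templates; the distress shouts ("Help me", "Ah", "Oy") are
  # voiced at raised airflow, as shouting is
  "A" = data.frame(onset = 0.40, duration = 0.18, peak = 0.9),
  "Good idea" = data.frame(onset = c(0.35, 0.95),
                           duration = c(0.22, 0.40), peak = c(1.3, 1.8)),
  "Help me" = data.frame(onset = c(0.35, 0.95),
                         duration = c(0.40, 0.25), peak = c(2.9, 1.9)),
  "Ah" = data.frame(onset = 0.35, duration = 0.50, peak = 3.1),
  "Oy" = data.frame(onset = c(0.35, 1.10), duration = c(0.35, 0.35),
                    peak = c(2.8, 2.6)))

#' Built-in and custom speech airflow templates
#'
#' `speechTemplate(label)` returns a built-in phrase template; pass `bursts`
#' to define a custom phrase.  `speechLabels()` lists the five canonical
#' classes; `speechLabels(extra = TRUE)` includes the additional phrases.
#'
#' @param label phrase label.
#' @param bursts optional data.frame with columns `onset`, `duration`,
#'   `peak` overriding the built-in table.
#' @return a [SpeechTemplate-class] object.
#' @examples
#' speechTemplate("no pains no gains")
#' speechLabels()
#' @export
speechTemplate <- function(label, bursts = NULL) {
  if (is.null(bursts)) {
    if (!label %in% names(.speechBursts))
      stop("unknown speech label '", label, "'; see speechLabels(extra=TRUE)",
           call. = FALSE)
    bursts <- .speechBursts[[label]]
  }
  new("SpeechTemplate", label = label, bursts = bursts)
}

#' @rdname speechTemplate
#' @param extra include the additional (non-canonical) phrases.
#' @export
speechLabels <- function(extra = FALSE) {
  canon <- c("HELP", "YES", "NO", "no pains no gains", "How are you")
  if (extra) names(.speechBursts) else canon
}

#' Construct a heartbeat (PPG-like) pattern
#'
#' Kind defaults: `resting` 60 bpm with 3\% beat-interval jitter,
#' `exercising` 120 bpm with 5\% jitter, `abnormal` (pain-stimulus
#' surrogate) 75 bpm with 15\% jitter plus a transient amplitude dip.
#'
#' @param kind `"resting"`, `"exercising"` or `"abnormal"`.
#' @param rate beats per minute (default per kind).
#' @param systolicAmp,dicroticAmp pulse amplitudes.
#' @param systolicWidth,dicroticWidth Gaussian widths, s.
#' @param jitter beat-interval coefficient of variation (default per kind).
#' @return a [HeartbeatPattern-class] object.
#' @export
heartbeatPattern <- function(kind = c("resting", "exercising", "abnormal"),
                             rate = NULL, systolicAmp = 1, dicroticAmp = 0.35,
                             systolicWidth = 0.05, dicroticWidth = 0.07,
                             jitter = NULL) {
  kind <- match.arg(kind)
  defRate <- c(resting = 60, exercising = 120, abnormal = 75)[[kind]]
  defJit <- c(resting = 0.03, exercising = 0.05, abnormal = 0.15)[[kind]]
  new("HeartbeatPattern", kind = kind,
      rate = if (is.null(rate)) defRate else rate,
      systolicAmp = systolicAmp, dicroticAmp = dicroticAmp,
      systolicWidth = systolicWidth, dicroticWidth = dicroticWidth,
      jitter = if (is.null(jitter)) defJit else jitter)
}
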