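# Accessor generics and show methods.  Slot access from user code should go
# through these.

#' Accessors for signal and trace objects
#'
#' `times()`, `velocity()`, `airTemperature()` read a [FlowSignal-class];
#' `times()`, `upperTemperature()`, `deltaT()`, `voltage()` read a
#' [VoltageTrace-class]; `featureVector()` reads a
#' [SpectralFeatures-class]; `accuracy()`, `confusionMatrix()` read a
#' [ClassifierReport-class]; `fusedLabel()` reads a
#' [LabeledRecording-class].
#'
#' @param x the object.
#' @return the corresponding numeric vector / matrix / character scalar.
#' @name accessors
#' @examples
#' fl <- flowSignal(seq(0, 1, 0.1), v = 1, Tair = 311.15)
#' head(velocity(fl))
NULL

#' @rdname accessors
#' @export
setGeneric("times", function(x) standardGeneric("times"))
#' @rdname accessors
#' @export
setGeneric("velocity", function(x) standardGeneric("velocity"))
#' @rdname accessors
#' @export
setGeneric("airTemperature", function(x) standardGeneric("airTemperature"))
#' @rdname accessors
#' @export
setGeneric("upperTemperature", function(x) standardGeneric("upperTemperature"))
#' @rdname accessors
#' @export
setGeneric("deltaT", function(x) standardGeneric("deltaT"))
#' @rdname accessors
#' @export
setGeneric("voltage", function(x) standardGeneric("voltage"))
#' @rdname accessors
#' @export
setGeneric("featureVector", function(x) standardGeneric("featureVector"))
#' @rdname accessors
#' @export
setGeneric("accuracy", function(x) standardGeneric("accuracy"))
#' @rdname accessors
#' @export
setGeneric("confusionMatrix", function(x) standardGeneric("confusionMatrix"))
#' @rdname accessors
#' @export
setGeneric("fusedLabel", function(x) standardGeneric("fusedLabel"))

#' @rdname accessors
setMethod("times", "FlowSignal", function(x) x@t)
#' @rdname accessors
setMethod("times", "VoltageTrace", function(x) x@t)
#' @rdname accessors
setMethod("velocity", "FlowSignal", function(x) x@v)
#' @rdname accessors
setMethod("airTemperature", "FlowSignal", function(x) x@Tair)
#' @rdname accessors
setMethod("upperTemperature", "VoltageTrace", function(x) x@Tupper)
#' @rdname accessors
setMethod("deltaT", "VoltageTrace", function(x) x@dT)
#' @rdname accessors
setMethod("voltage", "VoltageTrace", function(x) x@V)
#' @rdname accessors
setMethod("featureVector", "SpectralFeatures", function(x) x@vector)
#' @rdname accessors
setMethod("accuracy", "ClassifierReport", function(x) x@accuracy)
#' @rdname accessors
setMethod("confusionMatrix", "ClassifierReport", function(x) x@confusion)
#' @rdname accessors
setMethod("fusedLabel", "LabeledRecording", function(x) x@fusedLabel)

setMethod("show", "FluidProperties", function(object) {
  cat("FluidProperties: kappa =", object@kappa, "W/(m K), rho =",
      object@rhoAir, "kg/m^3, mu =", object@mu, "Pa s, Pr =", object@Pr, "\n")
})

setMethod("show", "DevicePlate", function(object) {
  cat("DevicePlate: L =", object@L, "m, A =", object@A, "m^2, m =",
      object@m, "kg, cp =", object@cp, "J/(kg K)\n",
      " alphaDevice =", object@alphaDevice * 1e3, "mV/K, Tlower =",
      object@Tlower, "K\n")
})

setMethod("show", "FlowSignal", function(object) {
  n <- length(object@t)
  cat(sprintf(
    "FlowSignal: %d samples over %.3g s; v in [%.3g, %.3g] m/s; Tair in [%.5g, %.5g] K\n",
    n, diff(range(object@t)), min(object@v), max(object@v),
    min(object@Tair), max(object@Tair)))
})

setMethod("show", "VoltageTrace", function(object) {
  cat(sprintf(
    "VoltageTrace: %d samples over %.3g s; V in [%.4g, %.4g] mV (alpha = %.4g mV/K, Tlower = %.5g K)\n",
    length(object@t), diff(range(object@t)), 1e3 * min(object@V),
    1e3 * max(object@V), 1e3 * object@alphaDevice, object@Tlower))
})

setMethod("show", "LegSolution", function(object) {
  cat(sprintf(
    "LegSolution: %d nodes; T_upper = %.6g K, dT = %.4g K, j = %.4g A/m^2, Vleg = %.4g mV\n",
    length(object@x), object@T[length(object@T)],
    object@T[length(object@T)] - object@T[1L], object@j, 1e3 * object@Vleg))
})

setMethod("show", "LabeledRecording", function(object) {
  cat(sprintf(
    "LabeledRecording: ted=%s hb=%s -> %s (%d TED samples, %d HB samples)\n",
    object@tedState, object@hbState, object@fusedLabel,
    length(object@ted@t), nrow(object@hb)))
})

setMethod("show", "AlarmState", function(object) {
  if (object@active)
    cat(sprintf("AlarmState: ACTIVE at t = %.3g s (%d contributing severe events)\n",
                object@triggerTime, nrow(object@events)))
  else cat("AlarmState: inactive\n")
})

setMethod("show", "ClassifierReport", function(object) {
  cat(sprintf("ClassifierReport: accuracy %.1f%% on %d held-out samples\n",
              100 * object@accuracy, sum(object@confusion)))
  print(object@confusion)
})

setMethod("show", "SpectralFeatures", function(object) {
  cat(sprintf(
    "SpectralFeatures: %d freq bins x %d frames; feature vector length %d\n",
    nrow(object@magnitude), ncol(object@magnitude), length(object@vector)))
})
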