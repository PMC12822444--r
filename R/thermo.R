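# Airflow-thermoelectric forward model.
#
# Physics: laminar flow over the flat air-facing surface gives an average
# convective coefficient via the flat-plate Nusselt correlation
#     Nu = 0.664 Re^(1/2) Pr^(1/3),  h = kappa Nu / L,  Re = rho v L / mu,
# the surface is a lumped thermal mass obeying Newton cooling
#     m cp dTupper/dt = h A (Tair - Tupper),
# and the device reads out V = alpha (Tupper - Tlower) by the Seebeck effect.
# With constant v and Tair the ODE has the closed form
#     Tupper(t) = Tair - (Tair - Tupper(0)) exp(-f t),  f = h A / (m cp).

#' Laminar flat-plate convective heat-transfer coefficient
#'
#' Computes \eqn{h = 0.664 (\kappa/L) Re^{1/2} Pr^{1/3}} with
#' \eqn{Re = \rho v L / \mu}.  Vectorized over `v`.  `h(0) = 0`: the model
#' is forced convection only, with no natural-convection floor.
#'
#' @param fluid a [FluidProperties-class] object.
#' @param L characteristic length along the flow, m (> 0).
#' @param v airflow speed, m/s (>= 0, vectorized).
#' @return convective coefficient(s) h, W/(m^2 K).
#' @examples
#' convectiveCoefficient(fluidProperties(), L = 0.01, v = 1)  # ~39.3
#' @export
convectiveCoefficient <- function(fluid, L, v) {
  stopifnot(is(fluid, "FluidProperties"))
  .assertScalar(L, "L", positive = TRUE)
  if (!is.numeric(v) || any(!is.finite(v)) || any(v < 0))
    stop("'v' must be finite and >= 0", call. = FALSE)
  Re <- fluid@rhoAir * v * L / fluid@mu
  0.664 * (fluid@kappa / L) * sqrt(Re) * fluid@Pr^(1 / 3)
}

#' Thermal response rate of the contact end
#'
#' \eqn{f = h A / (m c_p)}, the inverse time constant of the first-order
#' surface-temperature response.
#'
#' @param h convective coefficient, W/(m^2 K) (>= 0, vectorized).
#' @param plate a [DevicePlate-class] object.
#' @return rate f, 1/s.
#' @export
thermalRate <- function(h, plate) {
  stopifnot(is(plate, "DevicePlate"))
  if (any(h < 0)) stop("'h' must be >= 0", call. = FALSE)
  h * plate@A / (plate@m * plate@cp)
}

#' Convective heat flux into the contact end
#'
#' \eqn{q = h A (T_{air} - T_{upper})}: positive during a warm exhale
#' (airflow heats the device), negative during a cool inhale.
#'
#' @param h convective coefficient, W/(m^2 K).
#' @param A contact area, m^2 (> 0).
#' @param Tair airflow temperature, K.
#' @param Tupper upper-surface temperature, K.
#' @return heat flow q, W.
#' @export
convectiveFlux <- function(h, A, Tair, Tupper) {
  .assertScalar(A, "A", positive = TRUE)
  if (any(h < 0)) stop("'h' must be >= 0", call. = FALSE)
  h * A * (Tair - Tupper)
}

#' Seebeck voltage from a temperature difference
#'
#' \eqn{V = \alpha \Delta T}.  Linear and odd in `dT`.
#'
#' @param alphaDevice effective Seebeck coefficient, V/K.
#' @param dT temperature difference, K (vectorized).
#' @return voltage, V.
#' @examples
#' voltageFromDT(412.5e-6, 30)  # one p/n couple at dT = 30 K: 12.375 mV
#' @export
voltageFromDT <- function(alphaDevice, dT) {
  .assertScalar(alphaDevice, "alphaDevice")
  alphaDevice * dT
}

#' Closed-form voltage response to a constant airflow step
#'
#' For constant speed `vConst` and air temperature `Tair`, the surface
#' temperature follows
#' \eqn{T_{upper}(t) = T_{air} - (T_{air} - T_{upper}(0)) e^{-f t}} and the
#' voltage \eqn{V = \alpha (T_{upper} - T_{lower})}, approaching
#' \eqn{\alpha (T_{air} - T_{lower})} monotonically.  Time is measured from
#' zero: `Tupper0` is the surface temperature at t = 0.
#'
#' @param plate a [DevicePlate-class].
#' @param fluid a [FluidProperties-class].
#' @param vConst constant airflow speed, m/s (>= 0).
#' @param Tair constant airflow temperature, K.
#' @param Tupper0 initial upper-surface temperature, K.
#' @param times evaluation times, s (non-empty, non-negative, increasing).
#' @return a [VoltageTrace-class].
#' @examples
#' tr <- stepResponse(devicePlate(), fluidProperties(), vConst = 1,
#'                    Tair = 311.15, Tupper0 = 293.15, times = seq(0, 10, 0.1))
#' voltage(tr)[1:3]
#' @export
stepResponse <- function(plate, fluid, vConst, Tair, Tupper0, times) {
  stopifnot(is(plate, "DevicePlate"), is(fluid, "FluidProperties"))
  .assertScalar(vConst, "vConst", nonneg = TRUE)
  .assertScalar(Tair, "Tair", positive = TRUE)
  .assertScalar(Tupper0, "Tupper0", positive = TRUE)
  if (!length(times)) stop("'times' must be non-empty", call. = FALSE)
  if (any(times < 0) || (length(times) > 1L && any(diff(times) <= 0)))
    stop("'times' must be non-negative and strictly increasing", call. = FALSE)
  f <- thermalRate(convectiveCoefficient(fluid, plate@L, vConst), plate)
  Tupper <- Tair - (Tair - Tupper0) * exp(-f * times)
  .makeVoltageTrace(times, Tupper, plate)
}

#' Simulate the voltage response to a time-varying airflow
#'
#' Integrates \eqn{dT_{upper}/dt = f(v)\,(T_{air} - T_{upper})} treating
#' `v` and `Tair` as piecewise constant over each sample interval and
#' applying the exact exponential update per interval, so the scheme is
#' unconditionally stable and reduces to [stepResponse()] exactly for
#' constant inputs.  The surface temperature equals `Tupper0` at the first
#' sample.
#'
#' @param plate a [DevicePlate-class].
#' @param fluid a [FluidProperties-class].
#' @param flow a [FlowSignal-class].
#' @param Tupper0 initial upper-surface temperature, K.
#' @return a [VoltageTrace-class] sampled at `times(flow)`.
#' @examples
#' fl <- genBreathFlow(breathPattern("normal"), duration = 10, seed = 1)
#' tr <- simulateResponse(devicePlate(), fluidProperties(), fl,
#'                        Tupper0 = celsiusToKelvin(27))
#' @export
simulateResponse <- function(plate, fluid, flow, Tupper0) {
  stopifnot(is(plate, "DevicePlate"), is(fluid, "FluidProperties"),
            is(flow, "FlowSignal"))
  .assertScalar(Tupper0, "Tupper0", positive = TRUE)
  t <- flow@t
  n <- length(t)
  f <- thermalRate(convectiveCoefficient(fluid, plate@L, flow@v), plate)
  Tupper <- numeric(n)
  Tupper[1L] <- Tupper0
  if (n > 1L) {
    dt <- diff(t)
    decay <- exp(-f[-n] * dt)
    Ta <- flow@Tair
    for (i in seq_len(n - 1L)) {
      Tupper[i + 1L] <- Ta[i] + (Tupper[i] - Ta[i]) * decay[i]
    }
  }
  .makeVoltageTrace(t, Tupper, plate)
}

#' Steady-state velocity sweep of the lumped device
#'
#' For each velocity, reports the steady-state temperature difference
#' `Tair - Tlower`-driven surface offset and the corresponding open-circuit
#' voltage of the lumped model (the surface reaches `Tair` as t -> infinity
#' whenever v > 0, so the lumped steady state is velocity-independent; this
#' helper instead reports the response rate and the 1-s transient voltage,
#' which do grow with velocity).  For the conduction-limited steady-state
#' sweep of a real couple, see [coupleSweep()].
#'
#' @param plate a [DevicePlate-class].
#' @param fluid a [FluidProperties-class].
#' @param velocities airflow speeds, m/s.
#' @param Tair airflow temperature, K.
#' @param horizon transient evaluation time, s.
#' @return data.frame with columns `velocity_mps`, `h_W_m2K`, `rate_per_s`,
#'   `dT_at_horizon_K`, `v_at_horizon_V`.
#' @export
velocitySweep <- function(plate, fluid, velocities, Tair,
                          horizon = 1) {
  stopifnot(is(plate, "DevicePlate"), is(fluid, "FluidProperties"))
  if (!length(velocities) || any(velocities < 0))
    stop("'velocities' must be non-empty and >= 0", call. = FALSE)
  h <- convectiveCoefficient(fluid, plate@L, velocities)
  f <- thermalRate(h, plate)
  dTh <- (Tair - plate@Tlower) * (1 - exp(-f * horizon))
  data.frame(velocity_mps = velocities, h_W_m2K = h, rate_per_s = f,
             dT_at_horizon_K = dTh,
             v_at_horizon_V = plate@alphaDevice * dTh)
}
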