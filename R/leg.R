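# One-dimensional steady-state thermoelectric leg solver.
#
# Governing equations on a leg of length Lx with uniform properties:
#   d/dx (kappa dT/dx) + rho_TED j^2 = 0          (energy, Joule source)
#   dj/dx = 0                                      (current continuity)
#   j = -sigma (dE/dx + alpha dT/dx)               (generalized Ohm's law)
# The Seebeck coefficient is constant, so the Thomson term T j dalpha/dT
# vanishes identically (a modelling choice, not an omission).  Boundary
# conditions: Dirichlet T = Tlower at x = 0 (skin side) and the Robin
# condition kappa dT/dx = h (Tair - T) at x = Lx (convective upper face);
# side faces adiabatic.  Discretization: second-order central differences
# with a ghost node at the Robin face, direct tridiagonal solve.

# Assemble and solve the conduction problem with uniform volumetric source S
# (W/m^3).  Returns the nodal temperature vector.
.solveConduction <- function(kappa, Lx, n, Tlower, h, Tair, S = 0) {
  dx <- Lx / (n - 1L)
  A <- matrix(0, n, n)
  b <- numeric(n)
  A[1L, 1L] <- 1
  b[1L] <- Tlower
  for (i in 2:(n - 1L)) {
    A[i, i - 1L] <- kappa / dx^2
    A[i, i] <- -2 * kappa / dx^2
    A[i, i + 1L] <- kappa / dx^2
    b[i] <- -S
  }
  # ghost-node elimination at the Robin face keeps second order:
  #   kappa (T[n-1] - T[n]) * 2/dx^2 + 2h/dx (Tair - T[n]) + S = 0
  A[n, n - 1L] <- 2 * kappa / dx^2
  A[n, n] <- -2 * kappa / dx^2 - 2 * h / dx
  b[n] <- -S - 2 * h * Tair / dx
  solve(A, b)
}

.legSolution <- function(mat, geom, T, j, Rload = Inf) {
  x <- seq(0, geom@length, length.out = geom@nNodes)
  # j = -sigma (E' + alpha T')  =>  E' = -j/sigma - alpha T'
  dx <- x[2L] - x[1L]
  # integrate E' with the trapezoid rule on the nodal gradient
  Tgrad <- c((T[2L] - T[1L]) / dx,
             (T[-(1:2)] - T[1:(length(T) - 2L)]) / (2 * dx),
             (T[length(T)] - T[length(T) - 1L]) / dx)
  Eprime <- -j / mat@sigma - mat@alpha * Tgrad
  E <- c(0, cumsum((Eprime[-1L] + Eprime[-length(Eprime)]) / 2 * dx))
  Vleg <- if (is.finite(Rload)) j * geom@crossSection * Rload
          else mat@alpha * (T[length(T)] - T[1L])
  new("LegSolution", x = x, T = T, E = E, j = j, Vleg = Vleg,
      iterations = 0L)
}

#' Open-circuit steady state of a thermoelectric leg
#'
#' Solves pure conduction (j = 0) with fixed `Tlower` at the skin face and a
#' convective (Robin) boundary at the air face.  With constant conductivity
#' the profile is linear and the upper-face temperature has the closed form
#' \eqn{T_{up} = (h T_{air} + (\kappa/L) T_{lower}) / (h + \kappa/L)}.
#' The terminal voltage is \eqn{V = \alpha (T_{up} - T_{lower})}.
#'
#' @param mat a [LegMaterial-class].
#' @param geom a [LegGeometry-class].
#' @param Tlower skin-side temperature, K.
#' @param h convective coefficient at the air face, W/(m^2 K) (>= 0).
#' @param Tair airflow temperature, K.
#' @return a [LegSolution-class].
#' @examples
#' sol <- solveOpenCircuit(legMaterial(), legGeometry(), Tlower = 293.15,
#'                         h = 39.3, Tair = 285.15)
#' sol
#' @export
solveOpenCircuit <- function(mat, geom, Tlower, h, Tair) {
  stopifnot(is(mat, "LegMaterial"), is(geom, "LegGeometry"))
  .assertScalar(h, "h", nonneg = TRUE)
  .assertScalar(Tlower, "Tlower", positive = TRUE)
  .assertScalar(Tair, "Tair", positive = TRUE)
  T <- .solveConduction(mat@kappa, geom@length, geom@nNodes, Tlower, h, Tair)
  .legSolution(mat, geom, T, j = 0)
}

#' Loaded steady state of a thermoelectric leg
#'
#' Couples the conduction solve to the external circuit by fixed-point
#' iteration: the thermal EMF \eqn{\alpha \Delta T} drives a current through
#' the internal resistance \eqn{L/(\sigma A)} in series with `Rload`; the
#' resulting uniform Joule source \eqn{\rho_{TED} j^2} re-enters the energy
#' equation; iterate until the current is stationary
#' (|dj|/|j| <= 1e-8).  Current density is uniform along the leg by the 1-D
#' continuity equation.  Terminal voltage is `j * A * Rload`.
#'
#' @param mat a [LegMaterial-class].
#' @param geom a [LegGeometry-class].
#' @param Tlower skin-side temperature, K.
#' @param h convective coefficient, W/(m^2 K).
#' @param Tair airflow temperature, K.
#' @param Rload external load resistance, ohm (>= 0; `Inf` reproduces the
#'   open circuit).
#' @param maxIter maximum fixed-point iterations.
#' @return a [LegSolution-class] with `iterations` set.
#' @export
solveLoaded <- function(mat, geom, Tlower, h, Tair, Rload,
                        maxIter = 100L) {
  stopifnot(is(mat, "LegMaterial"), is(geom, "LegGeometry"))
  if (!is.numeric(Rload) || length(Rload) != 1L || is.na(Rload) || Rload < 0)
    stop("'Rload' must be a single number >= 0", call. = FALSE)
  rho <- 1 / mat@sigma
  Rint <- geom@length / (mat@sigma * geom@crossSection)
  j <- 0
  T <- NULL
  for (it in seq_len(maxIter)) {
    S <- rho * j^2
    T <- .solveConduction(mat@kappa, geom@length, geom@nNodes, Tlower, h,
                          Tair, S)
    dT <- T[length(T)] - T[1L]
    I <- mat@alpha * dT / (Rint + Rload)
    jNew <- if (is.finite(Rload)) I / geom@crossSection else 0
    if (abs(jNew - j) <= 1e-8 * max(abs(jNew), 1e-300)) {
      sol <- .legSolution(mat, geom, T, jNew, Rload)
      sol@iterations <- it
      return(sol)
    }
    j <- jNew
  }
  stop(sprintf(
    "solveLoaded did not converge in %d iterations (last j = %g A/m^2, dT = %g K)",
    maxIter, j, T[length(T)] - T[1L]), call. = FALSE)
}

#' Velocity sweep of a p/n thermocouple
#'
#' For each inlet velocity: compute the flat-plate convective coefficient
#' (characteristic length = the leg's face width, `sqrt(crossSection)`),
#' solve both legs open circuit, and report the mean upper-face temperature
#' offset and the couple open-circuit voltage
#' \eqn{V_{oc} = \alpha_p \Delta T_p - \alpha_n \Delta T_n}.  With air
#' cooler than the skin, both |dT| and |Voc| grow monotonically with
#' velocity.
#'
#' @param p,n p-type and n-type [LegMaterial-class] objects.
#' @param geom a [LegGeometry-class] (shared by both legs).
#' @param fluid a [FluidProperties-class].
#' @param Tlower skin-side temperature, K.
#' @param Tair airflow temperature, K.
#' @param velocities inlet speeds, m/s (non-empty, each >= 0).
#' @return data.frame with columns `velocity_mps`, `dT_K`, `v_oc_V`.
#' @examples
#' coupleSweep(legMaterial(), legMaterialN(), legGeometry(),
#'             fluidProperties(), Tlower = celsiusToKelvin(20),
#'             Tair = celsiusToKelvin(12), velocities = 1:5)
#' @export
coupleSweep <- function(p, n, geom, fluid, Tlower, Tair, velocities) {
  stopifnot(is(p, "LegMaterial"), is(n, "LegMaterial"),
            is(geom, "LegGeometry"), is(fluid, "FluidProperties"))
  if (!length(velocities) || any(velocities < 0))
    stop("'velocities' must be non-empty with each element >= 0",
         call. = FALSE)
  Lchar <- sqrt(geom@crossSection)
  res <- lapply(velocities, function(v) {
    h <- convectiveCoefficient(fluid, Lchar, v)
    sp <- solveOpenCircuit(p, geom, Tlower, h, Tair)
    sn <- solveOpenCircuit(n, geom, Tlower, h, Tair)
    dTp <- sp@T[length(sp@T)] - Tlower
    dTn <- sn@T[length(sn@T)] - Tlower
    c(dT = (dTp + dTn) / 2, voc = p@alpha * dTp - n@alpha * dTn)
  })
  res <- do.call(rbind, res)
  data.frame(velocity_mps = velocities, dT_K = res[, "dT"],
             v_oc_V = res[, "voc"])
}
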