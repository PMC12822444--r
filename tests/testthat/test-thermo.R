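# Forward model: convective coefficient, thermal rate, flux, step response
# and the piecewise-exponential integrator.

test_that("convective coefficient follows the laminar flat-plate correlation", {
  # hand evaluation: 0.664*(0.0257/0.01)*sqrt(1.2*1*0.01/1.8e-5)*0.71^(1/3)
  expect_equal(convectiveCoefficient(airFix, L = 0.01, v = 1),
               39.30746, tolerance = 1e-6)
  expect_identical(convectiveCoefficient(airFix, L = 0.02, v = 0), 0)
  # square-root scaling: quadrupling v doubles h
  for (v in c(0.3, 1, 2.7)) {
    expect_equal(convectiveCoefficient(airFix, 0.01, 4 * v) /
                 convectiveCoefficient(airFix, 0.01, v), 2,
                 tolerance = 1e-12)
  }
  # h ~ L^(-1/2): Re must include L
  expect_equal(convectiveCoefficient(airFix, 0.04, 1) /
               convectiveCoefficient(airFix, 0.01, 1), 0.5,
               tolerance = 1e-12)
  expect_error(convectiveCoefficient(airFix, -0.01, 1), "L")
  expect_error(convectiveCoefficient(airFix, 0.01, -1), "v")
  expect_error(fluidProperties(kappa = -1), "kappa")
})

test_that("fitted log-log slope of h(v) is exactly one half", {
  v <- seq(0.5, 4, length.out = 40)
  h <- convectiveCoefficient(airFix, 0.01, v)
  slope <- coef(lm(log(h) ~ log(v)))[[2L]]
  expect_equal(slope, 0.5, tolerance = 1e-6)
})

test_that("thermal rate is h*A/(m*cp) with the expected scalings", {
  pl <- devicePlate(A = 1e-4, m = 1e-3, cp = 200)
  expect_equal(thermalRate(39.3, pl), 39.3 * 1e-4 / 0.2, tolerance = 1e-12)
  expect_identical(thermalRate(0, pl), 0)
  pl2 <- devicePlate(A = 2e-4, m = 1e-3, cp = 200)
  expect_equal(thermalRate(10, pl2), 2 * thermalRate(10, pl),
               tolerance = 1e-12)
})

test_that("convective flux carries the exhale/inhale sign convention", {
  expect_equal(convectiveFlux(10, 0.01, 311.15, 293.15), 1.8,
               tolerance = 1e-12)
  expect_identical(convectiveFlux(25, 0.01, 300, 300), 0)
  expect_gt(convectiveFlux(25, 0.01, TexhFix, 300), 0)   # warm exhale heats
  expect_lt(convectiveFlux(25, 0.01, TambFix, 300), 0)   # cool inhale cools
})

test_that("Seebeck readout is linear and matches the per-couple constants", {
  alphaCouple <- 202.5e-6 - (-210e-6)
  expect_equal(voltageFromDT(alphaCouple, 30), 12.375e-3, tolerance = 1e-12)
  expect_identical(voltageFromDT(alphaCouple, 0), 0)
  expect_equal(voltageFromDT(alphaCouple, -8), -3.3e-3, tolerance = 1e-9)
  expect_equal(voltageFromDT(0.01, -3), -voltageFromDT(0.01, 3))
})

test_that("step response follows the closed-form exponential approach", {
  # plate chosen so f = 0.5 1/s exactly at v = 1: f = h A/(m cp)
  h1 <- convectiveCoefficient(airFix, 0.01, 1)
  pl <- devicePlate(A = 1e-4, m = h1 * 1e-4 / (0.5 * 500), cp = 500,
                    Tlower = 293.15)
  tr <- stepResponse(pl, airFix, vConst = 1, Tair = 311.15,
                     Tupper0 = 293.15, times = c(0, 1, 2, 10, 100))
  expect_equal(upperTemperature(tr)[1L], 293.15)
  expect_equal(upperTemperature(tr)[3L], 311.15 - 18 * exp(-1),
               tolerance = 1e-9)
  # monotone approach to T_air, no overshoot
  expect_true(all(diff(upperTemperature(tr)) > 0))
  expect_lt(abs(upperTemperature(tr)[5L] - 311.15), 1e-15 + 18 * exp(-50))
  # voltage endpoints
  expect_equal(voltage(tr)[1L], pl@alphaDevice * (293.15 - pl@Tlower))
  # zero initial gap: T stays at T_air
  tr0 <- stepResponse(pl, airFix, 1, 311.15, 311.15, times = 0:5)
  expect_true(all(abs(upperTemperature(tr0) - 311.15) < 1e-12))
  # no convection: pure hold
  trh <- stepResponse(pl, airFix, 0, 311.15, 300, times = 0:5)
  expect_true(all(upperTemperature(trh) == 300))
  expect_error(stepResponse(pl, airFix, 1, 311.15, 293.15,
                            times = numeric(0)), "non-empty")
  expect_error(stepResponse(pl, airFix, 1, 311.15, 293.15,
                            times = c(1, 1, 2)), "increasing")
})

test_that("integrator equals the closed form on constant inputs", {
  for (grid in list(seq(0, 20, by = 0.01), c(0, 0.05, 0.3, 1, 2, 7, 20))) {
    fl <- flowSignal(grid, v = 1, Tair = 311.15)
    sim <- simulateResponse(plateFix, airFix, fl, Tupper0 = 293.15)
    cf <- stepResponse(plateFix, airFix, 1, 311.15, 293.15, times = grid)
    expect_lt(max(abs(upperTemperature(sim) - upperTemperature(cf))), 1e-9)
  }
})

test_that("voltage rises during warm exhale and falls during cool inhale", {
  t <- seq(0, 8, by = 0.01)
  exhale <- (t %% 4) < 2
  fl <- flowSignal(t, v = 1.5, Tair = ifelse(exhale, TexhFix, TambFix))
  tr <- simulateResponse(plateFix, airFix, fl, Tupper0 = 300)
  V <- voltage(tr)
  # within each half-cycle (away from switch samples) the trend is monotone
  expect_true(all(diff(V[t > 0.1 & t < 1.9]) > 0))
  expect_true(all(diff(V[t > 2.1 & t < 3.9]) < 0))
  expect_true(all(diff(V[t > 4.1 & t < 5.9]) > 0))
})

test_that("zero flow holds the surface temperature", {
  fl <- flowSignal(seq(0, 5, 0.1), v = 0, Tair = 311.15)
  tr <- simulateResponse(plateFix, airFix, fl, Tupper0 = 299)
  expect_true(all(upperTemperature(tr) == 299))
})

test_that("per-step surface energy balance matches the convective integral", {
  # m cp dT == integral of h A (Tair - T) dt over each step, to <= 0.1%
  fl <- genBreathFlow(breathPattern("normal"), duration = 10, seed = 3)
  tr <- simulateResponse(plateFix, airFix, fl, Tupper0 = 300)
  t <- times(fl); v <- velocity(fl); Ta <- airTemperature(fl)
  Tu <- upperTemperature(tr)
  h <- convectiveCoefficient(airFix, plateFix@L, v)
  f <- thermalRate(h, plateFix)
  mcp <- plateFix@m * plateFix@cp
  n <- length(t)
  dt <- diff(t)
  lhs <- mcp * diff(Tu)
  # exact integral of q over the step with piecewise-constant v, Tair:
  # h A (Ta - T_i) (1 - exp(-f dt)) / f, with the f -> 0 limit h A (Ta-T_i) dt
  i <- seq_len(n - 1L)
  fac <- ifelse(f[i] > 0, (1 - exp(-f[i] * dt)) / f[i], dt)
  rhs <- h[i] * plateFix@A * (Ta[i] - Tu[i]) * fac
  scale <- pmax(abs(lhs), abs(rhs), 1e-12)
  expect_lt(max(abs(lhs - rhs) / scale), 1e-3)
})

test_that("steady-state distance to T_air shrinks monotonically to zero", {
  fl <- flowSignal(seq(0, 600, 0.5), v = 2, Tair = 285.15)
  tr <- simulateResponse(plateFix, airFix, fl, Tupper0 = 310)
  gap <- abs(upperTemperature(tr) - 285.15)
  expect_true(all(diff(gap) <= 0))
  expect_lt(gap[length(gap)], 1e-6)
})

test_that("voltage trace invariants hold exactly", {
  fl <- genBreathFlow(breathPattern("normal"), duration = 5, seed = 9)
  tr <- simulateResponse(plateFix, airFix, fl, 300)
  expect_identical(deltaT(tr), upperTemperature(tr) - plateFix@Tlower)
  expect_identical(voltage(tr), plateFix@alphaDevice * deltaT(tr))
  expect_true(validObject(tr))
})
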