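# One-dimensional thermoelectric leg solver.

pMat <- legMaterial()      # published p-type constants
nMat <- legMaterialN()
geomFix <- legGeometry()   # 2.5 mm leg, 1.4 mm x 1.4 mm

test_that("open-circuit solution matches the Robin closed form at all nodes", {
  Tlow <- 293.15; Tair <- 285.15; h <- 39.3
  sol <- solveOpenCircuit(pMat, geomFix, Tlow, h, Tair)
  Tup <- robinTupper(pMat@kappa, geomFix@length, Tlow, h, Tair)
  expect_equal(Tup, 292.3834, tolerance = 1e-6)       # hand-checked value
  # linear profile between the Dirichlet and Robin faces
  expected <- Tlow + (Tup - Tlow) * sol@x / geomFix@length
  expect_lt(max(abs(sol@T - expected)), 1e-9)
  expect_equal(sol@Vleg, pMat@alpha * (Tup - Tlow), tolerance = 1e-9)
  expect_identical(sol@j, 0)
})

test_that("insulated and infinite-h limits behave as pure conduction says", {
  sol0 <- solveOpenCircuit(pMat, geomFix, 293.15, 0, 285.15)
  expect_true(all(abs(sol0@T - 293.15) < 1e-9))
  expect_equal(sol0@Vleg, 0, tolerance = 1e-12)
  solInf <- solveOpenCircuit(pMat, geomFix, 293.15, 1e9, 285.15)
  expect_lt(abs(solInf@T[geomFix@nNodes] - 285.15), 1e-3)
})

test_that("halving the node spacing leaves the face temperature unchanged", {
  s1 <- solveOpenCircuit(pMat, legGeometry(nNodes = 51L), 293.15, 39.3, 285.15)
  s2 <- solveOpenCircuit(pMat, legGeometry(nNodes = 101L), 293.15, 39.3, 285.15)
  expect_lt(abs(s1@T[51L] - s2@T[101L]), 1e-6)
})

test_that("interior heat flux is continuous in the discrete solution", {
  sol <- solveOpenCircuit(pMat, geomFix, 293.15, 39.3, 285.15)
  dx <- diff(sol@x[1:2])
  flux <- -pMat@kappa * diff(sol@T) / dx
  expect_lt(max(abs(diff(flux))) , 1e-8 * abs(flux[1L]))
})

test_that("loaded solve recovers the open circuit for a huge load", {
  solOC <- solveOpenCircuit(pMat, geomFix, 293.15, 39.3, 285.15)
  solL <- solveLoaded(pMat, geomFix, 293.15, 39.3, 285.15, Rload = 1e12)
  expect_lt(max(abs(solL@T - solOC@T)), 1e-6)
})

test_that("delivered power peaks near the matched load", {
  Rint <- geomFix@length / (pMat@sigma * geomFix@crossSection)
  scan <- c(0.2, 0.5, 1, 2, 5) * Rint
  P <- vapply(scan, function(R) {
    s <- solveLoaded(pMat, geomFix, 293.15, 200, 275.15, R)
    I <- s@j * geomFix@crossSection
    I^2 * R
  }, 1.0)
  expect_equal(which.max(P), 3L)
  expect_gt(P[3L], 0)
})

test_that("no temperature gradient means no current and a flat profile", {
  s <- solveLoaded(pMat, geomFix, 293.15, 50, 293.15, Rload = 0.01)
  expect_lt(abs(s@j), 1e-6)          # numerically zero current density
  expect_true(all(abs(s@T - 293.15) < 1e-9))
})

test_that("couple sweep grows monotonically in speed with cold inflow", {
  sw <- coupleSweep(pMat, nMat, geomFix, airFix,
                    Tlower = celsiusToKelvin(20), Tair = celsiusToKelvin(12),
                    velocities = 1:5)
  expect_equal(nrow(sw), 5L)
  expect_true(all(sw$dT_K < 0))                 # cold flow cools the top
  expect_true(all(diff(abs(sw$dT_K)) > 0))
  expect_true(all(diff(abs(sw$v_oc_V)) > 0))
  # still air: no temperature difference, no voltage
  sw0 <- coupleSweep(pMat, nMat, geomFix, airFix, 293.15, 285.15,
                     velocities = 0)
  expect_lt(abs(sw0$dT_K), 1e-9)
  expect_lt(abs(sw0$v_oc_V), 1e-12)
})
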