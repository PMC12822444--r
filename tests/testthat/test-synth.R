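# Synthetic physiological generators: determinism, physical ranges, and
# the contracts the recognition stages rely on.

test_that("breath generator is deterministic and respects the velocity range", {
  p <- breathPattern("normal")
  a <- genBreathFlow(p, duration = 60, fs = 100, seed = 5)
  b <- genBreathFlow(p, duration = 60, fs = 100, seed = 5)
  expect_identical(velocity(a), velocity(b))
  expect_identical(airTemperature(a), airTemperature(b))
  expect_true(all(velocity(a) >= 0))
  expect_true(all(velocity(a) <= 2.5))
  # 15 breaths/min for 60 s -> 15 exhale lobes (runs of exhale-temperature air)
  exhale <- airTemperature(a) == p@exhaleT
  lobes <- sum(diff(c(FALSE, exhale)) == 1L)
  expect_equal(lobes, 15L)
  c2 <- genBreathFlow(p, duration = 60, fs = 100, seed = 6)
  expect_false(identical(velocity(a), velocity(c2)))
})

test_that("feeble breathing is strictly weaker than normal at the same seed", {
  for (s in c(1, 7, 23)) {
    vN <- max(velocity(genBreathFlow(breathPattern("normal"), 30, seed = s)))
    vF <- max(velocity(genBreathFlow(breathPattern("feeble"), 30, seed = s)))
    expect_lt(vF, vN)
  }
})

test_that("weightless breathing has a near-zero-flow gap each cycle", {
  fl <- genBreathFlow(breathPattern("weightless"), duration = 12, seed = 4)
  t <- times(fl); v <- velocity(fl)
  # first 0.4 s of each 4 s cycle sits inside the 0.5 s gap
  inGap <- (t %% 4) < 0.4
  expect_lt(stats::quantile(v[inGap], 0.95), 0.15)
  expect_gt(max(v[!inGap]), 0.8)
})

test_that("speech generator reproduces per seed and separates labels", {
  a <- genSpeechFlow(speechTemplate("HELP"), seed = 11)
  b <- genSpeechFlow(speechTemplate("HELP"), seed = 11)
  expect_identical(velocity(a), velocity(b))
  # four words -> four airflow bursts
  tpl <- speechTemplate("no pains no gains")
  expect_equal(nrow(tpl@bursts), 4L)
  fl <- genSpeechFlow(tpl, seed = 2)
  warm <- airTemperature(fl) == celsiusToKelvin(38)
  expect_equal(sum(diff(c(FALSE, warm)) == 1L), 4L)
  # different labels differ at the same seed
  for (other in setdiff(speechLabels(), "HELP")) {
    fo <- genSpeechFlow(speechTemplate(other), seed = 11)
    expect_gt(sqrt(sum((velocity(a) - velocity(fo))^2)), 0)
  }
  expect_error(speechTemplate("mystery phrase"), "unknown speech label")
})

test_that("cough trains place the requested events with ordered severity", {
  fl <- genCoughTrain("severe", count = 3, window = 5, seed = 8)
  expect_true(all(times(fl) >= 0 & times(fl) <= 5))
  v <- velocity(fl)
  # three supra-baseline transients
  high <- v > 2
  expect_equal(sum(diff(c(FALSE, high)) == 1L), 3L)
  # quiet train
  fl0 <- genCoughTrain("mild", count = 0, window = 5, seed = 8)
  expect_lt(max(velocity(fl0)), 1)
  # severity ordering of peaks at equal seed
  pk <- vapply(c("mild", "moderate", "severe"), function(int)
    max(velocity(genCoughTrain(int, 3, 5, seed = 8))), 1.0)
  expect_true(pk[["mild"]] < pk[["moderate"]])
  expect_true(pk[["moderate"]] < pk[["severe"]])
  expect_error(genCoughTrain("mild", count = 20, window = 5, seed = 1),
               "cannot place")
})

test_that("heartbeat traces have the right rate, jitter ordering, and seeds", {
  hb <- genHeartbeat(heartbeatPattern("resting"), duration = 10, seed = 3)
  expect_identical(hb,
    genHeartbeat(heartbeatPattern("resting"), duration = 10, seed = 3))
  pk <- .findPeaksPublic(hb$value, threshold = 0.5, minGap = 30L)
  expect_true(abs(length(pk) - 10L) <= 1L)
  # abnormal rhythm is more irregular than resting at the same seed
  cvOf <- function(kind, s) {
    x <- genHeartbeat(heartbeatPattern(kind), duration = 20, seed = s)
    p <- .findPeaksPublic(x$value, threshold = 0.5, minGap = 30L)
    iv <- diff(x$time_s[p])
    sd(iv) / mean(iv)
  }
  for (s in c(3, 12)) expect_gt(cvOf("abnormal", s), cvOf("resting", s))
})

test_that("fusion datasets are balanced, labelled by the rule, and seeded", {
  ds <- genFusionDataset(7, seed = 21, duration = 4)
  expect_length(ds, 28L)
  labs <- vapply(ds, fusedLabel, "")
  expect_equal(sum(labs == "abnormal"), 7L)
  combos <- table(vapply(ds, function(r) paste(r@tedState, r@hbState), ""))
  expect_true(all(combos == 7L))
  for (r in ds) {
    want <- if (r@tedState == "A-TEDS" && r@hbState == "A-HBS")
      "abnormal" else "normal"
    expect_identical(r@fusedLabel, want)
    # forward-model invariant carried into every recording
    expect_identical(voltage(r@ted), r@ted@alphaDevice * deltaT(r@ted))
  }
  ds2 <- genFusionDataset(7, seed = 21, duration = 4)
  expect_identical(lapply(ds, function(x) x@ted@V),
                   lapply(ds2, function(x) x@ted@V))
})
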