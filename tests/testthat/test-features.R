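# Spectral features, cough detection, the alarm rule and the fusion label.

test_that("spectrogram puts a pure tone in the right bin, frame by frame", {
  fs <- 100
  x <- sin(2 * pi * 2 * (0:999) / fs)
  sf <- spectralFeatures(x, fs = fs, frameLen = 0.64, hop = 0.32)
  peakFreq <- sf@freqs[apply(sf@magnitude, 2L, which.max)]
  expect_true(all(abs(peakFreq - 2) < 1 / 0.64))
  expect_identical(max(spectralFeatures(rep(0, 500), fs = fs)@magnitude), 0)
})

test_that("windowed frame energy agrees between time and frequency domains", {
  # Parseval for the first Hann-windowed frame of the one-sided spectrum
  fs <- 100; nWin <- 64
  set.seed(42)
  x <- rnorm(600)
  sf <- spectralFeatures(x, fs = fs, frameLen = nWin / fs, hop = 32 / fs)
  w <- as.numeric(signal::hanning(nWin))
  frame <- x[seq_len(nWin)] * w
  eTime <- sum(frame^2)
  X <- fft(frame)
  eFull <- sum(Mod(X)^2) / nWin
  expect_equal(eFull, eTime, tolerance = 1e-6)
  # and the one-sided magnitudes stored for that frame are the fft's
  expect_equal(as.numeric(sf@magnitude[, 1L]),
               Mod(X)[seq_len(nrow(sf@magnitude))], tolerance = 1e-6)
})

test_that("feature vectors share one length across unequal traces", {
  a <- spectralFeatures(rnorm(500), fs = 100)
  b <- spectralFeatures(rnorm(1400), fs = 100)
  expect_identical(length(featureVector(a)), length(featureVector(b)))
  expect_error(spectralFeatures(rnorm(10), fs = 100), "shorter than one frame")
})

test_that("cough detection recovers generated events and their intensity", {
  th <- coughThresholds()
  for (int in c("mild", "moderate", "severe")) {
    for (s in c(2, 13)) {
      fl <- genCoughTrain(int, count = 3, window = 5, seed = s)
      tr <- simulateResponse(plateFix, airFix, fl, Tupper0 = TambFix)
      ev <- detectCoughs(tr, th)
      expect_equal(nrow(ev), 3L)
      expect_true(all(ev$intensity == int))
    }
  }
  # quiet trace: no events
  fl0 <- genCoughTrain("mild", count = 0, window = 5, seed = 2)
  tr0 <- simulateResponse(plateFix, airFix, fl0, Tupper0 = TambFix)
  expect_equal(nrow(detectCoughs(tr0, th)), 0L)
})

test_that("mixed-intensity trains keep per-event intensity assignment", {
  # mild train followed by a severe train, concatenated end to end
  flM <- genCoughTrain("mild", 2, window = 5, seed = 31)
  flS <- genCoughTrain("severe", 3, window = 5, seed = 32)
  t2 <- c(times(flM), times(flS) + 5)
  fl <- flowSignal(t2, c(velocity(flM), velocity(flS)),
                   c(airTemperature(flM), airTemperature(flS)))
  tr <- simulateResponse(plateFix, airFix, fl, Tupper0 = TambFix)
  ev <- detectCoughs(tr)
  expect_equal(sum(ev$intensity == "mild"), 2L)
  expect_equal(sum(ev$intensity == "severe"), 3L)
})

test_that("alarm rule triggers on exactly >=3 severe events within 5 s", {
  mk <- function(times, intensity = "severe")
    data.frame(time = times, intensity = rep(intensity, length(times)))
  a <- alarmRule(mk(c(0.5, 2.0, 4.5)))
  expect_true(a@active)
  expect_equal(a@triggerTime, 4.5)
  expect_false(alarmRule(mk(c(0.5, 4.5)))@active)
  expect_false(alarmRule(mk(c(0.5, 1, 2, 3, 4), "mild"))@active)
  # exhaustive truth table: k severe events spread over span s
  for (k in 0:5) {
    for (span in c(2, 4.99, 5, 6, 10)) {
      tt <- if (k > 0) seq(0, span, length.out = max(k, 2L))[seq_len(k)] else numeric(0)
      st <- alarmRule(mk(tt))
      # any-window rule: fires iff some 3 consecutive severe events span <= 5
      fires <- FALSE
      if (k >= 3) {
        for (i in seq_len(k - 2L))
          if (tt[i + 2L] - tt[i] <= 5) fires <- TRUE
      }
      expect_identical(st@active, fires)
    }
  }
  # non-severe events never contribute, whatever the mix
  mixed <- data.frame(time = c(0.2, 0.6, 1.1, 1.9, 2.5),
                      intensity = c("severe", "mild", "severe", "moderate",
                                    "severe"))
  st <- alarmRule(mixed)
  expect_true(st@active)
  expect_equal(nrow(st@events), 3L)
  expect_true(all(st@events$intensity == "severe"))
})

test_that("window placement matters: three severe spread past 5 s stay silent", {
  ev <- data.frame(time = c(0, 3, 6.5), intensity = "severe")
  expect_false(alarmRule(ev)@active)
  # but a later clustered trio fires even after early stragglers
  ev2 <- data.frame(time = c(0, 6, 7, 8), intensity = "severe")
  st <- alarmRule(ev2)
  expect_true(st@active)
  expect_equal(st@triggerTime, 8)
})

test_that("fusion label implements the conjunction over all four states", {
  expect_identical(fusionLabel("A-TEDS", "A-HBS"), "abnormal")
  expect_identical(fusionLabel("A-TEDS", "normal"), "normal")
  expect_identical(fusionLabel("normal", "A-HBS"), "normal")
  expect_identical(fusionLabel("normal", "normal"), "normal")
  expect_error(fusionLabel("odd", "normal"), "unknown tedState")
  expect_error(fusionLabel("normal", "odd"), "unknown hbState")
})

test_that("alarm end-to-end: generated severe train through the device", {
  fl <- genCoughTrain("severe", count = 3, window = 5, seed = 17)
  tr <- simulateResponse(plateFix, airFix, fl, Tupper0 = TambFix)
  st <- alarmRule(detectCoughs(tr))
  expect_true(st@active)
  flM <- genCoughTrain("moderate", count = 5, window = 5, seed = 17)
  trM <- simulateResponse(plateFix, airFix, flM, Tupper0 = TambFix)
  expect_false(alarmRule(detectCoughs(trM))@active)
})
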