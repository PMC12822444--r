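# Shared fixtures: default air, a default plate, and small helpers used
# across the test files.  Everything is generated in code at test time.

airFix <- fluidProperties()          # kappa 0.0257, rho 1.2, mu 1.8e-5, Pr 0.71
plateFix <- devicePlate()
TambFix <- celsiusToKelvin(20)
TexhFix <- celsiusToKelvin(38)

# simple local-maximum picker shared by the heartbeat tests
.findPeaksPublic <- airtherm:::.findPeaks

# closed-form upper-face temperature under a Robin boundary on a leg with
# conductivity kappa and length L (independent oracle for the leg solver)
robinTupper <- function(kappa, L, Tlower, h, Tair) {
  (h * Tair + (kappa / L) * Tlower) / (h + kappa / L)
}

# speech feature set: 10 samples per canonical class through the forward
# model, seeds derived from `root`
speechFeatureSet <- function(root) {
  labs <- rep(speechLabels(), each = 10L)
  seeds <- root * 1000L + seq_along(labs)
  feats <- lapply(seq_along(labs), function(i) {
    fl <- genSpeechFlow(speechTemplate(labs[i]), seed = seeds[i])
    voltageSpectrum(simulateResponse(plateFix, airFix, fl,
                                     Tupper0 = celsiusToKelvin(27)))
  })
  list(features = feats, labels = labs)
}
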