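# Shared fixtures for the test suite.  Heavy objects (the scaled training
# study) are built once per test run and memoized, because several
# acceptance checks interrogate the same trained model.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# Scaled-down study conditions: 64-pixel images, width-0.25 network,
# counts 1-10.  Style A (phase-contrast-like) is the pretraining domain,
# style B (bright-field-like) the transfer target.  The "natural" role is
# played by the standard preset, the "synthetic" role by a visually
# cleaner preset (less noise), mirroring how simplified synthetic data
# accompanies real micrographs.
scaledCounts <- list(minCount = 1, maxCount = 10, geomP = 0.15)

naturalPreset <- function(style) stylePreset(style)
syntheticPreset <- function(style)
  stylePreset(style, noiseAmplitudeRange = c(0.005, 0.015))

scaledSets <- function(style, nNat, nSyn, seedBase, labeledFraction = 0.5) {
  nat <- generateImageSet(naturalPreset(style), nNat, scaledCounts,
                          seed = seedBase, resolution = 64,
                          modality = "natural")
  drop <- withr::with_seed(seedBase + 1,
    sample(nNat, round((1 - labeledFraction) * nNat)))
  nat@label[drop] <- NA_integer_
  syn <- generateImageSet(syntheticPreset(style), nSyn, scaledCounts,
                          seed = seedBase + 2, resolution = 64,
                          modality = "synthetic")
  list(natural = nat, synthetic = syn)
}

scaledTrainConfig <- function(maxEpochs, seed, regressorDelayEpochs = 50) {
  trainConfig(learningRate = 1e-3, weightDecay = 1e-5, optimizer = "adam",
              batchSize = 64, maxEpochs = maxEpochs,
              regressorDelayEpochs = regressorDelayEpochs,
              earlyStopPatience = 0, validationEvery = 25,
              validationFraction = 0.1, synNatRatio = 1, seed = seed)
}

tinyModel <- function() {
  memo("tinyModel", function() twinVAE(resolution = 64, width = 0.25, seed = 7))
}

# the pretraining study: 300 images per role on style A, 400 epochs
scaledStudyData <- function() {
  memo("scaledStudyData", function() {
    c(scaledSets("pc", 300, 300, seedBase = 1101),
      list(testSynthetic = generateImageSet(syntheticPreset("pc"), 100,
                                            scaledCounts, seed = 1201,
                                            resolution = 64,
                                            modality = "synthetic")))
  })
}

scaledStudyModel <- function() {
  memo("scaledStudyModel", function() {
    d <- scaledStudyData()
    m <- twinVAE(resolution = 64, width = 0.25, seed = 101)
    trainTwinVAE(m, d$natural, d$synthetic, scaledTrainConfig(400, seed = 202))
  })
}

expect_all_equal_state <- function(s1, s2, parts, skipRunning = TRUE) {
  for (p in parts) {
    for (nm in names(s1[[p]])) {
      if (skipRunning && startsWith(nm, "bn.running")) next
      expect_identical(s1[[p]][[nm]], s2[[p]][[nm]],
                       label = paste0(p, "/", nm))
    }
  }
}

state_changed <- function(s1, s2, part) {
  any(vapply(names(s1[[part]]), function(nm) {
    if (startsWith(nm, "bn.running")) return(FALSE)
    !identical(s1[[part]][[nm]], s2[[part]][[nm]])
  }, TRUE))
}
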