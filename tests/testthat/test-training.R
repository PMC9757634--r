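test_that("augmentation preserves annotations, shape and range", {
  set.seed(51)
  img <- imageSample(matrix(runif(64^2), 64), 4, "natural", "pc")
  out <- augmentSample(img, augmentConfig(noiseAmplitude = 0.05))
  expect_identical(out@label, 4L)
  expect_identical(out@modality, "natural")
  expect_identical(dim(out@pixels), c(64L, 64L))
  expect_true(all(out@pixels >= 0 & out@pixels <= 1))
  # all steps disabled: the identity
  off <- augmentConfig(enableFlips = FALSE, enableCrop = FALSE,
                       enableRotation90 = FALSE, enableSmallRotation = FALSE,
                       enableNoise = FALSE)
  expect_identical(augmentSample(img, off)@pixels, img@pixels)
  expect_error(augmentSample(img, augmentConfig(cropScale = 0.001)), "crop")
})

test_that("the crop step uses the published intermediate size", {
  # at 128 pixels and crop scale 0.9 the crop side is exactly 115
  expect_identical(as.integer(round(128 * 0.9)), 115L)
  # verify behaviorally: with only the crop enabled, a delta image widens
  # by the 115 -> 128 bilinear upscale factor
  set.seed(52)
  img <- matrix(0, 128, 128); img[64, 64] <- 1
  cfg <- augmentConfig(enableFlips = FALSE, enableRotation90 = FALSE,
                       enableSmallRotation = FALSE, enableNoise = FALSE)
  out <- augmentSample(img, cfg)
  # the impulse stays a local blob (a few pixels after bilinear resampling)
  expect_true(sum(out > 0) >= 1 && sum(out > 0) <= 9)
  expect_gt(max(out), 0.2)
})

test_that("augmentation keeps the pixel mean stable over many draws", {
  set.seed(53)
  img <- renderScene(sampleScene(stylePreset("bf"), 5, resolution = 64))
  cfg <- augmentConfig(noiseAmplitude = 0.02)
  mu <- replicate(400, mean(augmentSample(img@pixels, cfg)))
  # crops/flips/rotations resample the same image content; only the noise
  # map and interpolation can shift the mean
  expect_lt(abs(mean(mu) - mean(img@pixels)), 0.02 + 0.01)
})

test_that("the mixed sampler realizes the configured ratio exactly", {
  set.seed(54)
  b <- mixedBatchSampler(100, 500, ratio = 2, batchSize = 30)
  nat <- unlist(lapply(b, `[[`, "natural"))
  syn <- unlist(lapply(b, `[[`, "synthetic"))
  expect_identical(sort(nat), 1:100)         # every natural sample once
  expect_length(syn, 200)                    # round(2 * 100) synthetic
  b2 <- mixedBatchSampler(100, 100, ratio = 1, batchSize = 40)
  expect_identical(sort(unlist(lapply(b2, `[[`, "natural"))), 1:100)
  expect_identical(sort(unlist(lapply(b2, `[[`, "synthetic"))), 1:100)
  b3 <- suppressWarnings(mixedBatchSampler(100, 500, ratio = 0.25,
                                           batchSize = 30))
  expect_length(unlist(lapply(b3, `[[`, "synthetic")), 25)
  # small pools draw synthetic samples with replacement
  b4 <- mixedBatchSampler(50, 10, ratio = 2, batchSize = 30)
  expect_length(unlist(lapply(b4, `[[`, "synthetic")), 100)
  expect_error(mixedBatchSampler(0, 10), "non-empty")
})

test_that("training for zero epochs returns the model unchanged", {
  m <- twinVAE(resolution = 64, width = 0.25, seed = 61)
  d <- memo("microSets", function() scaledSets("bf", 24, 24, seedBase = 6101,
                                               labeledFraction = 1))
  before <- getCheckpoint(m)$state
  m <- trainTwinVAE(m, d$natural, d$synthetic, scaledTrainConfig(0, seed = 1))
  expect_identical(getCheckpoint(m)$state, before)
  expect_identical(nrow(m@history), 0L)
  expect_error(trainTwinVAE(m, d$natural[integer(0)], d$synthetic,
                            scaledTrainConfig(1, seed = 1)), "non-empty")
  unl <- d$synthetic; unl@label[1] <- NA_integer_
  expect_error(trainTwinVAE(m, d$natural, unl, scaledTrainConfig(1, seed = 1)),
               "fully labeled")
})

test_that("the regression weight is zero before the delay elapses", {
  m <- twinVAE(resolution = 64, width = 0.25, seed = 62)
  d <- memo("microSets", function() scaledSets("bf", 24, 24, seedBase = 6101,
                                               labeledFraction = 1))
  cfg <- scaledTrainConfig(4, seed = 2, regressorDelayEpochs = 3)
  m <- trainTwinVAE(m, d$natural, d$synthetic, cfg)
  expect_identical(m@history$reg_weight_natural, c(0, 0, 0, 3))
  expect_identical(m@history$reg_weight_synthetic, c(0, 0, 0, 3))
})

test_that("training is reproducible and reduces the twin loss", {
  d <- memo("microSets2", function() scaledSets("pc", 40, 40, seedBase = 6301,
                                                labeledFraction = 1))
  run <- function() {
    m <- twinVAE(resolution = 64, width = 0.25, seed = 63)
    trainTwinVAE(m, d$natural, d$synthetic,
                 scaledTrainConfig(10, seed = 64, regressorDelayEpochs = 0))
  }
  m1 <- run(); m2 <- run()
  expect_identical(m1@history, m2@history)
  expect_identical(getCheckpoint(m1)$state, getCheckpoint(m2)$state)
  expect_lt(tail(m1@history$total, 1), m1@history$total[1])
})

test_that("labels only influence the regression term of the loss", {
  d <- memo("microSets2", function() scaledSets("pc", 40, 40, seedBase = 6301,
                                                labeledFraction = 1))
  unlabeled <- d$natural
  unlabeled@label[] <- NA_integer_
  # a single batch per epoch so the loss components are computed at the
  # same parameter state in both runs
  cfg <- scaledTrainConfig(1, seed = 65, regressorDelayEpochs = 0)
  cfg@batchSize <- 128L
  cfg@validationFraction <- 0
  mL <- trainTwinVAE(twinVAE(resolution = 64, width = 0.25, seed = 66),
                     d$natural, d$synthetic, cfg)
  mU <- trainTwinVAE(twinVAE(resolution = 64, width = 0.25, seed = 66),
                     unlabeled, d$synthetic, cfg)
  # identical first-epoch reconstruction and KL components: removing the
  # natural labels changes nothing but the regression contribution
  expect_identical(mL@history$rec_natural[1], mU@history$rec_natural[1])
  expect_identical(mL@history$rec_synthetic[1], mU@history$rec_synthetic[1])
  expect_identical(mL@history$kl_natural[1], mU@history$kl_natural[1])
  expect_identical(mL@history$kl_synthetic[1], mU@history$kl_synthetic[1])
})

test_that("a training YAML file resolves to the matching configuration", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "model: {resolution: 64, width: 0.25, seed: 3}",
    "train:",
    "  learning_rate: 0.0013",
    "  batch_size: 32",
    "  max_epochs: 7",
    "  optimizer: radam",
    "  syn_nat_ratio: 2",
    "weights:",
    "  natural: {c_rec: 100, c_reg: 3, c_kl: 2, rec_kind: bce}",
    "  synthetic: {c_rec: 50}",
    "augment: {enabled: yes, crop_scale: 0.9}",
    "plan: frozen_core"
  ), path)
  cf <- readTrainConfigFile(path)
  expect_equal(cf$config@learningRate, 0.0013)
  expect_identical(cf$config@batchSize, 32L)
  expect_identical(cf$config@optimizer, "radam")
  expect_identical(cf$config@weightsNatural@recKind, "bce")
  expect_equal(cf$config@weightsSynthetic@cRec, 50)
  expect_s4_class(cf$config@augment, "AugmentConfig")
  expect_identical(cf$plan@scheme, "frozen_core")
  expect_identical(cf$model$resolution, 64L)
})
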