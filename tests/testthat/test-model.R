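test_that("the architecture scales with the width multiplier", {
  m <- tinyModel()
  info <- TwinVAE:::eng_info(m@ptr)
  expect_identical(info$encoder_channels, c(8L, 16L, 32L, 64L))
  expect_identical(info$latent_dim, 64L)
  expect_identical(info$shared_channels, 128L)
  full <- twinVAE(resolution = 32, width = 1, seed = 1)
  fi <- TwinVAE:::eng_info(full@ptr)
  expect_identical(fi$encoder_channels, c(32L, 64L, 128L, 256L))
  expect_identical(fi$latent_dim, 256L)
  expect_error(twinVAE(resolution = 48), "multiple of 32")
})

test_that("the eight named parts partition the parameter set", {
  st <- getCheckpoint(tinyModel())$state
  expect_identical(sort(names(st)), sort(networkParts()))
  nFromParts <- sum(vapply(st, function(p) {
    sum(vapply(p[!startsWith(names(p), "bn.running")], length, 1))
  }, 0))
  expect_equal(nFromParts, TwinVAE:::eng_info(tinyModel()@ptr)$n_parameters)
  # no tensor name appears twice within a part
  for (p in st) expect_false(anyDuplicated(names(p)) > 0)
})

test_that("encoding routes by modality and honors evaluation determinism", {
  m <- tinyModel()
  px <- matrix(runif(64^2, 0.2, 0.8), 64, 64)
  asNat <- imageSample(px, 3, "natural", "pc")
  asSyn <- imageSample(px, 3, "synthetic", "pc")
  eN <- encodeImages(m, asNat)
  eS <- encodeImages(m, asSyn)
  # same pixels, different outer encoders: different codes
  expect_gt(max(abs(eN$mean - eS$mean)), 1e-4)
  # evaluation mode is deterministic and the sample equals the mean
  e2 <- encodeImages(m, asNat)
  expect_identical(eN$mean, e2$mean)
  expect_identical(eN$sample, eN$mean)
  # stochastic sampling varies while the mean stays fixed
  s1 <- encodeImages(m, asNat, sample = TRUE)
  s2 <- encodeImages(m, asNat, sample = TRUE)
  expect_identical(s1$mean, s2$mean)
  expect_gt(max(abs(s1$sample - s2$sample)), 1e-6)
})

test_that("decoding produces rasters in [0, 1] at the configured size", {
  m <- tinyModel()
  z <- matrix(rnorm(64 * 3), 64, 3)
  for (mod in c("natural", "synthetic")) {
    out <- decodeLatent(m, z, mod)
    expect_identical(dim(out), c(4096L, 3L))
    expect_true(all(out >= 0 & out <= 1))
  }
  z0 <- matrix(0, 64, 1)
  expect_identical(decodeLatent(m, z0, "natural"),
                   decodeLatent(m, z0, "natural"))
  expect_error(decodeLatent(m, matrix(0, 10, 1), "natural"), "latent")
})

test_that("the forward pass returns finite counts and matching shapes", {
  m <- tinyModel()
  smp <- imageSample(matrix(0.5, 64, 64), NA, "natural", "bf")
  out <- twinForward(m, smp)
  expect_identical(dim(out$reconstruction), c(4096L, 1L))
  expect_true(is.finite(out$predictedCount))
  expect_identical(nrow(out$latent$mean), 64L)
})

test_that("gradients from one modality never touch the other twin's outer parts", {
  m <- tinyModel()
  x <- matrix(runif(4096 * 4), 4096, 4)
  r <- TwinVAE:::eng_train_batch(m@ptr, x, rep(3, 4), rep(3, 4),
                                 matrix(0, 4096, 0), numeric(0), numeric(0),
                                 100, 100, 0L, 0L, 2, 2,
                                 1e-3, 0, 0L, 0.9, 0.999, rep(TRUE, 8), FALSE)
  gn <- setNames(as.numeric(r$grad_norms), networkParts())
  expect_equal(gn[["outer_encoder_synthetic"]], 0)
  expect_equal(gn[["outer_decoder_synthetic"]], 0)
  expect_gt(gn[["outer_encoder_natural"]], 0)
  expect_gt(gn[["shared_encoder"]], 0)
  expect_gt(gn[["regressor"]], 0)
})

test_that("shared layers are one storage serving both modalities", {
  m <- twinVAE(resolution = 64, width = 0.25, seed = 33)
  synImg <- imageSample(matrix(runif(64^2), 64), 2, "synthetic", "bf")
  before <- encodeImages(m, synImg)$mean
  # optimize on a natural-only batch; outer synthetic parts cannot move
  x <- matrix(runif(4096 * 8), 4096, 8)
  s0 <- getCheckpoint(m)$state
  TwinVAE:::eng_train_batch(m@ptr, x, rep(2, 8), rep(3, 8),
                            matrix(0, 4096, 0), numeric(0), numeric(0),
                            100, 100, 0L, 0L, 2, 2,
                            1e-2, 0, 0L, 0.9, 0.999, rep(TRUE, 8), TRUE)
  s1 <- getCheckpoint(m)$state
  expect_all_equal_state(s0, s1, c("outer_encoder_synthetic",
                                   "outer_decoder_synthetic"))
  # yet the synthetic path sees the updated shared weights
  after <- encodeImages(m, synImg)$mean
  expect_gt(max(abs(after - before)), 1e-6)
})

test_that("reconstruction losses match their closed forms", {
  x1 <- matrix(1, 4, 4); d5 <- matrix(0.5, 4, 4)
  expect_equal(reconstructionLoss(x1, x1, "mse"), 0)
  expect_equal(reconstructionLoss(x1, d5, "mse"), 0.25)
  expect_equal(reconstructionLoss(x1, d5, "bce"), log(2), tolerance = 1e-12)
  expect_error(reconstructionLoss(x1, matrix(1, 2, 2)), "shape")
})

test_that("regression and KL losses match their closed forms", {
  expect_equal(regressionLoss(3, 3), 0)
  expect_equal(regressionLoss(1, 3), 4)
  expect_equal(regressionLoss(30, 0), 900)
  expect_error(regressionLoss(NA, 1), "unlabeled")
  expect_equal(klDivergence(0, 0), 0)
  expect_equal(klDivergence(1, 0), 0.5)
  set.seed(5)
  for (i in 1:20) {
    mu <- matrix(rnorm(16), 8); lv <- matrix(rnorm(16, sd = 0.5), 8)
    expect_gte(klDivergence(mu, lv), 0)
  }
})

test_that("the twin loss combines components per the published weighting", {
  w <- lossWeights(cRec = 100, cReg = 3, cKL = 2)
  expect_equal(twinLoss(0.01, 4, 0.5, w), 14)
  # unlabeled samples contribute no regression term
  expect_equal(twinLoss(0.01, NA, 0.5, w, labeled = FALSE),
               twinLoss(0.01, 999, 0.5, w, labeled = FALSE))
  expect_equal(twinLoss(1, 1, 1, lossWeights(0, 0, 0)), 0)
  # linearity: doubling all weights doubles the loss
  w2 <- lossWeights(cRec = 200, cReg = 6, cKL = 4)
  set.seed(6)
  for (i in 1:10) {
    comp <- runif(3, 0, 5)
    expect_equal(twinLoss(comp[1], comp[2], comp[3], w2),
                 2 * twinLoss(comp[1], comp[2], comp[3], w))
  }
})

test_that("the BCE reconstruction weight decays multiplicatively per epoch", {
  wb <- lossWeights(cRec = 100, recKind = "bce", recDecayRate = 3e-5)
  expect_equal(effectiveRecWeight(wb, 0), 100)
  expect_equal(effectiveRecWeight(wb, 1000), 100 * (1 - 3e-5)^1000)
  wm <- lossWeights(cRec = 100, recKind = "mse")
  expect_equal(effectiveRecWeight(wm, 1000), 100)
})

test_that("checkpoints round-trip bit-exactly", {
  m <- tinyModel()
  ck <- getCheckpoint(m)
  m2 <- twinVAEFromCheckpoint(ck)
  expect_identical(getCheckpoint(m2)$state, ck$state)
  path <- withr::local_tempfile(fileext = ".rds")
  writeCheckpoint(ck, path)
  expect_identical(readCheckpoint(path)$state, ck$state)
  x <- imageSample(matrix(runif(64^2), 64), 1, "natural", "pc")
  expect_identical(twinForward(m, x)$predictedCount,
                   twinForward(m2, x)$predictedCount)
  # architecture mismatch is rejected with a descriptive error
  other <- twinVAE(resolution = 64, width = 0.5, seed = 1)
  expect_error(setCheckpoint(other, ck), "incompatible")
})
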