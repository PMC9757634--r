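test_that("count sampling respects its support and decreasing shape", {
  expect_identical(sampleCount(list(minCount = 1, maxCount = 1), n = 5),
                   rep(1L, 5))
  set.seed(41)
  draws <- sampleCount(list(minCount = 1, maxCount = 30, geomP = 0.2),
                       n = 10000)
  expect_true(all(draws >= 1 & draws <= 30))
  freq <- tabulate(draws, 30) / 10000
  # empirical frequencies decrease along the support, as the closed-form
  # pmf does: check the spot pattern P(1) > P(10) > P(30)
  expect_gt(freq[1], freq[10])
  expect_gt(freq[10], freq[30])
  pmf <- countPMF(list(minCount = 1, maxCount = 30, geomP = 0.2))
  expect_true(all(diff(pmf) <= 0))
  expect_equal(sum(pmf), 1)
  expect_lt(max(abs(freq - pmf)), 0.02)
  expect_error(sampleCount(list(minCount = -1)), "support")
  expect_error(sampleCount(list(minCount = 5, maxCount = 31)), "support")
})

test_that("scene sampling conserves the requested count and is seeded", {
  p <- stylePreset("bf")
  set.seed(1)
  empty <- sampleScene(p, 0, resolution = 64)
  expect_identical(nrow(empty@cells), 0L)
  set.seed(2)
  s5 <- sampleScene(p, 5, resolution = 64)
  expect_identical(nrow(s5@cells), 5L)
  set.seed(3); a <- sampleScene(p, 7, resolution = 64)
  set.seed(3); b <- sampleScene(p, 7, resolution = 64)
  expect_identical(a, b)
  expect_error(sampleScene(p, 31), "count")
})

test_that("dense scenes place all cells by relaxing separation", {
  set.seed(9)
  for (res in c(64L, 128L)) {
    s <- sampleScene(stylePreset("pc"), 30, resolution = res)
    expect_identical(nrow(s@cells), 30L)
  }
})

test_that("rendering is range-safe and resolves single cells", {
  # empty scene with no noise renders the constant background
  sc <- new("SceneSpec", cells = data.frame(), backgroundLevel = 0.5,
            noiseAmplitude = 0, style = "bf", resolution = 64L,
            seed = NA_integer_)
  img <- renderScene(sc)
  expect_true(all(img@pixels == 0.5))
  expect_identical(img@label, 0L)
  expect_identical(img@modality, "synthetic")

  # any rendered scene stays inside [0, 1] at the requested resolution
  set.seed(11)
  for (style in c("bf", "pc")) {
    s <- sampleScene(stylePreset(style), 12, resolution = 64)
    r <- renderScene(s)
    expect_gte(min(r@pixels), 0)
    expect_lte(max(r@pixels), 1)
    expect_identical(dim(r@pixels), c(64L, 64L))
    expect_identical(r@label, 12L)
  }

  # one high-contrast cell yields exactly one thresholded component
  set.seed(12)
  p <- stylePreset("bf", interiorBrightnessRange = c(0.1, 0.1),
                   noiseAmplitudeRange = c(0, 0))
  one <- renderScene(sampleScene(p, 1, resolution = 64))
  expect_identical(countComponents(one@pixels, "dark", threshold = 0.45), 1L)
})

test_that("rendering with a stored seed is a pure function of the scene", {
  set.seed(13)
  sc <- sampleScene(stylePreset("pc"), 4, resolution = 64, seed = 99L)
  r1 <- renderScene(sc)
  set.seed(4242)  # global RNG state must not matter
  r2 <- renderScene(sc)
  expect_identical(r1@pixels, r2@pixels)
})

test_that("dataset generation is byte-identical under a fixed seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  m1 <- generateDataset(stylePreset("pc"), 10, scaledCounts, seed = 7,
                        outDir = d1, resolution = 64)
  m2 <- generateDataset(stylePreset("pc"), 10, scaledCounts, seed = 7,
                        outDir = d2, resolution = 64)
  files <- sort(list.files(d1))
  expect_identical(files, sort(list.files(d2)))
  expect_length(files, 11L)  # 10 PNG + manifest
  for (f in files) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6), label = f)
  }
  expect_identical(m1@data, m2@data)
  expect_true(all(m1@data$label >= 1 & m1@data$label <= 10))
  # loading round-trips the rendered pixels up to 8-bit quantization
  set1 <- loadImageSet(file.path(d1, "manifest.csv"))
  ref <- generateImageSet(stylePreset("pc"), 10, scaledCounts, seed = 7,
                          resolution = 64)
  expect_lt(max(abs(set1@images - ref@images)), 1 / 255)
  expect_identical(set1@label, ref@label)
})

test_that("background estimation averages sparse reference images", {
  mk <- function(v, lab) imageSample(matrix(v, 8, 8), lab)
  ref <- imageSet(list(mk(0.2, 1), mk(0.4, 2)))
  expect_equal(backgroundFromReference(ref), 0.3)
  expect_equal(backgroundFromReference(imageSet(list(mk(0.7, 1), mk(0.7, 3)))),
               0.7)
  dense <- imageSet(list(mk(0.5, 10)))
  expect_error(backgroundFromReference(dense, maxCount = 5), "no reference")
})

test_that("the two style presets are separable by trivial pixel statistics", {
  set.seed(21)
  nPer <- 75
  bf <- generateImageSet(stylePreset("bf"), nPer, scaledCounts, seed = 31,
                         resolution = 64)
  pc <- generateImageSet(stylePreset("pc"), nPer, scaledCounts, seed = 32,
                         resolution = 64)
  feat <- function(s) apply(s@images, 3, mean)
  fb <- feat(bf); fp <- feat(pc)
  # fit a mean-gray threshold on 50 images per style, test on the rest
  thr <- (mean(fb[1:50]) + mean(fp[1:50])) / 2
  test <- c(fb[51:nPer], fp[51:nPer])
  truth <- rep(c("bf", "pc"), each = nPer - 50)
  pred <- ifelse(test > thr, "bf", "pc")
  expect_gt(mean(pred == truth) * 100, 90)
})
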