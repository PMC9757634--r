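test_that("metrics match hand-computed values", {
  r <- computeMetrics(c(3, 7, 12), c(3, 7, 12))
  expect_equal(r@mae, 0); expect_equal(r@mre, 0); expect_equal(r@accuracy, 100)

  r <- computeMetrics(c(2, 2), c(1, 4))
  expect_equal(r@mae, 1.5)
  expect_equal(r@mre, 75)
  expect_equal(r@accuracy, 0)
  expect_equal(unname(r@perCountMRE["1"]), 100)
  expect_equal(unname(r@perCountMRE["4"]), 50)

  # rounding is half away from zero
  r <- computeMetrics(c(1.4, 2.6), c(1, 3))
  expect_equal(r@accuracy, 100)
  expect_equal(computeMetrics(2.5, 3)@accuracy, 100)  # 2.5 rounds up to 3
  expect_equal(computeMetrics(2.5, 2)@accuracy, 0)
  expect_equal(TwinVAE:::roundHalfAway(2.5), 3)
  expect_equal(TwinVAE:::roundHalfAway(-2.5), -3)

  expect_error(computeMetrics(1:3, 1:2), "length")
  expect_error(computeMetrics(numeric(0), integer(0)), "empty")
  expect_error(computeMetrics(1, 0), "at least 1")
})

test_that("metrics agree with a brute-force oracle on random sets", {
  set.seed(81)
  for (rep in 1:1000) {
    n <- sample(1:40, 1)
    labels <- sample(1:30, n, replace = TRUE)
    pred <- labels + rnorm(n, 0, 2)
    r <- computeMetrics(pred, labels)
    # independent elementwise reimplementation
    ae <- abs(pred - labels)
    expect_equal(r@mae, sum(ae) / n)
    expect_equal(r@mre, sum(ae / labels) * 100 / n)
    acc <- 0
    for (i in seq_len(n)) {
      ri <- floor(abs(pred[i]) + 0.5) * sign(pred[i])
      if (ri == labels[i]) acc <- acc + 1
    }
    expect_equal(r@accuracy, 100 * acc / n)
    for (l in unique(labels))
      expect_equal(unname(r@perCountMRE[as.character(l)]),
                   mean(ae[labels == l] / l) * 100)
  }
})

test_that("evaluation is deterministic and order-invariant", {
  m <- tinyModel()
  d <- memo("evalSet", function() {
    s <- scaledSets("pc", 20, 20, seedBase = 8101, labeledFraction = 1)
    c(s$natural, s$synthetic)
  })
  r1 <- evaluateModel(m, d)
  r2 <- evaluateModel(m, d)
  expect_identical(r1@mae, r2@mae)
  expect_identical(r1@meanRecLoss, r2@meanRecLoss)
  perm <- withr::with_seed(1, sample(nImages(d)))
  r3 <- evaluateModel(m, d[perm])
  expect_equal(r3@mae, r1@mae)
  expect_equal(r3@mre, r1@mre)
  expect_equal(r3@accuracy, r1@accuracy)
  expect_equal(r3@meanRecLoss, r1@meanRecLoss)
  unl <- d; unl@label[] <- NA_integer_
  expect_error(evaluateModel(m, unl), "labeled")
})

test_that("evaluation reproduces an injected-oracle constant predictor", {
  d <- memo("evalSet", function() {
    s <- scaledSets("pc", 20, 20, seedBase = 8101, labeledFraction = 1)
    c(s$natural, s$synthetic)
  })
  labels <- sampleLabels(d)
  const <- mean(labels)
  r <- computeMetrics(rep(const, length(labels)), labels)
  expect_equal(r@mae, mean(abs(const - labels)))
  expect_equal(r@accuracy,
               100 * mean(TwinVAE:::roundHalfAway(const) == labels))
})

test_that("cross-decoding shares the encoder with the forward path", {
  m <- tinyModel()
  smp <- imageSample(matrix(runif(64^2), 64), 2, "natural", "pc")
  # target == source reduces to the ordinary reconstruction bit-exactly
  own <- crossDecode(m, smp, "natural")
  fwd <- twinForward(m, smp)$reconstruction
  expect_identical(as.vector(own), as.vector(fwd))
  # swapping the decoder yields a valid raster of the same size
  other <- crossDecode(m, smp, "synthetic")
  expect_identical(dim(other), c(64L, 64L))
  expect_true(all(other >= 0 & other <= 1))
  expect_false(identical(own, other))
})

test_that("latent embeddings are seeded and row-aligned", {
  m <- tinyModel()
  d <- memo("evalSet", function() {
    s <- scaledSets("pc", 20, 20, seedBase = 8101, labeledFraction = 1)
    c(s$natural, s$synthetic)
  })
  e1 <- embedDataset(m, d, seed = 5)
  expect_identical(nrow(e1), nImages(d))
  expect_identical(e1$modality, d@modality)
  e2 <- embedDataset(m, d, seed = 5)
  expect_identical(e1$x, e2$x)
  # duplicated input image implies duplicated pre-projection latent code
  codes <- encodeImages(m, c(d[1], d[1]))$mean
  expect_identical(codes[, 1], codes[, 2])
  expect_error(embedDataset(m, d[1:5], seed = 1), "at least 10")
})
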