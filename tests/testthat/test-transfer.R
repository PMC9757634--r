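test_that("freeze masks implement the four schemes", {
  parts <- networkParts()
  outer <- parts[startsWith(parts, "outer_")]
  shared <- c("shared_encoder", "bottleneck", "shared_decoder")

  m <- buildFreezeMask(freezePlan("simultaneous"), 0)
  expect_true(all(m))

  m <- buildFreezeMask(freezePlan("frozen_outer"), 0)
  expect_true(all(!m[outer]))
  expect_true(all(m[shared]))
  expect_true(m[["regressor"]])

  m <- buildFreezeMask(freezePlan("frozen_core"), 0)
  expect_false(m[["shared_encoder"]])
  expect_true(all(!m[shared]))
  expect_true(m[["outer_encoder_natural"]])

  m <- buildFreezeMask(freezePlan("frozen_core", regressorFrozen = TRUE), 0)
  expect_false(m[["regressor"]])

  # thawing: frozen at the start, scheduled parts unfreeze, schedule
  # exhausted means everything trains
  plan <- freezePlan("thawing", maxEpochs = 500)
  expect_true(all(!buildFreezeMask(plan, 0)[outer]))
  expect_true(all(buildFreezeMask(plan, 10000)))

  expect_error(freezePlan("thawing",
    thawSchedule = data.frame(epoch = c(5, 2), part = rep("bottleneck", 2))),
    "increasing")
  expect_error(freezePlan("thawing",
    thawSchedule = data.frame(epoch = 1, part = "no_such_part")),
    "unknown part")
})

test_that("masked steps change exactly the trainable parameters", {
  for (scheme in c("frozen_outer", "frozen_core", "simultaneous", "thawing")) {
    m <- twinVAE(resolution = 32, width = 0.25, seed = 71)
    mask <- buildFreezeMask(freezePlan(scheme, maxEpochs = 100), 0)
    s0 <- getCheckpoint(m)$state
    maskedStep(m, mask, learningRate = 1e-2, weightDecay = 1e-4)
    s1 <- getCheckpoint(m)$state
    for (p in networkParts()) {
      if (mask[[p]]) {
        expect_true(state_changed(s0, s1, p), label = paste(scheme, p))
      } else {
        expect_all_equal_state(s0, s1, p)
      }
    }
  }
})

test_that("gradients flow through frozen outer layers into the shared core", {
  m <- tinyModel()
  set.seed(72)
  x <- matrix(runif(4096 * 4), 4096, 4)
  r <- TwinVAE:::eng_train_batch(m@ptr, x, rep(3, 4), rep(3, 4),
                                 x, rep(2, 4), rep(3, 4),
                                 100, 100, 0L, 0L, 2, 2, 1e-3, 0, 0L,
                                 0.9, 0.999,
                                 unname(buildFreezeMask(freezePlan("frozen_outer"), 0)[networkParts()]),
                                 FALSE)
  gn <- setNames(as.numeric(r$grad_norms), networkParts())
  expect_gt(gn[["shared_encoder"]], 0)
  expect_gt(gn[["bottleneck"]], 0)
  expect_gt(gn[["shared_decoder"]], 0)
})

test_that("frozen-core transfer keeps the shared parts bit-identical", {
  d <- memo("transferSets", function() scaledSets("bf", 32, 32, seedBase = 7301,
                                                  labeledFraction = 1))
  src <- tinyModel()
  ck <- getCheckpoint(src)
  cfg <- scaledTrainConfig(4, seed = 74, regressorDelayEpochs = 0)
  out <- transferTwinVAE(ck, d$natural, d$synthetic,
                         freezePlan("frozen_core"), cfg)
  s1 <- getCheckpoint(out)$state
  expect_all_equal_state(ck$state, s1,
                         c("shared_encoder", "bottleneck", "shared_decoder"))
  expect_true(state_changed(ck$state, s1, "outer_encoder_natural"))
  # the history records what was trainable
  expect_false(grepl("shared_encoder", out@history$trainable[1]))
})

test_that("simultaneous transfer is exactly training from the checkpoint", {
  d <- memo("transferSets", function() scaledSets("bf", 32, 32, seedBase = 7301,
                                                  labeledFraction = 1))
  src <- twinVAE(resolution = 64, width = 0.25, seed = 75)
  ck <- getCheckpoint(src)
  cfg <- scaledTrainConfig(3, seed = 76, regressorDelayEpochs = 0)
  a <- transferTwinVAE(ck, d$natural, d$synthetic,
                       freezePlan("simultaneous"), cfg)
  b <- twinVAEFromCheckpoint(ck, resetOptimizer = TRUE)
  b <- trainTwinVAE(b, d$natural, d$synthetic, cfg)
  expect_identical(getCheckpoint(a)$state, getCheckpoint(b)$state)
  expect_identical(a@history, b@history)
})

test_that("zero-epoch transfers return the source parameters", {
  d <- memo("transferSets", function() scaledSets("bf", 32, 32, seedBase = 7301,
                                                  labeledFraction = 1))
  ck <- getCheckpoint(tinyModel())
  cfg <- scaledTrainConfig(0, seed = 1)
  out <- transferTwinVAE(ck, d$natural, d$synthetic,
                         freezePlan("simultaneous"), cfg)
  expect_identical(getCheckpoint(out)$state, ck$state)
  dd <- doubleTransfer(ck, d$natural, d$synthetic, d$natural, d$synthetic,
                       freezePlan("simultaneous"), cfg)
  expect_identical(getCheckpoint(dd$model)$state, ck$state)
  expect_identical(nrow(dd$history), 0L)
})

test_that("double transfer chains two stages and marks their histories", {
  d <- memo("transferSets", function() scaledSets("bf", 32, 32, seedBase = 7301,
                                                  labeledFraction = 1))
  dA <- memo("transferSetsA", function() scaledSets("pc", 32, 32, seedBase = 7401,
                                                    labeledFraction = 1))
  ck <- getCheckpoint(tinyModel())
  cfg <- scaledTrainConfig(2, seed = 77, regressorDelayEpochs = 0)
  dd <- doubleTransfer(ck, d$natural, d$synthetic, dA$natural, dA$synthetic,
                       freezePlan("simultaneous"), cfg)
  expect_identical(unique(dd$history$stage), c("A_to_B", "B_to_A"))
  expect_identical(nrow(dd$history), 4L)
  expect_true(state_changed(ck$state, getCheckpoint(dd$model)$state,
                            "outer_encoder_natural"))
})
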