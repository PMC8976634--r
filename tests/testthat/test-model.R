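test_that("the built network matches the two-route architecture", {
  m <- buildModel(modelConfig())
  a <- architectureSummary(m)
  expect_equal(a$upperConvLayers, 4)
  expect_equal(a$upperPoolLayers, 1)
  expect_equal(a$lowerConvLayers, 2)
  expect_equal(a$lowerPoolLayers, 1)
  expect_equal(a$concatInputs, 2)
  expect_equal(a$outputUnits, 2)
  expect_equal(a$outputActivation, "softmax")
})

test_that("trainable parameter counts equal the per-layer hand count", {
  cases <- list(
    list(up = c(16L, 16L, 16L, 32L), lo = c(16L, 32L), fc = 32L),
    list(up = c(8L, 8L, 8L, 16L), lo = c(8L, 16L), fc = 12L),
    list(up = c(4L, 5L, 6L, 7L), lo = c(3L, 9L), fc = 5L)
  )
  for (cs in cases) {
    cfg <- modelConfig(upperFilters = cs$up, lowerFilters = cs$lo,
                       fcUnits = cs$fc)
    expect_equal(countParams(buildModel(cfg)),
                 naiveParamCount(3, cs$up, cs$lo, cs$fc))
  }
})

test_that("softmax outputs are probabilities for any input", {
  m <- buildModel(modelConfig(seed = 2))
  p <- suppressWarnings(predict(m, matrix(0, 1, 10)))
  expect_equal(sum(p$prob), 1, tolerance = 1e-12)
  expect_true(all(p$prob >= 0 & p$prob <= 1))
  set.seed(3)
  p2 <- suppressWarnings(predict(m, matrix(runif(50 * 10), 50, 10)))
  expect_equal(unname(rowSums(p2$prob)), rep(1, 50), tolerance = 1e-12)
})

test_that("analytic gradients agree with numerical differentiation", {
  cfg <- modelConfig(upperFilters = c(3L, 3L, 3L, 4L),
                     lowerFilters = c(3L, 4L), fcUnits = 5L, seed = 11)
  m <- buildModel(cfg)
  set.seed(43)
  # jitter all parameters so no ReLU preactivation sits exactly on the
  # kink, where central differences are ill-defined
  w <- lapply(m@weights, function(p) {
    q <- p + stats::rnorm(length(p), 0, 0.05)
    dim(q) <- dim(p)
    q
  })
  set.seed(42)
  X <- matrix(runif(6 * 10), 6, 10)
  Y <- pvcnet:::oneHot(sample(c("PVC", "non-PVC"), 6, replace = TRUE))
  lg <- pvcnet:::nnLossGrad(w, cfg, X, Y)
  for (nm in names(w)) {
    idx <- sample(length(w[[nm]]), min(4, length(w[[nm]])))
    for (i in idx) {
      e <- 1e-5
      wp <- w; wp[[nm]][i] <- wp[[nm]][i] + e
      wm <- w; wm[[nm]][i] <- wm[[nm]][i] - e
      num <- (pvcnet:::nnLossGrad(wp, cfg, X, Y)$loss -
                pvcnet:::nnLossGrad(wm, cfg, X, Y)$loss) / (2 * e)
      expect_equal(unname(lg$grads[[nm]][i]), num, tolerance = 1e-5)
    }
  }
})

makeSeparable <- function(n, seed) {
  set.seed(seed)
  X <- matrix(runif(n * 10), n, 10)
  lab <- ifelse(X[, 8] > 0.5, "PVC", "non-PVC")
  X[, 8] <- ifelse(lab == "PVC", X[, 8] + 0.3, X[, 8] - 0.3)
  X[X < 0] <- 0; X[X > 1] <- 1
  list(X = X, lab = lab)
}

test_that("training reduces the loss on separable features", {
  d <- makeSeparable(600, 101)
  m <- trainModel(buildModel(modelConfig(seed = 0)), d$X, d$lab)
  expect_lt(utils::tail(m@history$loss, 1), m@history$loss[1])
  expect_equal(nrow(m@history), 40)
  # learning-rate schedule: dropped by 0.2 after lrDropPeriod epochs
  expect_equal(m@history$lr[1], 1e-4)
  expect_equal(m@history$lr[21], 2e-5)
})

test_that("identical data and seed give identical trained weights", {
  d <- makeSeparable(300, 102)
  cfg <- modelConfig(maxEpochs = 6L, seed = 5)
  m1 <- trainModel(buildModel(cfg), d$X, d$lab)
  m2 <- trainModel(buildModel(cfg), d$X, d$lab)
  expect_identical(m1@weights, m2@weights)
  expect_identical(m1@history, m2@history)
})

test_that("single-class training sets are rejected naming the missing class", {
  X <- matrix(runif(50 * 10), 50, 10)
  expect_error(trainModel(buildModel(modelConfig()), X,
                          rep("non-PVC", 50)), "PVC")
  expect_error(trainModel(buildModel(modelConfig()), X,
                          rep("PVC", 50)), "non-PVC")
  expect_error(trainModel(buildModel(modelConfig()), X[0, , drop = FALSE],
                          character(0)), "empty")
})

test_that("prediction is invariant to batching", {
  d <- makeSeparable(60, 103)
  cfg <- modelConfig(maxEpochs = 4L, seed = 7)
  m <- trainModel(buildModel(cfg), d$X, d$lab)
  batch <- predict(m, d$X[1:10, ])
  single <- vapply(1:10, function(i)
    predict(m, d$X[i, , drop = FALSE])$label, character(1))
  expect_identical(batch$label, single)
})

test_that("feature vectors of the wrong length raise a shape error", {
  m <- buildModel(modelConfig())
  expect_error(suppressWarnings(predict(m, matrix(0, 2, 7))), "10")
  expect_error(trainModel(m, matrix(0, 5, 7), rep("PVC", 5)), "10")
})

test_that("training on permuted labels stays at chance level", {
  d <- makeSeparable(600, 104)
  set.seed(0)
  permuted <- sample(d$lab[1:400])
  cfg <- modelConfig(maxEpochs = 10L, seed = 0)
  m <- trainModel(buildModel(cfg), d$X[1:400, ], permuted)
  heldTruth <- d$lab[401:600]
  heldPred <- predict(m, d$X[401:600, ])$label
  sens <- mean(heldPred[heldTruth == "PVC"] == "PVC")
  spec <- mean(heldPred[heldTruth == "non-PVC"] == "non-PVC")
  balanced <- (sens + spec) / 2
  expect_gte(balanced, 0.4)
  expect_lte(balanced, 0.6)
})

test_that("a predict on a perfectly fitted example returns its label", {
  d <- makeSeparable(200, 105)
  cfg <- modelConfig(learningRate = 1e-3, maxEpochs = 200L,
                     lrDropPeriod = 100L, seed = 1)
  m <- trainModel(buildModel(cfg), d$X, d$lab)
  fitted <- predict(m, d$X)
  well <- which(abs(fitted$prob[, "PVC"] - (d$lab == "PVC")) < 0.05)
  expect_gt(length(well), 0)
  expect_identical(fitted$label[well], d$lab[well])
})
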