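test_that("statistical features match hand-computed values", {
  # constant series: everything but the mean is zero
  f <- statisticalFeatures(c(800, 800, 800, 800))
  expect_equal(unname(f[c("SDSD", "rMSSD", "SDRR", "pRR10", "pRR50",
                          "Ratio")]), rep(0, 6))
  expect_equal(unname(f["MeanRR"]), 800)

  # single-difference pair
  f <- statisticalFeatures(c(700, 760))
  expect_equal(unname(f["rMSSD"]), 60)
  expect_equal(unname(f["SDSD"]), 0)
  expect_equal(unname(f["pRR10"]), 100)
  expect_equal(unname(f["pRR50"]), 100)
  expect_equal(unname(f["MeanRR"]), 730)
  expect_equal(unname(f["Ratio"]), 60 / 730)

  # four-interval series, frozen from the naive-loop oracle
  f <- statisticalFeatures(c(800, 812, 795, 860))
  expect_equal(unname(f["MeanRR"]), 816.75)
  expect_equal(unname(f["pRR10"]), 100)
  expect_equal(unname(f["pRR50"]), 100 / 3, tolerance = 1e-12)
  expect_equal(unname(f["Ratio"]), 65 / 816.75, tolerance = 1e-12)
  expect_equal(unname(f["rMSSD"]), sqrt(4658 / 3), tolerance = 1e-12)
  expect_equal(unname(f["SDSD"]), sqrt(3458 / 3), tolerance = 1e-12)
  expect_equal(unname(f["SDRR"]), sqrt(2646.75 / 4), tolerance = 1e-12)
})

test_that("statistical features require at least two positive intervals", {
  expect_error(statisticalFeatures(800), "2 RR")
  expect_error(statisticalFeatures(c(800, -5)), "positive")
})

test_that("features agree with the naive-loop oracle on random RR series", {
  set.seed(404)
  for (i in 1:200) {
    rr <- randomRRSeries()
    expect_equal(statisticalFeatures(rr), naiveStatFeatures(rr),
                 tolerance = 1e-9)
  }
})

test_that("pRR10 >= pRR50 and rMSSD >= SDSD on random series", {
  set.seed(405)
  for (i in 1:200) {
    f <- statisticalFeatures(randomRRSeries())
    expect_gte(f[["pRR10"]], f[["pRR50"]])
    expect_gte(f[["rMSSD"]], f[["SDSD"]] - 1e-12)
    # population identity: rMSSD^2 = SDSD^2 + mean(diff)^2
    expect_gte(f[["Ratio"]], 0)
  }
})

test_that("morphological features convert fiducials to width and amplitudes", {
  fid <- data.frame(q = 0, s = 36, rAmp = 1.0, qAmp = -0.1, sAmp = -0.2)
  m <- morphologicalFeatures(fid, fs = 360)
  expect_equal(unname(m["qrs_width"]), 100)
  expect_equal(unname(m["qr_amplitude"]), 1.1)
  expect_equal(unname(m["rs_amplitude"]), 1.2)
  expect_error(morphologicalFeatures(fid[0, ], 360), "fiducial")
})

test_that("PVC-only windows measure the configured wide QRS width", {
  rec <- generateRecord(synthConfig(nBeats = 60, pvcFraction = 1,
                                    allowConsecutive = TRUE, noiseSd = 0,
                                    seed = 31))
  feats <- suppressMessages(extractWindowFeatures(rec))
  expect_true(all(abs(feats$qrs_width - 160) <= 10))
  expect_true(all(feats$label == "PVC"))
})

test_that("window labeling implements the 95% rule on beat fractions", {
  expect_equal(labelWindow(rep(TRUE, 20)), "PVC")
  expect_equal(labelWindow(c(rep(TRUE, 19), FALSE)), "PVC")      # 95%
  expect_equal(labelWindow(c(rep(TRUE, 18), FALSE, FALSE)), "non-PVC")
  expect_error(labelWindow(logical(0)), "no beats")
})

test_that("window labels are invariant to beat order", {
  set.seed(77)
  for (i in 1:50) {
    v <- runif(sample(5:40, 1)) < runif(1)
    expect_equal(labelWindow(v), labelWindow(sample(v)))
  }
})

test_that("segmentation drops partial windows and sparse windows", {
  rec <- generateRecord(synthConfig(nBeats = 400, pvcFraction = 0, seed = 41))
  wins <- segmentWindows(rec)
  # ~25 beats per 20 s window at mean RR 800 ms
  perWin <- vapply(wins, function(w) length(w$beatRows), integer(1))
  expect_true(all(perWin >= 20 & perWin <= 30))
  expect_lte(sum(perWin), 400)
  # a record shorter than one window yields nothing
  short <- generateRecord(synthConfig(nBeats = 5, pvcFraction = 0, seed = 42))
  expect_length(segmentWindows(short), 0)
})

test_that("every beat is assigned to the window containing its R sample", {
  rec <- generateRecord(synthConfig(nBeats = 300, pvcFraction = 0.2,
                                    seed = 43))
  wins <- segmentWindows(rec)
  ann <- beatAnnotations(rec)
  for (w in wins) {
    s <- ann$sample[w$beatRows]
    expect_true(all(s >= w$startSample & s <= w$endSample))
  }
})

test_that("min-max normalization maps the training range onto [0, 1] exactly", {
  df <- as.data.frame(stats::setNames(rep(list(c(2, 4, 10)), 10),
                                      pvcFeatureNames()))
  params <- fitNormalization(df)
  expect_equal(unname(params@fmin), rep(2, 10))
  expect_equal(unname(params@fmax), rep(10, 10))
  n <- applyNormalization(df, params)
  expect_equal(unname(n[1, ]), rep(0, 10))     # FV = Fmin -> 0
  expect_equal(unname(n[3, ]), rep(1, 10))     # FV = Fmax -> 1
  mid <- df[1, ]; mid[1, ] <- 6                # midpoint -> 0.5 exactly
  expect_equal(unname(applyNormalization(mid, params)[1, ]), rep(0.5, 10))
})

test_that("degenerate features are flagged and map to zero", {
  df <- as.data.frame(stats::setNames(rep(list(c(5, 5)), 10),
                                      pvcFeatureNames()))
  params <- fitNormalization(df)
  expect_true(all(params@degenerate))
  expect_equal(unname(applyNormalization(df, params)[1, ]), rep(0, 10))
})

test_that("refitting normalization on the same data is deterministic", {
  set.seed(55)
  df <- as.data.frame(stats::setNames(
    lapply(1:10, function(i) runif(20)), pvcFeatureNames()))
  expect_equal(fitNormalization(df), fitNormalization(df))
})

test_that("test-time values outside the training range are clipped to [0, 1]", {
  set.seed(56)
  train <- as.data.frame(stats::setNames(
    lapply(1:10, function(i) runif(30)), pvcFeatureNames()))
  test <- as.data.frame(stats::setNames(
    lapply(1:10, function(i) runif(30, -1, 2)), pvcFeatureNames()))
  params <- fitNormalization(train)
  expect_true(all(applyNormalization(train, params) >= 0 &
                    applyNormalization(train, params) <= 1))
  nt <- applyNormalization(test, params)
  expect_true(all(nt >= 0 & nt <= 1))
})

test_that("extracted feature tables carry labels consistent with beat fractions", {
  rec <- generateRecord(synthConfig(nBeats = 500, pvcFraction = 0.5,
                                    allowConsecutive = TRUE, seed = 57))
  feats <- suppressMessages(extractWindowFeatures(rec))
  expect_identical(feats$label,
                   ifelse(feats$pvcBeatFraction >= 0.95, "PVC", "non-PVC"))
  expect_identical(names(feats)[3:12], pvcFeatureNames())
})
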