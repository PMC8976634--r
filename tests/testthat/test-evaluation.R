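test_that("confusion counts handle perfect and degenerate predictors", {
  cc <- confusionCounts(c("PVC", "PVC", "non-PVC", "non-PVC"),
                        c("PVC", "PVC", "non-PVC", "non-PVC"))
  expect_equal(cc, c(TP = 2L, FP = 0L, TN = 2L, FN = 0L))
  truth <- c(rep("PVC", 3), rep("non-PVC", 7))
  cc <- confusionCounts(rep("non-PVC", 10), truth)
  expect_equal(cc, c(TP = 0L, FP = 0L, TN = 7L, FN = 3L))
  expect_error(confusionCounts("PVC", c("PVC", "PVC")), "equal length")
})

test_that("confusion counts match a brute-force tally on random labels", {
  set.seed(909)
  for (i in 1:20) {
    pred <- sample(c("PVC", "non-PVC"), 100, replace = TRUE)
    truth <- sample(c("PVC", "non-PVC"), 100, replace = TRUE)
    expect_equal(confusionCounts(pred, truth), naiveConfusion(pred, truth))
  }
})

test_that("metrics implement precision, recall and their harmonic mean", {
  m <- computeMetrics(c(TP = 100L, FP = 0L, TN = 5L, FN = 0L))
  expect_equal(m$ppv, 100)
  expect_equal(m$recall, 100)
  expect_equal(m$fScore, 100)
  m <- computeMetrics(c(TP = 30L, FP = 10L, TN = 50L, FN = 10L))
  expect_equal(m$ppv, 75)
  expect_equal(m$recall, 75)
  expect_equal(m$fScore, 75)
})

test_that("zero-denominator metrics are reported undefined, never 0 or 100", {
  m <- computeMetrics(c(TP = 0L, FP = 0L, TN = 10L, FN = 2L))
  expect_true(is.na(m$ppv))
  expect_equal(m$recall, 0)
  expect_true("ppv" %in% m$undefined)
  m <- computeMetrics(c(TP = 0L, FP = 3L, TN = 10L, FN = 0L))
  expect_true(is.na(m$recall))
  expect_true("recall" %in% m$undefined)
})

test_that("F-score reproduces the published per-record values to 1 d.p.", {
  expect_equal(round(fMeasure(99.5, 100), 1), 99.7)
  expect_equal(round(fMeasure(95.4, 94.3), 1), 94.8)
  expect_equal(round(fMeasure(98.7, 96.3), 1), 97.5)
  expect_equal(round(fMeasure(97.5, 94.1), 1), 95.8)
})

test_that("F-score is symmetric, bounded by the arithmetic mean, idempotent on equals", {
  set.seed(910)
  for (i in 1:50) {
    p <- runif(1, 1, 100); r <- runif(1, 1, 100)
    expect_equal(fMeasure(p, r), fMeasure(r, p))
    expect_lte(fMeasure(p, r), (p + r) / 2 + 1e-12)
    x <- runif(1, 1, 100)
    expect_equal(fMeasure(x, x), x)
  }
  expect_true(is.na(fMeasure(0, 0)))
})

test_that("per-record report pools counts additively and micro equals pooled", {
  set.seed(911)
  ids <- rep(c("recA", "recB", "recC"), each = 40)
  truth <- sample(c("PVC", "non-PVC"), 120, replace = TRUE, prob = c(.4, .6))
  pred <- ifelse(runif(120) < 0.8, truth,
                 ifelse(truth == "PVC", "non-PVC", "PVC"))
  rep_ <- perRecordReport(ids, pred, truth)
  pr <- rep_@perRecord
  expect_equal(sum(pr$TP) + sum(pr$FP) + sum(pr$TN) + sum(pr$FN), 120)
  pooled <- confusionCounts(pred, truth)
  expect_equal(unname(rep_@counts), unname(pooled))
  # micro metrics equal metrics of the summed per-record counts
  summed <- c(TP = sum(pr$TP), FP = sum(pr$FP), TN = sum(pr$TN),
              FN = sum(pr$FN))
  expect_equal(rep_@micro$ppv, computeMetrics(summed)$ppv)
  expect_equal(rep_@micro$fScore, computeMetrics(summed)$fScore)
  # two records with identical counts produce identical rows
  r2 <- perRecordReport(rep(c("x", "y"), each = 40),
                        rep(pred[1:40], 2), rep(truth[1:40], 2))
  expect_equal(r2@perRecord$fScore[1], r2@perRecord$fScore[2])
})

test_that("records without PVC truth windows are excluded from per-record rows", {
  ids <- rep(c("hasPvc", "noPvc"), each = 10)
  truth <- c(rep("PVC", 5), rep("non-PVC", 15))
  pred <- truth
  expect_message(rep_ <- perRecordReport(ids, pred, truth), "noPvc")
  expect_equal(rep_@perRecord$recordId, "hasPvc")
  # pooled counts still include the skipped record's windows
  expect_equal(sum(rep_@counts), 20L)
})

test_that("F lies between PPV and recall in every report row", {
  set.seed(912)
  ids <- rep(c("r1", "r2"), each = 50)
  truth <- sample(c("PVC", "non-PVC"), 100, replace = TRUE)
  pred <- ifelse(runif(100) < 0.7, truth, sample(c("PVC", "non-PVC"), 100,
                                                 replace = TRUE))
  rep_ <- perRecordReport(ids, pred, truth)
  for (i in seq_len(nrow(rep_@perRecord))) {
    row <- rep_@perRecord[i, ]
    expect_gte(row$fScore, min(row$ppv, row$recall) - 1e-9)
    expect_lte(row$fScore, max(row$ppv, row$recall) + 1e-9)
  }
})
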