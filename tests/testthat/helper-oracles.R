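# Independent naive-loop oracles used to cross-check the vectorized
# implementations. Deliberately written with explicit loops and without
# reference to package internals.

naiveStatFeatures <- function(rr) {
  n <- length(rr)
  m <- 0
  for (x in rr) m <- m + x
  m <- m / n
  v <- 0
  for (x in rr) v <- v + (x - m)^2
  sdrr <- sqrt(v / n)
  d <- numeric(n - 1)
  for (i in seq_len(n - 1)) d[i] <- rr[i + 1] - rr[i]
  md <- 0
  for (x in d) md <- md + x
  md <- md / length(d)
  vd <- 0; sq <- 0; n10 <- 0; n50 <- 0
  for (x in d) {
    vd <- vd + (x - md)^2
    sq <- sq + x^2
    if (abs(x) > 10) n10 <- n10 + 1
    if (abs(x) > 50) n50 <- n50 + 1
  }
  mx <- rr[1]; mn <- rr[1]
  for (x in rr) { if (x > mx) mx <- x; if (x < mn) mn <- x }
  c(SDSD = sqrt(vd / length(d)),
    Ratio = (mx - mn) / m,
    rMSSD = sqrt(sq / length(d)),
    SDRR = sdrr,
    pRR10 = 100 * n10 / length(d),
    pRR50 = 100 * n50 / length(d),
    MeanRR = m)
}

naiveConfusion <- function(pred, truth) {
  tp <- 0L; fp <- 0L; tn <- 0L; fn <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] == "PVC" && truth[i] == "PVC") tp <- tp + 1L
    if (pred[i] == "PVC" && truth[i] != "PVC") fp <- fp + 1L
    if (pred[i] != "PVC" && truth[i] != "PVC") tn <- tn + 1L
    if (pred[i] != "PVC" && truth[i] == "PVC") fn <- fn + 1L
  }
  c(TP = tp, FP = fp, TN = tn, FN = fn)
}

# per-layer parameter arithmetic, independent of the implementation:
# conv: taps * inChannels * filters + filters; fc: in * out + out
naiveParamCount <- function(k, upperFilters, lowerFilters, fcUnits,
                            inputLength = 10, poolSize = 2) {
  total <- 0
  cin <- 1
  len <- inputLength
  for (i in seq_along(upperFilters)) {
    total <- total + k * cin * upperFilters[i] + upperFilters[i]
    cin <- upperFilters[i]
    if (i <= 3) len <- len else len <- len - k + 1   # first three padded
  }
  upLen <- floor((inputLength - k + 1) / poolSize)   # only conv4 unpadded
  cin <- 1
  loLen <- inputLength
  for (i in seq_along(lowerFilters)) {
    total <- total + k * cin * lowerFilters[i] + lowerFilters[i]
    cin <- lowerFilters[i]
    loLen <- loLen - k + 1
  }
  loLen <- floor(loLen / poolSize)
  concat <- upLen * upperFilters[length(upperFilters)] +
    loLen * lowerFilters[length(lowerFilters)]
  total <- total + concat * fcUnits + fcUnits
  total <- total + fcUnits * 2 + 2
  total
}

randomRRSeries <- function() {
  n <- sample(2:40, 1)
  round(stats::runif(n, 300, 1500), 3)
}
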