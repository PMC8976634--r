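# Windowed feature extraction: 20 s segmentation, seven RR-interval
# statistics, three QRS morphology features, the 95 % PVC labeling rule and
# min-max normalization.

#' Segment a record into fixed-length windows
#'
#' Consecutive non-overlapping windows of \code{windowS} seconds anchored
#' at the record start; the final partial window is discarded. A beat
#' belongs to the window containing its R sample. Windows with fewer than
#' \code{minBeats} beats (too few RR intervals for the statistics) are
#' dropped with a message.
#'
#' @param record an \linkS4class{ECGRecord}.
#' @param windowS window length in seconds.
#' @param minBeats minimum beats a window must contain (default 3, i.e. at
#'   least 2 RR intervals).
#' @return A list of windows, each a list with \code{windowIndex}
#'   (0-based), \code{startSample}, \code{endSample} and \code{beatRows}
#'   (row indices into the annotation table).
#' @export
segmentWindows <- function(record, windowS = 20, minBeats = 3L) {
  stopifnot(is(record, "ECGRecord"))
  ann <- record@annotations
  if (!nrow(ann)) stop("record has no annotated beats")
  wLen <- record@fs * windowS
  nWin <- floor(nrow(record@signal) / wLen)
  if (nWin < 1L) return(list())
  winOf <- floor((ann$sample - 1L) / wLen)      # 0-based window index
  out <- vector("list", nWin)
  dropped <- 0L
  for (k in seq_len(nWin) - 1L) {
    rows <- which(winOf == k)
    if (length(rows) < minBeats) { dropped <- dropped + 1L; next }
    out[[k + 1L]] <- list(windowIndex = k,
                          startSample = as.integer(k * wLen) + 1L,
                          endSample = as.integer((k + 1L) * wLen),
                          beatRows = rows)
  }
  if (dropped)
    message(sprintf("record %s: dropped %d window(s) with < %d beats",
                    record@recordId, dropped, minBeats))
  out[!vapply(out, is.null, logical(1))]
}

#' Seven time-domain RR-interval statistics
#'
#' Given the RR intervals of one window (ms), computes MeanRR, SDRR
#' (population SD of the intervals), SDSD (population SD of the successive
#' differences), rMSSD (root mean square of the successive differences),
#' pRR10 and pRR50 (percentage of successive differences with magnitude
#' strictly greater than 10 ms / 50 ms) and Ratio ((max - min) / MeanRR).
#' Population formulas keep the identity
#' rMSSD^2 = SDSD^2 + mean(diff)^2 exact, which implies rMSSD >= SDSD.
#'
#' @param intervals numeric vector of RR intervals in ms (>= 2 values).
#' @return Named numeric vector: SDSD, Ratio, rMSSD, SDRR, pRR10, pRR50,
#'   MeanRR.
#' @examples
#' statisticalFeatures(c(800, 812, 795, 860))
#' @export
statisticalFeatures <- function(intervals) {
  if (length(intervals) < 2L)
    stop("at least 2 RR intervals are required")
  if (any(intervals <= 0)) stop("RR intervals must be positive")
  d <- diff(intervals)
  popSd <- function(v) sqrt(mean((v - mean(v))^2))
  meanRR <- mean(intervals)
  c(SDSD = popSd(d),
    Ratio = (max(intervals) - min(intervals)) / meanRR,
    rMSSD = sqrt(mean(d^2)),
    SDRR = popSd(intervals),
    pRR10 = 100 * mean(abs(d) > 10),
    pRR50 = 100 * mean(abs(d) > 50),
    MeanRR = meanRR)
}

#' Three QRS morphology features of a window
#'
#' Per beat: QRS width = (s - q) in ms, QR amplitude = R - Q amplitude, RS
#' amplitude = R - S amplitude; the window value is the mean over its
#' beats.
#'
#' @param fiducials data.frame with columns \code{q}, \code{s},
#'   \code{rAmp}, \code{qAmp}, \code{sAmp} (one row per beat).
#' @param fs sampling rate, Hz.
#' @return Named numeric vector: qrs_width (ms), qr_amplitude (mV),
#'   rs_amplitude (mV).
#' @export
morphologicalFeatures <- function(fiducials, fs) {
  if (is.null(fiducials) || nrow(fiducials) == 0L)
    stop("no valid fiducials in window")
  c(qrs_width = mean((fiducials$s - fiducials$q) * 1000 / fs),
    qr_amplitude = mean(fiducials$rAmp - fiducials$qAmp),
    rs_amplitude = mean(fiducials$rAmp - fiducials$sAmp))
}

#' Label a window PVC or non-PVC
#'
#' A window is labeled PVC when at least \code{threshold} (default 95 %) of
#' its beats are PVC beats; otherwise non-PVC.
#'
#' @param isPvc logical vector, one value per beat in the window.
#' @param threshold required PVC beat fraction.
#' @return "PVC" or "non-PVC".
#' @examples
#' labelWindow(c(rep(TRUE, 19), FALSE))  # 19/20 PVC beats -> "PVC"
#' @export
labelWindow <- function(isPvc, threshold = 0.95) {
  if (!length(isPvc)) stop("window contains no beats")
  if (mean(isPvc) >= threshold) "PVC" else "non-PVC"
}

#' Extract the per-window feature table of a record
#'
#' Runs segmentation, RR statistics, fiducial-based morphology and the
#' 95 % labeling rule over one record. RR intervals are computed only
#' between beats inside the same window. Beats without usable fiducials
#' (too close to the record boundary) contribute to the RR statistics and
#' the label but not to the morphology means; windows with no usable
#' fiducials at all are dropped with a message.
#'
#' @param record an \linkS4class{ECGRecord}.
#' @param windowS window length, seconds.
#' @param pvcThreshold PVC beat fraction required for a PVC label.
#' @param align align annotated R indices to the local signal maximum.
#' @return data.frame with columns recordId, windowIndex, the ten features
#'   of \code{\link{pvcFeatureNames}}, label, nBeats, pvcBeatFraction.
#' @export
extractWindowFeatures <- function(record, windowS = 20, pvcThreshold = 0.95,
                                  align = TRUE) {
  wins <- segmentWindows(record, windowS)
  if (!length(wins)) {
    return(emptyFeatureFrame())
  }
  fid <- beatFiducials(record, align = align)
  ann <- record@annotations
  rows <- vector("list", length(wins))
  droppedMorph <- 0L
  for (i in seq_along(wins)) {
    w <- wins[[i]]
    beats <- ann[w$beatRows, , drop = FALSE]
    rr <- diff(beats$sample) * 1000 / record@fs
    stat <- statisticalFeatures(rr)
    f <- fid[fid$beat %in% w$beatRows, , drop = FALSE]
    if (!nrow(f)) { droppedMorph <- droppedMorph + 1L; next }
    morph <- morphologicalFeatures(f, record@fs)
    rows[[i]] <- data.frame(
      recordId = record@recordId, windowIndex = w$windowIndex,
      as.list(c(stat, morph)),
      label = labelWindow(beats$isPvc, pvcThreshold),
      nBeats = nrow(beats), pvcBeatFraction = mean(beats$isPvc),
      stringsAsFactors = FALSE)
  }
  if (droppedMorph)
    message(sprintf("record %s: dropped %d window(s) without fiducials",
                    record@recordId, droppedMorph))
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(emptyFeatureFrame())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("recordId", "windowIndex", pvcFeatureNames(), "label",
          "nBeats", "pvcBeatFraction")]
}

emptyFeatureFrame <- function() {
  cols <- c(list(recordId = character(0), windowIndex = integer(0)),
            stats::setNames(rep(list(numeric(0)), 10), pvcFeatureNames()),
            list(label = character(0), nBeats = integer(0),
                 pvcBeatFraction = numeric(0)))
  do.call(data.frame, c(cols, stringsAsFactors = FALSE))
}

#' Fit min-max normalization on training windows
#'
#' Learns the per-feature minimum and maximum over the training windows
#' only; test data are later scaled with these frozen parameters. Features
#' with a degenerate training range (max == min) are flagged.
#'
#' @param trainFeatures data.frame containing the ten feature columns.
#' @return A \linkS4class{NormalizationParams}.
#' @export
fitNormalization <- function(trainFeatures) {
  fn <- pvcFeatureNames()
  if (!all(fn %in% names(trainFeatures)))
    stop("trainFeatures must contain the ten feature columns")
  if (nrow(trainFeatures) < 2L)
    stop("at least 2 training windows are required")
  m <- as.matrix(trainFeatures[, fn])
  fmin <- apply(m, 2, min)
  fmax <- apply(m, 2, max)
  new("NormalizationParams", fmin = fmin, fmax = fmax,
      degenerate = fmax == fmin)
}

#' Apply min-max normalization
#'
#' Maps each feature value FV to (FV - Fmin) / (Fmax - Fmin) and clips the
#' result to [0, 1], so test-time values outside the training range stay in
#' the classifier's input domain. Degenerate features map to 0.
#'
#' @param features data.frame with the ten feature columns, or a numeric
#'   matrix with those columns.
#' @param params a \linkS4class{NormalizationParams}.
#' @return Numeric matrix (windows x 10) with values in [0, 1].
#' @export
applyNormalization <- function(features, params) {
  stopifnot(is(params, "NormalizationParams"))
  fn <- pvcFeatureNames()
  m <- if (is.data.frame(features)) as.matrix(features[, fn])
       else features[, fn, drop = FALSE]
  rng <- params@fmax - params@fmin
  out <- sweep(m, 2, params@fmin[fn])
  out <- sweep(out, 2, ifelse(rng[fn] == 0, 1, rng[fn]), "/")
  out[, params@degenerate[fn]] <- 0
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}
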