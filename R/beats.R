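# R-peak detection and Q/S fiducial location.
#
# The detector is Pan-Tompkins style: 5-15 Hz band-pass, derivative,
# squaring, 150 ms moving-window integration, adaptive signal/noise
# thresholds with a 200 ms refractory period. On annotated databases the
# annotated R indices are preferred (aligned to the local signal maximum).

#' Detect R peaks in a single-lead ECG
#'
#' Pan-Tompkins style QRS detection. Returns strictly increasing sample
#' indices of R peaks, at least 200 ms apart. A flat (constant) signal
#' yields an empty result.
#'
#' @param x numeric vector, single-lead ECG in mV.
#' @param fs sampling rate, Hz.
#' @return Integer vector of R-peak sample indices.
#' @examples
#' rec <- generateRecord(synthConfig(nBeats = 20, pvcFraction = 0, seed = 2))
#' peaks <- detectRPeaks(ecgSignal(rec)[, 1], sampFreq(rec))
#' @export
detectRPeaks <- function(x, fs) {
  if (length(x) < 2 * fs)
    stop("signal must be at least 2 s long")
  if (stats::sd(x) == 0) return(integer(0))

  bp <- signal::butter(3, c(5, 15) / (fs / 2), type = "pass")
  xf <- signal::filtfilt(bp, x - mean(x))
  # Pan-Tompkins five-point derivative, then squaring
  dv <- stats::filter(xf, c(2, 1, 0, -1, -2) / 8, sides = 2)
  dv[is.na(dv)] <- 0
  sq <- as.numeric(dv)^2
  nInt <- max(3L, msSamples(150, fs))
  integ <- stats::filter(sq, rep(1 / nInt, nInt), sides = 2)
  integ[is.na(integ)] <- 0
  integ <- as.numeric(integ)

  # candidate local maxima of the integrated energy
  cand <- which(diff(sign(diff(integ))) < 0) + 1L
  cand <- cand[integ[cand] > 0]
  if (!length(cand)) return(integer(0))

  refr <- msSamples(200, fs)
  spki <- max(integ[seq_len(min(length(integ), 2L * as.integer(fs)))]) / 2
  npki <- mean(integ[seq_len(min(length(integ), 2L * as.integer(fs)))]) / 2
  accepted <- integer(0)
  lastQrs <- -refr
  for (i in cand) {
    thr <- npki + 0.25 * (spki - npki)
    if (integ[i] >= thr && (i - lastQrs) > refr) {
      accepted <- c(accepted, i)
      lastQrs <- i
      spki <- 0.125 * integ[i] + 0.875 * spki
    } else {
      npki <- 0.125 * integ[i] + 0.875 * npki
    }
  }
  if (!length(accepted)) return(integer(0))

  # refine each detection to the raw-signal maximum within +/-100 ms
  half <- msSamples(100, fs)
  r <- vapply(accepted, function(i) {
    lo <- max(1L, i - half); hi <- min(length(x), i + half)
    lo + which.max(x[lo:hi]) - 1L
  }, integer(1))
  r <- unique(r)
  keep <- c(TRUE, diff(r) > refr)
  r[keep]
}

#' Align annotated R indices to the local signal maximum
#'
#' Annotation R positions can be a few samples off the sampled waveform
#' maximum; each index is moved to the signal maximum within a +/-tol
#' sample neighbourhood.
#'
#' @param x single-lead signal, mV.
#' @param annSamples integer vector of annotated R sample indices.
#' @param tol half-width of the search neighbourhood in samples
#'   (default 36, i.e. 100 ms at 360 Hz).
#' @return Integer vector of aligned indices.
#' @export
alignRPeaks <- function(x, annSamples, tol = 36L) {
  vapply(annSamples, function(i) {
    lo <- max(1L, i - tol); hi <- min(length(x), i + tol)
    lo + which.max(x[lo:hi]) - 1L
  }, integer(1))
}

# argmin over x[lo:hi]; returns index into x
argminIn <- function(x, lo, hi) lo + which.min(x[lo:hi]) - 1L

#' Locate Q and S fiducials around an R peak
#'
#' The Q fiducial is the signal minimum in the interval before the R peak
#' and the S fiducial the minimum after it. A half-window of 80 ms is
#' searched first (covers a normal, sub-120 ms QRS); when the minimum lands
#' on the window edge — the trough lies beyond, as for a wide ventricular
#' complex — the search widens to 150 ms. Search windows are clipped so
#' they never cross the adjacent R peaks.
#'
#' @param x single-lead signal, mV.
#' @param fs sampling rate, Hz.
#' @param rIndex sample index of the R peak.
#' @param prevR,nextR sample indices of the neighbouring R peaks (optional).
#' @param halfMs,wideMs normal and widened search half-windows, ms.
#' @return A list with \code{q}, \code{s} (sample indices) and \code{rAmp},
#'   \code{qAmp}, \code{sAmp} (mV).
#' @export
locateQS <- function(x, fs, rIndex, prevR = NULL, nextR = NULL,
                     halfMs = 80, wideMs = 150) {
  half <- msSamples(halfMs, fs)
  wide <- msSamples(wideMs, fs)
  if (rIndex - half < 1L || rIndex + half > length(x))
    stop("R peak too close to the record boundary for fiducial search")

  loLim <- if (!is.null(prevR)) prevR + 1L else 1L
  hiLim <- if (!is.null(nextR)) nextR - 1L else length(x)

  searchSide <- function(before) {
    win <- function(h) {
      if (before) c(max(loLim, rIndex - h), rIndex - 1L)
      else c(rIndex + 1L, min(hiLim, rIndex + h))
    }
    w <- win(half)
    idx <- argminIn(x, w[1], w[2])
    atEdge <- if (before) idx <= w[1] else idx >= w[2]
    if (atEdge) {
      w <- win(wide)
      w[1] <- max(1L, w[1]); w[2] <- min(length(x), w[2])
      idx <- argminIn(x, w[1], w[2])
    }
    idx
  }
  q <- searchSide(TRUE)
  s <- searchSide(FALSE)
  list(q = q, s = s, rAmp = x[rIndex], qAmp = x[q], sAmp = x[s])
}

# Fiducials for every usable beat of a record. Beats whose search window
# would cross the record boundary are skipped.
beatFiducials <- function(record, align = TRUE, lead = 1L) {
  x <- record@signal[, lead]
  fs <- record@fs
  ann <- record@annotations
  if (!nrow(ann)) {
    return(data.frame(beat = integer(0), r = integer(0), q = integer(0),
                      s = integer(0), rAmp = numeric(0), qAmp = numeric(0),
                      sAmp = numeric(0)))
  }
  r <- if (align) alignRPeaks(x, ann$sample, tol = msSamples(100, fs))
       else ann$sample
  margin <- msSamples(150, fs)
  out <- vector("list", length(r))
  for (i in seq_along(r)) {
    if (r[i] - margin < 1L || r[i] + margin > length(x)) next
    f <- locateQS(x, fs, r[i],
                  prevR = if (i > 1L) r[i - 1L] else NULL,
                  nextR = if (i < length(r)) r[i + 1L] else NULL)
    out[[i]] <- data.frame(beat = i, r = r[i], q = f$q, s = f$s,
                           rAmp = f$rAmp, qAmp = f$qAmp, sAmp = f$sAmp)
  }
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}
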