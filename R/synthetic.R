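# Synthetic annotated single-lead ECG with controllable PVC burden.
#
# Each beat is a sum of Gaussian wavelets. Normal beats carry P, Q, R, S, T
# deflections; PVC beats drop the P wave, double the QRS wavelet widths
# (wide, bizarre ventricular complex), perturb the Q/R/S amplitudes by up to
# +/-20 % and carry an enlarged inverted T wave. A PVC shortens its
# preceding RR interval (prematurity) and lengthens the following one
# (compensatory pause).

# Gaussian wavelet parameters relative to the R peak. Offsets of Q and S are
# +/- width/2 so the Q-to-S fiducial distance equals the configured QRS
# width; wavelet sigmas scale with the width so the troughs stay
# identifiable.
beatTemplate <- function(isPvc, qrsWidth, ampScale = 1) {
  half <- qrsWidth / 2
  if (!isPvc) {
    data.frame(
      wave   = c("P", "Q", "R", "S", "T"),
      offset = c(-200, -half, 0, half, 300),
      amp    = c(0.15, -0.10, 1.00, -0.20, 0.30),
      sigma  = c(25, qrsWidth * 0.125, qrsWidth * 0.15, qrsWidth * 0.125, 60)
    )
  } else {
    data.frame(
      wave   = c("Q", "R", "S", "T"),
      offset = c(-half, 0, half, 300),
      amp    = c(-0.10, 1.00, -0.20, 0) * ampScale + c(0, 0, 0, -0.45),
      sigma  = c(qrsWidth * 0.125, qrsWidth * 0.15, qrsWidth * 0.125, 80)
    )
  }
}

# Add one wavelet (per-beat centers/amplitudes) into the signal, vectorized
# over beats for each sample offset.
addWavelet <- function(sig, centers, amps, sigmaSamp, halfSupport) {
  n <- length(sig)
  for (off in (-halfSupport):halfSupport) {
    idx <- centers + off
    ok <- idx >= 1L & idx <= n
    if (!any(ok)) next
    sig[idx[ok]] <- sig[idx[ok]] +
      amps[ok] * exp(-off^2 / (2 * sigmaSamp^2))
  }
  sig
}

#' Generate a synthetic annotated ECG record
#'
#' Produces a single-lead ECG at the configured sampling rate with exactly
#' \code{nBeats} annotated beats ('N' normal, 'V' PVC). PVC placement is
#' i.i.d. Bernoulli with probability \code{pvcFraction}; unless
#' \code{allowConsecutive} is set, a beat directly following a PVC is forced
#' normal. A PVC's preceding RR interval is multiplied by
#' \code{pvcPrematurity} and the following one by
#' \code{compensatoryFactor}. The ground-truth R-wave sample index of every
#' beat is stored as the annotation sample. Identical configs (including
#' seed) give bit-identical output.
#'
#' @param config a \linkS4class{SynthConfig}.
#' @param recordId identifier of the generated record.
#' @return An \linkS4class{ECGRecord} with one lead named "synthI".
#' @examples
#' rec <- generateRecord(synthConfig(nBeats = 30, pvcFraction = 0.2, seed = 4))
#' table(beatAnnotations(rec)$symbol)
#' @export
generateRecord <- function(config, recordId = sprintf("synth-%d", config@seed)) {
  stopifnot(is(config, "SynthConfig"))
  validObject(config)
  withSeed(config@seed, {
    n <- config@nBeats
    fs <- config@fs

    isPvc <- stats::runif(n) < config@pvcFraction
    if (!config@allowConsecutive && n > 1L) {
      for (i in 2:n) if (isPvc[i - 1L] && isPvc[i]) isPvc[i] <- FALSE
    }

    # RR interval preceding beat i (i >= 2), ms; multiplicative prematurity
    # and compensatory-pause factors keep consecutive PVCs unambiguous.
    rr <- config@meanRR + stats::rnorm(n - 1L, 0, config@rrJitterSd)
    rr <- pmax(rr, 250)   # physiological floor
    fac <- rep(1, n - 1L)
    fac[isPvc[-1L]] <- fac[isPvc[-1L]] * config@pvcPrematurity
    fac[isPvc[-n]] <- fac[isPvc[-n]] * config@compensatoryFactor
    rr <- rr * fac

    rTimes <- config@meanRR + c(0, cumsum(rr))          # ms from record start
    rIdx <- msSamples(rTimes, fs) + 1L
    nSamp <- max(rIdx) + msSamples(600, fs)

    sig <- numeric(nSamp)
    ampScale <- stats::runif(n, 0.8, 1.2)               # used for PVC beats
    for (pvc in c(FALSE, TRUE)) {
      sel <- which(isPvc == pvc)
      if (!length(sel)) next
      width <- if (pvc) config@pvcQrsWidth else config@normalQrsWidth
      tpl <- beatTemplate(pvc, width)
      for (w in seq_len(nrow(tpl))) {
        centers <- rIdx[sel] + msSamples(tpl$offset[w], fs)
        amps <- rep(tpl$amp[w], length(sel))
        if (pvc && tpl$wave[w] %in% c("Q", "R", "S"))
          amps <- tpl$amp[w] * ampScale[sel]
        sSamp <- tpl$sigma[w] * fs / 1000
        sig <- addWavelet(sig, centers, amps, sSamp,
                          halfSupport = as.integer(ceiling(4 * sSamp)))
      }
    }
    if (config@noiseSd > 0)
      sig <- sig + stats::rnorm(nSamp, 0, config@noiseSd)

    ann <- data.frame(
      sample = rIdx,
      symbol = ifelse(isPvc, "V", "N"),
      aamiClass = ifelse(isPvc, "V", "N"),
      isPvc = isPvc,
      stringsAsFactors = FALSE
    )
    ECGRecord(recordId, fs, matrix(sig, ncol = 1L), ann, leads = "synthI")
  })
}
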