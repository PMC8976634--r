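#' @import methods
NULL

#' Canonical window-feature column order
#'
#' The fixed 10-column feature order used throughout the package: seven
#' RR-interval statistics followed by three QRS morphology features.
#'
#' @return Character vector of the ten feature names.
#' @export
pvcFeatureNames <- function() {
  c("SDSD", "Ratio", "rMSSD", "SDRR", "pRR10", "pRR50", "MeanRR",
    "qrs_width", "qr_amplitude", "rs_amplitude")
}

#' SynthConfig: parameters of the synthetic ECG generator
#'
#' Describes one synthetic single-lead record: beat count, PVC burden,
#' sampling rate, RR-interval statistics, QRS widths of the two beat types,
#' the prematurity/compensatory-pause multipliers and the additive noise
#' level. PVC beats must have QRS width of at least 120 ms and normal beats
#' below 120 ms, matching the clinical definition of a wide ventricular
#' complex.
#'
#' @slot nBeats number of annotated beats to generate.
#' @slot pvcFraction per-beat PVC probability in [0, 1].
#' @slot fs sampling rate in Hz.
#' @slot meanRR mean RR interval of the underlying sinus rhythm, ms.
#' @slot rrJitterSd standard deviation of per-beat RR jitter, ms.
#' @slot normalQrsWidth Q-to-S width of normal beats, ms (< 120).
#' @slot pvcQrsWidth Q-to-S width of PVC beats, ms (>= 120).
#' @slot pvcPrematurity multiplier (< 1) applied to the RR interval
#'   preceding a PVC.
#' @slot compensatoryFactor multiplier (> 1) applied to the RR interval
#'   following a PVC (compensatory pause).
#' @slot noiseSd standard deviation of additive Gaussian noise, mV.
#' @slot allowConsecutive logical; if FALSE (default) a beat directly
#'   following a PVC is forced to be normal.
#' @slot seed integer RNG seed; identical configs give bit-identical records.
#' @exportClass SynthConfig
setClass("SynthConfig",
  representation(
    nBeats = "integer", pvcFraction = "numeric", fs = "numeric",
    meanRR = "numeric", rrJitterSd = "numeric",
    normalQrsWidth = "numeric", pvcQrsWidth = "numeric",
    pvcPrematurity = "numeric", compensatoryFactor = "numeric",
    noiseSd = "numeric", allowConsecutive = "logical", seed = "integer"
  )
)

setValidity("SynthConfig", function(object) {
  msg <- character(0)
  if (object@nBeats < 1L)
    msg <- c(msg, "nBeats must be >= 1")
  if (object@pvcFraction < 0 || object@pvcFraction > 1)
    msg <- c(msg, "pvcFraction must lie in [0, 1]")
  if (object@fs <= 0)
    msg <- c(msg, "fs must be > 0")
  if (object@meanRR <= 0)
    msg <- c(msg, "meanRR must be > 0")
  if (object@rrJitterSd < 0)
    msg <- c(msg, "rrJitterSd must be >= 0")
  if (!(object@normalQrsWidth < 120))
    msg <- c(msg, "normalQrsWidth must be < 120 ms (normal QRS)")
  if (!(object@pvcQrsWidth >= 120))
    msg <- c(msg, "pvcQrsWidth must be >= 120 ms (wide ventricular QRS)")
  if (!(object@pvcPrematurity < 1))
    msg <- c(msg, "pvcPrematurity must be < 1")
  if (!(object@compensatoryFactor > 1))
    msg <- c(msg, "compensatoryFactor must be > 1")
  if (object@noiseSd < 0)
    msg <- c(msg, "noiseSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a SynthConfig
#'
#' @param nBeats number of beats.
#' @param pvcFraction per-beat PVC probability.
#' @param fs sampling rate, Hz.
#' @param meanRR mean sinus RR interval, ms.
#' @param rrJitterSd RR jitter SD, ms.
#' @param normalQrsWidth normal QRS width, ms.
#' @param pvcQrsWidth PVC QRS width, ms.
#' @param pvcPrematurity RR multiplier before a PVC.
#' @param compensatoryFactor RR multiplier after a PVC.
#' @param noiseSd additive noise SD, mV.
#' @param allowConsecutive allow two PVCs in a row.
#' @param seed RNG seed.
#' @return A validated \linkS4class{SynthConfig}.
#' @examples
#' cfg <- synthConfig(nBeats = 50, pvcFraction = 0.1, seed = 1)
#' @export
synthConfig <- function(nBeats = 400L, pvcFraction = 0.1, fs = 360,
                        meanRR = 800, rrJitterSd = 40,
                        normalQrsWidth = 80, pvcQrsWidth = 160,
                        pvcPrematurity = 0.7, compensatoryFactor = 1.3,
                        noiseSd = 0.02, allowConsecutive = FALSE,
                        seed = 1L) {
  new("SynthConfig",
      nBeats = as.integer(nBeats), pvcFraction = pvcFraction, fs = fs,
      meanRR = meanRR, rrJitterSd = rrJitterSd,
      normalQrsWidth = normalQrsWidth, pvcQrsWidth = pvcQrsWidth,
      pvcPrematurity = pvcPrematurity,
      compensatoryFactor = compensatoryFactor, noiseSd = noiseSd,
      allowConsecutive = allowConsecutive, seed = as.integer(seed))
}

#' ECGRecord: a sampled ECG with per-beat annotations
#'
#' Container for one record: the signal matrix (samples x leads, mV), the
#' sampling rate, lead names and an ordered beat-annotation table with one
#' row per beat (columns \code{sample}, \code{symbol}, \code{aamiClass},
#' \code{isPvc}). The annotation sample index marks the R wave.
#'
#' @slot recordId character record identifier.
#' @slot fs sampling rate, Hz.
#' @slot leads character vector of lead names, one per signal column.
#' @slot signal numeric matrix, samples in rows, leads in columns, mV.
#' @slot annotations data.frame of beat annotations ordered by sample.
#' @exportClass ECGRecord
setClass("ECGRecord",
  representation(recordId = "character", fs = "numeric",
                 leads = "character", signal = "matrix",
                 annotations = "data.frame")
)

setValidity("ECGRecord", function(object) {
  msg <- character(0)
  a <- object@annotations
  if (object@fs <= 0) msg <- c(msg, "fs must be > 0")
  if (ncol(object@signal) != length(object@leads))
    msg <- c(msg, "one lead name per signal column required")
  need <- c("sample", "symbol", "aamiClass", "isPvc")
  if (!all(need %in% names(a))) {
    msg <- c(msg, sprintf("annotations must have columns: %s",
                          paste(need, collapse = ", ")))
  } else if (nrow(a)) {
    if (is.unsorted(a$sample))
      msg <- c(msg, "annotations must be sorted by sample index")
    if (any(a$sample < 1L) || any(a$sample > nrow(object@signal)))
      msg <- c(msg, "annotation sample indices must lie within the signal")
    if (!all(a$aamiClass %in% c("N", "S", "V", "F", "Q")))
      msg <- c(msg, "aamiClass must be one of N, S, V, F, Q")
    if (!identical(a$isPvc, a$aamiClass == "V"))
      msg <- c(msg, "isPvc must equal (aamiClass == 'V')")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an ECGRecord
#'
#' @param recordId record identifier.
#' @param fs sampling rate, Hz.
#' @param signal numeric matrix or vector of samples in mV.
#' @param annotations data.frame with columns \code{sample}, \code{symbol},
#'   \code{aamiClass}, \code{isPvc}.
#' @param leads lead names.
#' @return An \linkS4class{ECGRecord}.
#' @export
ECGRecord <- function(recordId, fs, signal, annotations,
                      leads = paste0("lead", seq_len(NCOL(signal)))) {
  if (is.null(dim(signal))) signal <- matrix(signal, ncol = 1L)
  rownames(annotations) <- NULL
  new("ECGRecord", recordId = as.character(recordId), fs = fs,
      leads = leads, signal = signal, annotations = annotations)
}

#' @describeIn ECGRecord-class record identifier
#' @param object an \code{ECGRecord}
#' @export
setGeneric("recordId", function(object) standardGeneric("recordId"))
#' @export
setMethod("recordId", "ECGRecord", function(object) object@recordId)

#' @describeIn ECGRecord-class sampling rate in Hz
#' @export
setGeneric("sampFreq", function(object) standardGeneric("sampFreq"))
#' @export
setMethod("sampFreq", "ECGRecord", function(object) object@fs)

#' @describeIn ECGRecord-class signal matrix (samples x leads, mV)
#' @export
setGeneric("ecgSignal", function(object) standardGeneric("ecgSignal"))
#' @export
setMethod("ecgSignal", "ECGRecord", function(object) object@signal)

#' @describeIn ECGRecord-class beat-annotation data.frame
#' @export
setGeneric("beatAnnotations",
           function(object) standardGeneric("beatAnnotations"))
#' @export
setMethod("beatAnnotations", "ECGRecord",
          function(object) object@annotations)

setMethod("show", "ECGRecord", function(object) {
  a <- object@annotations
  cat(sprintf("ECGRecord '%s': %d samples x %d lead(s) @ %g Hz (%.1f s)\n",
              object@recordId, nrow(object@signal), ncol(object@signal),
              object@fs, nrow(object@signal) / object@fs))
  cat(sprintf("  %d annotated beats (%d PVC, %d other)\n",
              nrow(a), sum(a$isPvc), sum(!a$isPvc)))
  cat(sprintf("  leads: %s\n", paste(object@leads, collapse = ", ")))
})

#' NormalizationParams: per-feature min-max scaling learned on training data
#'
#' Stores, for each of the ten window features, the minimum and maximum
#' observed on the training windows. Normalization maps a raw value FV to
#' (FV - Fmin) / (Fmax - Fmin), clipped to [0, 1]; features whose training
#' range is degenerate (Fmax == Fmin) are flagged and map to 0.
#'
#' @slot fmin named numeric vector of per-feature training minima.
#' @slot fmax named numeric vector of per-feature training maxima.
#' @slot degenerate named logical vector, TRUE where fmax == fmin.
#' @exportClass NormalizationParams
setClass("NormalizationParams",
  representation(fmin = "numeric", fmax = "numeric",
                 degenerate = "logical")
)

setValidity("NormalizationParams", function(object) {
  if (length(object@fmin) != length(object@fmax))
    return("fmin and fmax must have equal length")
  if (any(object@fmax < object@fmin))
    return("fmax must be >= fmin for every feature")
  TRUE
})

setMethod("show", "NormalizationParams", function(object) {
  cat(sprintf("NormalizationParams for %d features", length(object@fmin)))
  if (any(object@degenerate))
    cat(sprintf(" (%d degenerate)", sum(object@degenerate)))
  cat("\n")
  print(data.frame(Fmin = object@fmin, Fmax = object@fmax,
                   degenerate = object@degenerate))
})

#' ModelConfig: architecture and training hyperparameters of the classifier
#'
#' The two-route 1-D convolutional network takes the 10-value normalized
#' feature vector. The upper route applies four length-3 convolutions (the
#' first three length-preserving) followed by one max-pool; the lower route
#' applies two length-3 convolutions followed by one max-pool. Both routes
#' are flattened, concatenated, passed through one hidden fully connected
#' layer and a 2-unit softmax head. Training uses Adam with the defaults
#' learning rate 1e-4, 40 epochs, batch size 200 and a step learning-rate
#' schedule with drop factor 0.2.
#'
#' @slot inputLength input feature count (10).
#' @slot nClasses output classes (2).
#' @slot upperFilters filter counts of the four upper-route convolutions.
#' @slot lowerFilters filter counts of the two lower-route convolutions.
#' @slot kernelLength taps per convolution kernel.
#' @slot poolSize max-pool window.
#' @slot fcUnits hidden fully connected width.
#' @slot learningRate initial Adam learning rate.
#' @slot maxEpochs training epochs.
#' @slot batchSize minibatch size.
#' @slot lrDropFactor multiplicative learning-rate drop.
#' @slot lrDropPeriod epochs between drops.
#' @slot classWeights logical; inverse-frequency class weights in the loss.
#' @slot seed integer seed for initialization and shuffling.
#' @exportClass ModelConfig
setClass("ModelConfig",
  representation(
    inputLength = "integer", nClasses = "integer",
    upperFilters = "integer", lowerFilters = "integer",
    kernelLength = "integer", poolSize = "integer", fcUnits = "integer",
    learningRate = "numeric", maxEpochs = "integer", batchSize = "integer",
    lrDropFactor = "numeric", lrDropPeriod = "integer",
    classWeights = "logical", seed = "integer"
  )
)

setValidity("ModelConfig", function(object) {
  msg <- character(0)
  if (object@inputLength != 10L)
    msg <- c(msg, "inputLength must be 10 (one window feature vector)")
  if (object@nClasses != 2L)
    msg <- c(msg, "nClasses must be 2 (PVC vs non-PVC)")
  if (length(object@upperFilters) != 4L)
    msg <- c(msg, "upperFilters must give 4 filter counts")
  if (length(object@lowerFilters) != 2L)
    msg <- c(msg, "lowerFilters must give 2 filter counts")
  if (any(c(object@upperFilters, object@lowerFilters) < 1L))
    msg <- c(msg, "filter counts must be >= 1")
  if (object@kernelLength < 1L) msg <- c(msg, "kernelLength must be >= 1")
  if (object@poolSize < 1L) msg <- c(msg, "poolSize must be >= 1")
  if (object@fcUnits < 1L) msg <- c(msg, "fcUnits must be >= 1")
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
  if (object@maxEpochs < 1L) msg <- c(msg, "maxEpochs must be >= 1")
  if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
  if (object@lrDropFactor <= 0 || object@lrDropFactor > 1)
    msg <- c(msg, "lrDropFactor must lie in (0, 1]")
  if (object@lrDropPeriod < 1L) msg <- c(msg, "lrDropPeriod must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a ModelConfig
#'
#' @param inputLength input feature count.
#' @param nClasses number of output classes.
#' @param upperFilters filter counts, upper route (4 values).
#' @param lowerFilters filter counts, lower route (2 values).
#' @param kernelLength convolution kernel taps.
#' @param poolSize max-pool window.
#' @param fcUnits hidden FC width.
#' @param learningRate initial Adam learning rate.
#' @param maxEpochs training epochs.
#' @param batchSize minibatch size.
#' @param lrDropFactor learning-rate drop factor.
#' @param lrDropPeriod epochs between learning-rate drops.
#' @param classWeights use inverse-frequency class weights.
#' @param seed RNG seed for init and shuffling.
#' @return A validated \linkS4class{ModelConfig}.
#' @export
modelConfig <- function(inputLength = 10L, nClasses = 2L,
                        upperFilters = c(16L, 16L, 16L, 32L),
                        lowerFilters = c(16L, 32L),
                        kernelLength = 3L, poolSize = 2L, fcUnits = 32L,
                        learningRate = 1e-4, maxEpochs = 40L,
                        batchSize = 200L, lrDropFactor = 0.2,
                        lrDropPeriod = 20L, classWeights = FALSE,
                        seed = 0L) {
  new("ModelConfig",
      inputLength = as.integer(inputLength), nClasses = as.integer(nClasses),
      upperFilters = as.integer(upperFilters),
      lowerFilters = as.integer(lowerFilters),
      kernelLength = as.integer(kernelLength),
      poolSize = as.integer(poolSize), fcUnits = as.integer(fcUnits),
      learningRate = learningRate, maxEpochs = as.integer(maxEpochs),
      batchSize = as.integer(batchSize), lrDropFactor = lrDropFactor,
      lrDropPeriod = as.integer(lrDropPeriod),
      classWeights = classWeights, seed = as.integer(seed))
}

#' PVCNet: the two-route convolutional PVC/non-PVC classifier
#'
#' Holds the architecture configuration, the weight tensors, the per-epoch
#' training history and (after training through the pipeline) the
#' normalization parameters the features must be scaled with.
#'
#' @slot config a \linkS4class{ModelConfig}.
#' @slot weights named list of weight arrays.
#' @slot history data.frame with one row per epoch (loss, accuracy, lr).
#' @slot normParams a \linkS4class{NormalizationParams} or NULL.
#' @slot trained logical.
#' @exportClass PVCNet
setClass("PVCNet",
  representation(config = "ModelConfig", weights = "list",
                 history = "data.frame", normParams = "ANY",
                 trained = "logical")
)

setMethod("show", "PVCNet", function(object) {
  cfg <- object@config
  cat(sprintf("PVCNet two-route 1-D CNN (%s)\n",
              if (object@trained) "trained" else "untrained"))
  cat(sprintf("  input %d | upper: %s conv + pool | lower: %s conv + pool\n",
              cfg@inputLength,
              paste(cfg@upperFilters, collapse = "-"),
              paste(cfg@lowerFilters, collapse = "-")))
  cat(sprintf("  fc %d -> softmax %d | %d trainable parameters\n",
              cfg@fcUnits, cfg@nClasses, countParams(object)))
  if (nrow(object@history))
    cat(sprintf("  final epoch: loss %.4f, accuracy %.3f\n",
                utils::tail(object@history$loss, 1),
                utils::tail(object@history$accuracy, 1)))
})

#' MetricsReport: per-record and aggregate PVC recognition metrics
#'
#' PPV (precision), recall (sensitivity) and F-score, all in percent, with
#' PVC as the positive class. The aggregate is reported both micro-averaged
#' (from pooled confusion counts over all windows, the headline) and
#' macro-averaged (mean of per-record metrics).
#'
#' @slot perRecord data.frame with one row per record (TP/FP/TN/FN and
#'   metrics).
#' @slot micro named list: pooled-count metrics and counts.
#' @slot macro named list: means of per-record metrics.
#' @slot counts named integer vector of pooled TP, FP, TN, FN.
#' @exportClass MetricsReport
setClass("MetricsReport",
  representation(perRecord = "data.frame", micro = "list",
                 macro = "list", counts = "integer")
)

setMethod("show", "MetricsReport", function(object) {
  fmt <- function(x) ifelse(is.na(x), "  --", sprintf("%5.1f", x))
  cat("PVC recognition report (PVC = positive class)\n")
  if (nrow(object@perRecord)) {
    cat("Per-record:\n")
    pr <- object@perRecord
    cat(sprintf("  %-10s %6s %6s %7s\n", "record", "PPV", "recall",
                "F-score"))
    for (i in seq_len(nrow(pr)))
      cat(sprintf("  %-10s %s %s  %s\n", pr$recordId[i], fmt(pr$ppv[i]),
                  fmt(pr$recall[i]), fmt(pr$fScore[i])))
  }
  cat(sprintf("Pooled (micro): PPV %s  recall %s  F %s  [TP %d FP %d TN %d FN %d]\n",
              fmt(object@micro$ppv), fmt(object@micro$recall),
              fmt(object@micro$fScore), object@counts["TP"],
              object@counts["FP"], object@counts["TN"],
              object@counts["FN"]))
  cat(sprintf("Mean of records (macro): PPV %s  recall %s  F %s\n",
              fmt(object@macro$ppv), fmt(object@macro$recall),
              fmt(object@macro$fScore)))
})
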