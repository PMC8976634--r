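# Window-level evaluation with PVC as the positive class: confusion
# counts, PPV (precision), recall (sensitivity) and F-score, per record and
# pooled.

#' Confusion counts with PVC as the positive class
#'
#' @param pred,truth character vectors of "PVC" / "non-PVC" labels, equal
#'   length.
#' @return Named integer vector: TP, FP, TN, FN.
#' @examples
#' confusionCounts(c("PVC", "non-PVC"), c("PVC", "PVC"))
#' @export
confusionCounts <- function(pred, truth) {
  if (length(pred) != length(truth))
    stop("pred and truth must have equal length")
  p <- pred == "PVC"; t <- truth == "PVC"
  c(TP = sum(p & t), FP = sum(p & !t), TN = sum(!p & !t), FN = sum(!p & t))
}

#' PPV, recall and F-score from confusion counts
#'
#' PPV = 100 TP / (TP + FP), recall = 100 TP / (TP + FN), F-score =
#' 2 PPV recall / (PPV + recall); all in percent. A metric whose
#' denominator is zero is undefined and reported as NA (never coerced to 0
#' or 100); the \code{undefined} element names which.
#'
#' @param counts named vector with TP, FP, TN, FN.
#' @return List: ppv, recall, fScore (percent or NA), undefined (character
#'   vector).
#' @export
computeMetrics <- function(counts) {
  tp <- counts[["TP"]]; fp <- counts[["FP"]]; fn <- counts[["FN"]]
  undefined <- character(0)
  ppv <- if (tp + fp > 0) 100 * tp / (tp + fp) else {
    undefined <- c(undefined, "ppv"); NA_real_
  }
  recall <- if (tp + fn > 0) 100 * tp / (tp + fn) else {
    undefined <- c(undefined, "recall"); NA_real_
  }
  f <- if (!is.na(ppv) && !is.na(recall)) fMeasure(ppv, recall) else {
    undefined <- c(undefined, "fScore"); NA_real_
  }
  if (!is.na(ppv) && !is.na(recall) && is.na(f))
    undefined <- c(undefined, "fScore")
  list(ppv = ppv, recall = recall, fScore = f, undefined = undefined)
}

#' Harmonic mean of precision and recall (F-score)
#'
#' @param precision,recall percentages.
#' @return F-score in percent; NA when both inputs are zero.
#' @examples
#' fMeasure(99.5, 100)   # 99.7 to 1 d.p.
#' @export
fMeasure <- function(precision, recall) {
  if (is.na(precision) || is.na(recall)) return(NA_real_)
  if (precision + recall == 0) return(NA_real_)
  2 * precision * recall / (precision + recall)
}

#' Per-record and aggregate PVC recognition report
#'
#' Builds a report with one row per record (confusion counts and metrics)
#' plus two aggregates: the micro average (metrics from confusion counts
#' pooled over all windows — the headline) and the macro average (mean of
#' the per-record metrics). Records with no PVC-labeled truth windows have
#' undefined recall; they are kept in the pooled counts but excluded from
#' the per-record rows with a message.
#'
#' @param recordIds character vector naming the source record of each
#'   window.
#' @param pred,truth window labels, "PVC" / "non-PVC".
#' @return A \linkS4class{MetricsReport}.
#' @export
perRecordReport <- function(recordIds, pred, truth) {
  if (length(recordIds) != length(pred) || length(pred) != length(truth))
    stop("recordIds, pred and truth must have equal length")
  pooled <- confusionCounts(pred, truth)
  rows <- list(); skipped <- character(0)
  for (id in unique(recordIds)) {
    sel <- recordIds == id
    cc <- confusionCounts(pred[sel], truth[sel])
    m <- computeMetrics(cc)
    if ("recall" %in% m$undefined) { skipped <- c(skipped, id); next }
    rows[[id]] <- data.frame(recordId = id, TP = cc[["TP"]],
                             FP = cc[["FP"]], TN = cc[["TN"]],
                             FN = cc[["FN"]], ppv = m$ppv,
                             recall = m$recall, fScore = m$fScore,
                             stringsAsFactors = FALSE)
  }
  if (length(skipped))
    message(sprintf(
      "record(s) without PVC truth windows left out of per-record rows: %s",
      paste(skipped, collapse = ", ")))
  perRec <- if (length(rows)) do.call(rbind, rows) else
    data.frame(recordId = character(0), TP = integer(0), FP = integer(0),
               TN = integer(0), FN = integer(0), ppv = numeric(0),
               recall = numeric(0), fScore = numeric(0))
  rownames(perRec) <- NULL
  micro <- computeMetrics(pooled)
  macro <- list(ppv = mean(perRec$ppv, na.rm = TRUE),
                recall = mean(perRec$recall, na.rm = TRUE),
                fScore = mean(perRec$fScore, na.rm = TRUE))
  new("MetricsReport", perRecord = perRec, micro = micro, macro = macro,
      counts = as.integer(pooled) |> stats::setNames(names(pooled)))
}
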