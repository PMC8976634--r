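# End-to-end pipeline: synthesize (or read) records, extract windowed
# features, fit normalization on the training split only, train the
# classifier and evaluate on the held-out split. Every source of
# randomness derives from one master seed.

#' Run the PVC recognition pipeline on synthetic records
#'
#' Generates \code{nRecordsPerClass} high-PVC-burden and
#' \code{nRecordsPerClass} low-burden records, splits each group half/half
#' into train and test, extracts 20 s window features, min-max normalizes
#' with parameters fitted on the training windows only, trains the
#' two-route CNN and evaluates window-level PVC recognition on the test
#' records.
#'
#' High-burden records are generated with consecutive PVCs allowed, since a
#' per-beat PVC probability near 1 is unrealizable under the
#' no-consecutive-PVC constraint.
#'
#' @param seed master seed; drives record generation, weight init and
#'   shuffling.
#' @param nRecordsPerClass records per burden class (default 30, i.e. 60
#'   records in total).
#' @param nBeats beats per record; the default 2250 gives roughly
#'   30-minute records at the default mean RR of 800 ms.
#' @param highPvcFraction,lowPvcFraction per-beat PVC probability of the
#'   two record groups.
#' @param windowS window length, seconds.
#' @param pvcThreshold PVC beat fraction required for a PVC window label.
#' @param modelCfg a \linkS4class{ModelConfig}; its seed is overridden by
#'   the master seed.
#' @param outDir optional directory for artifacts (feature tables,
#'   predictions, metrics as CSV, serialized model, run info).
#' @param verbose print stage progress.
#' @return A list: \code{report} (\linkS4class{MetricsReport}),
#'   \code{model}, \code{normParams}, \code{trainFeatures},
#'   \code{testFeatures}, \code{predictions}.
#' @export
runPipeline <- function(seed = 0L, nRecordsPerClass = 30L, nBeats = 2250L,
                        highPvcFraction = 0.98, lowPvcFraction = 0.02,
                        windowS = 20, pvcThreshold = 0.95,
                        modelCfg = modelConfig(), outDir = NULL,
                        verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))

  makeRecords <- function(fraction, tag, offset) {
    lapply(seq_len(nRecordsPerClass), function(i) {
      cfg <- synthConfig(nBeats = nBeats, pvcFraction = fraction,
                        allowConsecutive = fraction > 0.5,
                        seed = deriveSeed(seed, offset + i))
      generateRecord(cfg, recordId = sprintf("%s-%02d", tag, i))
    })
  }
  say("generating %d synthetic records...", 2L * nRecordsPerClass)
  recs <- c(makeRecords(highPvcFraction, "high", 0L),
            makeRecords(lowPvcFraction, "low", 1000L))

  half <- nRecordsPerClass %/% 2L
  isTrain <- c(seq_len(nRecordsPerClass) <= half,
               seq_len(nRecordsPerClass) <= half)

  say("extracting window features...")
  feats <- lapply(recs, extractWindowFeatures, windowS = windowS,
                  pvcThreshold = pvcThreshold)
  trainFeat <- do.call(rbind, feats[isTrain])
  testFeat <- do.call(rbind, feats[!isTrain])
  if (!nrow(trainFeat) || !nrow(testFeat))
    stop("feature extraction produced an empty split")

  normParams <- fitNormalization(trainFeat)
  Xtr <- applyNormalization(trainFeat, normParams)
  Xte <- applyNormalization(testFeat, normParams)

  say("training classifier on %d windows...", nrow(Xtr))
  cfg <- modelCfg
  cfg@seed <- deriveSeed(seed, 2L)
  model <- buildModel(cfg)
  model <- trainModel(model, Xtr, trainFeat$label,
                      normParams = normParams, verbose = verbose)

  say("evaluating on %d held-out windows...", nrow(Xte))
  pr <- predict(model, Xte)
  report <- perRecordReport(testFeat$recordId, pr$label, testFeat$label)

  predictions <- data.frame(recordId = testFeat$recordId,
                            windowIndex = testFeat$windowIndex,
                            truth = testFeat$label, pred = pr$label,
                            probPVC = pr$prob[, "PVC"],
                            stringsAsFactors = FALSE)

  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    utils::write.csv(trainFeat, file.path(outDir, "train_features.csv"),
                     row.names = FALSE)
    utils::write.csv(testFeat, file.path(outDir, "test_features.csv"),
                     row.names = FALSE)
    utils::write.csv(predictions, file.path(outDir, "predictions.csv"),
                     row.names = FALSE)
    utils::write.csv(cbind(subset = "pooled",
                           as.data.frame(as.list(model@history[
                             nrow(model@history), ]))),
                     file.path(outDir, "training_tail.csv"),
                     row.names = FALSE)
    utils::write.csv(report@perRecord, file.path(outDir, "per_record.csv"),
                     row.names = FALSE)
    saveRDS(model, file.path(outDir, "model.rds"))
    writeLines(c(sprintf("seed: %d", seed),
                 sprintf("records: %d x %d beats", 2L * nRecordsPerClass,
                         nBeats),
                 sprintf("pvc fractions: %.3f / %.3f", highPvcFraction,
                         lowPvcFraction),
                 sprintf("config hash: %s", configHash(cfg))),
               file.path(outDir, "run_info.txt"))
  }

  list(report = report, model = model, normParams = normParams,
       trainFeatures = trainFeat, testFeatures = testFeat,
       predictions = predictions)
}

# cheap deterministic fingerprint of a config (no external digest dep)
configHash <- function(cfg) {
  s <- paste(utils::capture.output(utils::str(cfg)), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %%
            4294967296)
}

#' Extract features for all records of a WFDB directory split
#'
#' Reads each record of the given ids from a directory of WFDB triplets
#' and row-binds their window feature tables.
#'
#' @param dataDir directory with .hea/.dat/.atr files.
#' @param recordIds character vector of record ids.
#' @param windowS window length, seconds.
#' @param pvcThreshold PVC labeling threshold.
#' @return The combined feature data.frame.
#' @export
extractFeaturesFromDir <- function(dataDir, recordIds, windowS = 20,
                                   pvcThreshold = 0.95) {
  feats <- lapply(recordIds, function(id)
    extractWindowFeatures(readWfdb(file.path(dataDir, id)),
                          windowS = windowS, pvcThreshold = pvcThreshold))
  do.call(rbind, feats)
}
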