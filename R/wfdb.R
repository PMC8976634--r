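# PhysioNet WFDB record I/O: ASCII .hea headers, .dat signal files in
# formats 212 (packed 12-bit pairs, the MIT-BIH format) and 16 (16-bit
# little-endian), and MIT-format .atr annotation files. No WFDB library is
# available for R, so the formats are implemented here directly.

# MIT annotation code table: code number -> mnemonic symbol.
.annCodes <- c(
  "1" = "N", "2" = "L", "3" = "R", "4" = "a", "5" = "V", "6" = "F",
  "7" = "J", "8" = "A", "9" = "S", "10" = "E", "11" = "j", "12" = "/",
  "13" = "Q", "14" = "~", "16" = "|", "18" = "s", "19" = "T", "20" = "*",
  "21" = "D", "22" = "\"", "23" = "=", "24" = "p", "25" = "B", "26" = "^",
  "27" = "t", "28" = "+", "29" = "u", "30" = "?", "31" = "!", "32" = "[",
  "33" = "]", "34" = "e", "35" = "n", "36" = "@", "37" = "x", "38" = "f",
  "39" = "(", "40" = ")", "41" = "r"
)

# WFDB beat-annotation symbols (everything else is a non-beat annotation
# such as a rhythm change or signal-quality marker).
.beatSymbols <- c("N", "L", "R", "e", "j", "A", "a", "J", "S", "V", "E",
                  "F", "/", "f", "Q", "B", "n", "r")

.symbolToCode <- stats::setNames(as.integer(names(.annCodes)),
                                 unname(.annCodes))

#' Map a WFDB beat-annotation symbol to its AAMI class
#'
#' Implements the standard AAMI EC57 five-class grouping: N (normal and
#' bundle-branch/escape variants), S (supraventricular ectopic), V
#' (ventricular ectopic, i.e. PVC and ventricular escape), F (fusion) and Q
#' (paced/unknown). Unrecognized beat codes map to Q with a warning.
#'
#' @param symbol character vector of single-character WFDB beat codes.
#' @return Character vector of AAMI classes ("N", "S", "V", "F" or "Q").
#' @examples
#' mapAamiClass(c("V", "N", "E", "A", "/"))
#' @export
mapAamiClass <- function(symbol) {
  map <- c(N = "N", L = "N", R = "N", e = "N", j = "N",
           A = "S", a = "S", J = "S", S = "S",
           V = "V", E = "V",
           F = "F",
           "/" = "Q", f = "Q", Q = "Q")
  out <- unname(map[symbol])
  if (anyNA(out)) {
    warning(sprintf("unknown beat code(s) %s mapped to AAMI class Q",
                    paste(unique(symbol[is.na(out)]), collapse = ", ")))
    out[is.na(out)] <- "Q"
  }
  out
}

packFmt212 <- function(d) {
  if (length(d) %% 2L) d <- c(d, 0L)
  d <- as.integer(d) %% 4096L            # 12-bit two's complement
  x1 <- d[seq(1L, length(d), 2L)]
  x2 <- d[seq(2L, length(d), 2L)]
  b <- integer(3L * length(x1))
  b[seq(1L, length(b), 3L)] <- x1 %% 256L
  b[seq(2L, length(b), 3L)] <- (x1 %/% 256L) + 16L * (x2 %/% 256L)
  b[seq(3L, length(b), 3L)] <- x2 %% 256L
  as.raw(b)
}

unpackFmt212 <- function(bytes, nValues) {
  b <- as.integer(bytes)
  nTriplets <- length(b) %/% 3L
  b1 <- b[seq(1L, 3L * nTriplets, 3L)]
  b2 <- b[seq(2L, 3L * nTriplets, 3L)]
  b3 <- b[seq(3L, 3L * nTriplets, 3L)]
  x1 <- b1 + 256L * (b2 %% 16L)
  x2 <- b3 + 256L * (b2 %/% 16L)
  x1 <- ifelse(x1 > 2047L, x1 - 4096L, x1)
  x2 <- ifelse(x2 > 2047L, x2 - 4096L, x2)
  d <- as.vector(rbind(x1, x2))
  d[seq_len(nValues)]
}

#' Write an ECGRecord as a WFDB record triplet
#'
#' Writes \code{<record>.hea}, \code{<record>.dat} (format 212 by default,
#' or 16) and, when the record carries annotations, a MIT-format
#' \code{<record>.atr}. Samples are digitized as
#' \code{round(mV * gain) + baseline}.
#'
#' @param record an \linkS4class{ECGRecord}.
#' @param dir output directory (created if needed).
#' @param fmt WFDB signal storage format, 212 or 16.
#' @param gain ADC units per mV.
#' @return The record path prefix, invisibly.
#' @export
writeWfdb <- function(record, dir, fmt = 212L, gain = 200) {
  stopifnot(is(record, "ECGRecord"), fmt %in% c(212L, 16L))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  id <- record@recordId
  nSig <- ncol(record@signal)
  nSamp <- nrow(record@signal)
  digital <- round(record@signal * gain)
  lim <- if (fmt == 212L) 2047 else 32767
  digital[] <- pmin(pmax(digital, -lim - 1), lim)

  adcRes <- if (fmt == 212L) 12L else 16L
  hea <- c(sprintf("%s %d %g %d", id, nSig, record@fs, nSamp),
           sprintf("%s.dat %d %g/mV %d 0 %d 0 0 %s",
                   id, fmt, gain, adcRes, as.integer(digital[1, ]),
                   record@leads))
  writeLines(hea, file.path(dir, paste0(id, ".hea")))

  interleaved <- as.integer(t(digital))   # frame order: s1 lead1..leadK, s2 ...
  con <- file(file.path(dir, paste0(id, ".dat")), "wb")
  if (fmt == 212L) {
    writeBin(packFmt212(interleaved), con)
  } else {
    writeBin(interleaved, con, size = 2L, endian = "little")
  }
  close(con)

  if (nrow(record@annotations))
    writeAtr(record@annotations, file.path(dir, paste0(id, ".atr")))
  invisible(file.path(dir, id))
}

writeAtr <- function(annotations, path) {
  words <- integer(0)
  prev <- 0L
  for (i in seq_len(nrow(annotations))) {
    code <- unname(.symbolToCode[annotations$symbol[i]])
    if (is.na(code))
      stop(sprintf("no MIT annotation code for symbol '%s'",
                   annotations$symbol[i]))
    delta <- annotations$sample[i] - prev
    prev <- annotations$sample[i]
    if (delta > 1023L || delta < 0L) {
      # SKIP: 4-byte interval, high-order 16 bits first; the annotation
      # word itself then carries a zero increment.
      words <- c(words, bitwShiftL(59L, 10L),
                 delta %/% 65536L, delta %% 65536L,
                 bitwShiftL(code, 10L))
    } else {
      words <- c(words, bitwShiftL(code, 10L) + delta)
    }
  }
  words <- c(words, 0L)                   # EOF
  con <- file(path, "wb")
  b <- integer(2L * length(words))
  b[seq(1L, length(b), 2L)] <- words %% 256L
  b[seq(2L, length(b), 2L)] <- words %/% 256L
  writeBin(as.raw(b), con)
  close(con)
}

readAtr <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  b <- as.integer(bytes)
  nWords <- length(b) %/% 2L
  words <- b[seq(1L, 2L * nWords, 2L)] + 256L * b[seq(2L, 2L * nWords, 2L)]
  samples <- integer(0)
  symbols <- character(0)
  t <- 0
  i <- 1L
  pendingSkip <- 0
  while (i <= nWords) {
    w <- words[i]
    code <- w %/% 1024L
    field <- w %% 1024L
    if (w == 0L) break                    # EOF
    if (code == 59L) {                    # SKIP: next two words = interval
      pendingSkip <- pendingSkip + words[i + 1L] * 65536 + words[i + 2L]
      i <- i + 3L
      next
    } else if (code == 63L) {             # AUX: skip field bytes (padded)
      i <- i + 1L + (field + field %% 2L) %/% 2L
      next
    } else if (code %in% c(60L, 61L, 62L)) {   # NUM / SUB / CHN
      i <- i + 1L
      next
    }
    t <- t + pendingSkip + field
    pendingSkip <- 0
    sym <- .annCodes[as.character(code)]
    if (!is.na(sym)) {
      samples <- c(samples, as.integer(t))
      symbols <- c(symbols, unname(sym))
    }
    i <- i + 1L
  }
  data.frame(sample = samples, symbol = symbols, stringsAsFactors = FALSE)
}

parseHeader <- function(heaPath) {
  lines <- readLines(heaPath, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  rec <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  name <- sub("/.*$", "", rec[1])
  nSig <- as.integer(rec[2])
  fs <- if (length(rec) >= 3) as.numeric(sub("[/(].*$", "", rec[3])) else 250
  nSamp <- if (length(rec) >= 4) as.integer(rec[4]) else NA_integer_
  sigs <- lapply(lines[seq_len(nSig) + 1L], function(l) {
    tok <- strsplit(trimws(l), "\\s+")[[1]]
    gainSpec <- if (length(tok) >= 3) tok[3] else "200"
    gain <- as.numeric(sub("[(/].*$", "", gainSpec))
    if (is.na(gain) || gain == 0) gain <- 200
    baseline <- if (grepl("\\(", gainSpec))
      as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gainSpec))
    else if (length(tok) >= 5) as.numeric(tok[5]) else 0
    if (is.na(baseline)) baseline <- 0
    list(file = tok[1],
         fmt = as.integer(sub("[x:+].*$", "", tok[2])),
         gain = gain, baseline = baseline,
         desc = if (length(tok) >= 9)
           paste(tok[9:length(tok)], collapse = " ")
         else sub("\\.dat$", "", tok[1]))
  })
  list(name = name, nSig = nSig, fs = fs, nSamp = nSamp, signals = sigs)
}

#' Read a WFDB record triplet
#'
#' Reads \code{<prefix>.hea}, \code{<prefix>.dat} (formats 212 and 16 are
#' supported) and \code{<prefix>.atr} if present. Signals are gain-corrected
#' to mV. Only beat annotations are kept (rhythm changes, signal-quality
#' and other non-beat codes are dropped); each beat is assigned its AAMI
#' class and PVC flag. If a preferred lead is named and present, its column
#' is moved first.
#'
#' @param prefix path prefix of the record (no extension).
#' @param leadPreference lead description to place first (default "MLII",
#'   the conventional MIT-BIH analysis lead).
#' @return An \linkS4class{ECGRecord}.
#' @export
readWfdb <- function(prefix, leadPreference = "MLII") {
  hea <- paste0(prefix, ".hea")
  dat <- paste0(prefix, ".dat")
  if (!file.exists(hea) || !file.exists(dat))
    stop(sprintf("WFDB record '%s' not found (.hea/.dat required)", prefix))
  h <- parseHeader(hea)
  fmts <- vapply(h$signals, `[[`, integer(1), "fmt")
  if (length(unique(fmts)) != 1L || !unique(fmts) %in% c(212L, 16L))
    stop(sprintf("unsupported WFDB signal format(s): %s",
                 paste(unique(fmts), collapse = ", ")))
  fmt <- fmts[1]
  bytes <- readBin(dat, "raw", n = file.size(dat))
  nTotal <- if (!is.na(h$nSamp)) h$nSamp * h$nSig else {
    if (fmt == 212L) (length(bytes) %/% 3L) * 2L else length(bytes) %/% 2L
  }
  d <- if (fmt == 212L) {
    unpackFmt212(bytes, nTotal)
  } else {
    readBin(bytes, "integer", n = nTotal, size = 2L, signed = TRUE,
            endian = "little")
  }
  mat <- matrix(as.numeric(d), ncol = h$nSig, byrow = TRUE)
  for (k in seq_len(h$nSig))
    mat[, k] <- (mat[, k] - h$signals[[k]]$baseline) / h$signals[[k]]$gain
  leads <- vapply(h$signals, `[[`, character(1), "desc")

  pref <- which(leads == leadPreference)
  if (length(pref) == 1L && pref != 1L) {
    ord <- c(pref, setdiff(seq_len(h$nSig), pref))
    mat <- mat[, ord, drop = FALSE]
    leads <- leads[ord]
  }

  atr <- paste0(prefix, ".atr")
  if (file.exists(atr)) {
    ann <- readAtr(atr)
    ann <- ann[ann$symbol %in% .beatSymbols &
                 ann$sample >= 1L & ann$sample <= nrow(mat), , drop = FALSE]
    if (nrow(ann)) {
      ann$aamiClass <- mapAamiClass(ann$symbol)
      ann$isPvc <- ann$aamiClass == "V"
    } else {
      warning(sprintf("record '%s' carries no beat annotations", h$name))
      ann <- emptyAnnotations()
    }
  } else {
    warning(sprintf("record '%s' has no .atr annotation file", h$name))
    ann <- emptyAnnotations()
  }
  ECGRecord(h$name, h$fs, mat, ann, leads = leads)
}

emptyAnnotations <- function() {
  data.frame(sample = integer(0), symbol = character(0),
             aamiClass = character(0), isPvc = logical(0),
             stringsAsFactors = FALSE)
}

# Inter-patient MIT-BIH partition: 22 training and 22 test records after
# excluding the four paced records.
.mitdbTrainIds <- c("101", "106", "108", "109", "112", "114", "115", "116",
                    "118", "119", "122", "124", "201", "203", "205", "207",
                    "208", "209", "215", "220", "223", "230")
.mitdbTestIds <- c("100", "103", "105", "111", "113", "117", "121", "123",
                   "200", "202", "210", "212", "213", "214", "219", "221",
                   "222", "228", "231", "232", "233", "234")
.mitdbExcludedIds <- c("102", "104", "107", "217")

#' Build the MIT-BIH inter-patient train/test split
#'
#' Returns the conventional inter-patient partition of the MIT-BIH
#' arrhythmia database: 22 training records, 22 test records, with the four
#' paced records (102, 104, 107, 217) always excluded. The fixed partition
#' is intersected with the records actually available; missing records are
#' reported with a message.
#'
#' @param availableIds character vector of record ids on hand; defaults to
#'   the full 48-record database.
#' @return A list with elements \code{trainIds}, \code{testIds} and
#'   \code{excludedIds}.
#' @examples
#' s <- buildSplit()
#' length(s$trainIds); length(s$testIds)
#' @export
buildSplit <- function(availableIds = c(.mitdbTrainIds, .mitdbTestIds,
                                        .mitdbExcludedIds)) {
  availableIds <- as.character(availableIds)
  missing <- setdiff(c(.mitdbTrainIds, .mitdbTestIds), availableIds)
  if (length(missing))
    message(sprintf("records absent from the split: %s",
                    paste(missing, collapse = ", ")))
  list(trainIds = intersect(.mitdbTrainIds, availableIds),
       testIds = intersect(.mitdbTestIds, availableIds),
       excludedIds = .mitdbExcludedIds)
}

#' Reference beat-count totals for the MIT-BIH split
#'
#' The published PVC / non-PVC beat totals of the inter-patient partition,
#' used by \code{\link{mitdbCountReport}} to flag deviations.
#'
#' @return A data.frame with rows test, train and overall.
#' @export
mitdbReferenceCounts <- function() {
  data.frame(
    subset = c("test", "train", "overall"),
    pvc = c(3157L, 3648L, 6805L),
    nonPvc = c(46539L, 47573L, 94112L),
    total = c(49696L, 51221L, 100917L)
  )
}

#' Beat counts over a local MIT-BIH copy
#'
#' Reads every available record of the inter-patient split from a directory
#' of WFDB files, tallies PVC and non-PVC beats per subset and compares
#' them with the published totals, listing any records that are missing.
#'
#' @param dataDir directory holding mitdb .hea/.dat/.atr files.
#' @return A list: \code{counts} (observed), \code{reference},
#'   \code{missingRecords}.
#' @export
mitdbCountReport <- function(dataDir) {
  ids <- sub("\\.hea$", "", basename(Sys.glob(file.path(dataDir, "*.hea"))))
  split <- buildSplit(ids)
  tally <- function(recIds) {
    pvc <- 0L; tot <- 0L
    for (id in recIds) {
      a <- beatAnnotations(readWfdb(file.path(dataDir, id)))
      pvc <- pvc + sum(a$isPvc); tot <- tot + nrow(a)
    }
    c(pvc = pvc, nonPvc = tot - pvc, total = tot)
  }
  te <- tally(split$testIds); tr <- tally(split$trainIds)
  counts <- data.frame(subset = c("test", "train", "overall"),
                       pvc = c(te["pvc"], tr["pvc"], te["pvc"] + tr["pvc"]),
                       nonPvc = c(te["nonPvc"], tr["nonPvc"],
                                  te["nonPvc"] + tr["nonPvc"]),
                       total = c(te["total"], tr["total"],
                                 te["total"] + tr["total"]))
  list(counts = counts, reference = mitdbReferenceCounts(),
       missingRecords = setdiff(c(.mitdbTrainIds, .mitdbTestIds), ids))
}
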