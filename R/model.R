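# The two-route 1-D convolutional PVC classifier.
#
# Upper route: four length-3 convolutions over the 10-value feature vector,
# the first three with length-preserving (zero) padding, followed by one
# size-2 max-pool. Lower route: two length-3 convolutions followed by one
# size-2 max-pool. Both routes are flattened, concatenated, passed through
# one hidden fully connected ReLU layer and a 2-unit softmax head. Hidden
# activations are ReLU; training minimizes cross-entropy with Adam under a
# step learning-rate schedule. Forward, backward and the optimizer are
# implemented here with dense linear algebra; every operation is batched
# over windows.

# ---- tensor primitives (x: array n x L x C, column-major) ----------------

padTime <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  out <- array(0, c(d[1], d[2] + 2L * pad, d[3]))
  out[, pad + seq_len(d[2]), ] <- x
  out
}

# convolution forward: W is k x Cin x Cout, b length Cout
convForward <- function(x, W, b, pad) {
  d <- dim(x); k <- dim(W)[1]; cout <- dim(W)[3]
  xp <- padTime(x, pad)
  lout <- d[2] + 2L * pad - k + 1L
  n <- d[1]
  acc <- matrix(0, n * lout, cout)
  for (j in seq_len(k)) {
    slab <- xp[, j:(j + lout - 1L), , drop = FALSE]
    dim(slab) <- c(n * lout, d[3])
    acc <- acc + slab %*% matrix(W[j, , ], dim(W)[2], cout)
  }
  acc <- sweep(acc, 2, b, "+")
  dim(acc) <- c(n, lout, cout)
  acc
}

# convolution backward: returns gradients wrt x, W, b
convBackward <- function(x, W, pad, dOut) {
  d <- dim(x); k <- dim(W)[1]; cin <- dim(W)[2]; cout <- dim(W)[3]
  n <- d[1]
  xp <- padTime(x, pad)
  lout <- dim(dOut)[2]
  dO2 <- dOut; dim(dO2) <- c(n * lout, cout)
  dW <- array(0, dim(W))
  dXp <- array(0, dim(xp))
  for (j in seq_len(k)) {
    idx <- j:(j + lout - 1L)
    slab <- xp[, idx, , drop = FALSE]
    dim(slab) <- c(n * lout, cin)
    dW[j, , ] <- crossprod(slab, dO2)
    dSlab <- dO2 %*% t(matrix(W[j, , ], cin, cout))
    dim(dSlab) <- c(n, lout, cin)
    dXp[, idx, ] <- dXp[, idx, , drop = FALSE] + dSlab
  }
  db <- colSums(dO2)
  dX <- if (pad > 0L) dXp[, pad + seq_len(d[2]), , drop = FALSE] else dXp
  list(dX = dX, dW = dW, db = db)
}

reluForward <- function(x) { x[x < 0] <- 0; x }
reluBackward <- function(preact, dOut) { dOut[preact <= 0] <- 0; dOut }

# max-pool along time, stride = size; keeps argmax slice for backprop
poolForward <- function(x, size) {
  d <- dim(x)
  lp <- d[2] %/% size
  out <- x[, size * (seq_len(lp) - 1L) + 1L, , drop = FALSE]
  arg <- array(1L, dim(out))
  if (size > 1L) for (s in 2:size) {
    cand <- x[, size * (seq_len(lp) - 1L) + s, , drop = FALSE]
    better <- cand > out
    out[better] <- cand[better]
    arg[better] <- s
  }
  list(out = out, arg = arg, inLen = d[2])
}

poolBackward <- function(pool, size, dOut) {
  d <- dim(dOut)
  dX <- array(0, c(d[1], pool$inLen, d[3]))
  for (s in seq_len(size)) {
    mask <- pool$arg == s
    slab <- array(0, d)
    slab[mask] <- dOut[mask]
    dX[, size * (seq_len(d[2]) - 1L) + s, ] <- slab
  }
  dX
}

flatten2 <- function(x) { d <- dim(x); dim(x) <- c(d[1], d[2] * d[3]); x }

# ---- architecture --------------------------------------------------------

# per-layer geometry: padding of each convolution and route output lengths
routeGeometry <- function(cfg) {
  k <- cfg@kernelLength
  upPad <- c(rep((k - 1L) %/% 2L, 3L), 0L)   # first three length-preserving
  loPad <- c(0L, 0L)
  upLen <- cfg@inputLength
  for (i in 1:4) upLen <- upLen + 2L * upPad[i] - k + 1L
  upLen <- upLen %/% cfg@poolSize
  loLen <- cfg@inputLength
  for (i in 1:2) loLen <- loLen + 2L * loPad[i] - k + 1L
  loLen <- loLen %/% cfg@poolSize
  list(upPad = upPad, loPad = loPad,
       upOut = upLen * cfg@upperFilters[4],
       loOut = loLen * cfg@lowerFilters[2])
}

initWeights <- function(cfg) {
  k <- cfg@kernelLength
  he <- function(k, cin, cout)
    array(stats::rnorm(k * cin * cout, 0, sqrt(2 / (k * cin))),
          c(k, cin, cout))
  upIn <- c(1L, cfg@upperFilters[-4])
  loIn <- c(1L, cfg@lowerFilters[-2])
  geo <- routeGeometry(cfg)
  w <- list()
  for (i in 1:4) {
    w[[paste0("upW", i)]] <- he(k, upIn[i], cfg@upperFilters[i])
    w[[paste0("upB", i)]] <- numeric(cfg@upperFilters[i])
  }
  for (i in 1:2) {
    w[[paste0("loW", i)]] <- he(k, loIn[i], cfg@lowerFilters[i])
    w[[paste0("loB", i)]] <- numeric(cfg@lowerFilters[i])
  }
  concatDim <- geo$upOut + geo$loOut
  w$fcW <- matrix(stats::rnorm(concatDim * cfg@fcUnits, 0,
                               sqrt(2 / concatDim)),
                  concatDim, cfg@fcUnits)
  w$fcB <- numeric(cfg@fcUnits)
  w$outW <- matrix(stats::rnorm(cfg@fcUnits * cfg@nClasses, 0,
                                sqrt(2 / cfg@fcUnits)),
                   cfg@fcUnits, cfg@nClasses)
  w$outB <- numeric(cfg@nClasses)
  w
}

#' Build an untrained PVCNet
#'
#' Instantiates the two-route architecture with seeded He-normal weight
#' initialization.
#'
#' @param config a \linkS4class{ModelConfig}.
#' @return An untrained \linkS4class{PVCNet}.
#' @examples
#' m <- buildModel(modelConfig(seed = 1))
#' countParams(m)
#' @export
buildModel <- function(config = modelConfig()) {
  validObject(config)
  w <- withSeed(config@seed, initWeights(config))
  new("PVCNet", config = config, weights = w,
      history = data.frame(epoch = integer(0), loss = numeric(0),
                           accuracy = numeric(0), lr = numeric(0)),
      normParams = NULL, trained = FALSE)
}

#' Count trainable parameters of a PVCNet
#'
#' @param object a \linkS4class{PVCNet} or \linkS4class{ModelConfig}.
#' @return Integer: total number of weights and biases.
#' @export
countParams <- function(object) {
  w <- if (is(object, "PVCNet")) object@weights
       else withSeed(0L, initWeights(object))
  sum(vapply(w, length, integer(1)))
}

#' Architecture summary of a PVCNet
#'
#' Introspection of the built network: convolution and pooling layer counts
#' per route, concatenation arity and head shape.
#'
#' @param model a \linkS4class{PVCNet}.
#' @return Named list with upperConvLayers, upperPoolLayers,
#'   lowerConvLayers, lowerPoolLayers, concatInputs, fcUnits,
#'   outputUnits, outputActivation.
#' @export
architectureSummary <- function(model) {
  cfg <- model@config
  list(upperConvLayers = length(cfg@upperFilters),
       upperPoolLayers = 1L,
       lowerConvLayers = length(cfg@lowerFilters),
       lowerPoolLayers = 1L,
       concatInputs = 2L,
       fcUnits = cfg@fcUnits,
       outputUnits = cfg@nClasses,
       outputActivation = "softmax")
}

# full forward pass; keep = TRUE retains intermediates for backprop
nnForward <- function(w, cfg, X, keep = FALSE) {
  n <- nrow(X)
  geo <- routeGeometry(cfg)
  x0 <- array(X, c(n, cfg@inputLength, 1L))
  cache <- list(x0 = x0)

  up <- x0
  for (i in 1:4) {
    z <- convForward(up, w[[paste0("upW", i)]], w[[paste0("upB", i)]],
                     geo$upPad[i])
    cache[[paste0("upIn", i)]] <- up
    cache[[paste0("upZ", i)]] <- z
    up <- reluForward(z)
  }
  upPool <- poolForward(up, cfg@poolSize)
  cache$upPrePool <- up
  cache$upPool <- upPool

  lo <- x0
  for (i in 1:2) {
    z <- convForward(lo, w[[paste0("loW", i)]], w[[paste0("loB", i)]],
                     geo$loPad[i])
    cache[[paste0("loIn", i)]] <- lo
    cache[[paste0("loZ", i)]] <- z
    lo <- reluForward(z)
  }
  loPool <- poolForward(lo, cfg@poolSize)
  cache$loPrePool <- lo
  cache$loPool <- loPool

  concat <- cbind(flatten2(upPool$out), flatten2(loPool$out))
  fcZ <- sweep(concat %*% w$fcW, 2, w$fcB, "+")
  fcA <- reluForward(fcZ)
  logits <- sweep(fcA %*% w$outW, 2, w$outB, "+")
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  probs <- e / rowSums(e)
  if (!keep) return(list(probs = probs))
  cache$concat <- concat; cache$fcZ <- fcZ; cache$fcA <- fcA
  list(probs = probs, cache = cache)
}

# loss and full gradient for one batch; Y is n x 2 one-hot,
# sampleWeights length n (already normalized to mean 1)
nnLossGrad <- function(w, cfg, X, Y, sampleWeights = NULL) {
  fw <- nnForward(w, cfg, X, keep = TRUE)
  p <- fw$probs; cache <- fw$cache
  n <- nrow(X)
  sw <- if (is.null(sampleWeights)) rep(1, n) else sampleWeights
  eps <- 1e-12
  loss <- -sum(sw * log(rowSums(Y * p) + eps)) / n

  g <- list()
  dLogits <- (p - Y) * (sw / n)
  g$outW <- crossprod(cache$fcA, dLogits)
  g$outB <- colSums(dLogits)
  dFcA <- dLogits %*% t(w$outW)
  dFcZ <- reluBackward(cache$fcZ, dFcA)
  g$fcW <- crossprod(cache$concat, dFcZ)
  g$fcB <- colSums(dFcZ)
  dConcat <- dFcZ %*% t(w$fcW)

  geo <- routeGeometry(cfg)
  dUpFlat <- dConcat[, seq_len(geo$upOut), drop = FALSE]
  dLoFlat <- dConcat[, geo$upOut + seq_len(geo$loOut), drop = FALSE]

  dUp <- dUpFlat; dim(dUp) <- dim(cache$upPool$out)
  dUp <- poolBackward(cache$upPool, cfg@poolSize, dUp)
  for (i in 4:1) {
    dZ <- reluBackward(cache[[paste0("upZ", i)]], dUp)
    bk <- convBackward(cache[[paste0("upIn", i)]], w[[paste0("upW", i)]],
                       geo$upPad[i], dZ)
    g[[paste0("upW", i)]] <- bk$dW
    g[[paste0("upB", i)]] <- bk$db
    dUp <- bk$dX
  }
  dLo <- dLoFlat; dim(dLo) <- dim(cache$loPool$out)
  dLo <- poolBackward(cache$loPool, cfg@poolSize, dLo)
  for (i in 2:1) {
    dZ <- reluBackward(cache[[paste0("loZ", i)]], dLo)
    bk <- convBackward(cache[[paste0("loIn", i)]], w[[paste0("loW", i)]],
                       geo$loPad[i], dZ)
    g[[paste0("loW", i)]] <- bk$dW
    g[[paste0("loB", i)]] <- bk$db
    dLo <- bk$dX
  }
  list(loss = loss, grads = g[names(w)], probs = p)
}

#' Class label coding used by the classifier
#'
#' @return Character vector c("non-PVC", "PVC"); column order of the
#'   softmax head.
#' @export
pvcClassLevels <- function() c("non-PVC", "PVC")

oneHot <- function(labels) {
  lv <- pvcClassLevels()
  if (!all(labels %in% lv))
    stop(sprintf("labels must be one of: %s", paste(lv, collapse = ", ")))
  Y <- matrix(0, length(labels), 2L, dimnames = list(NULL, lv))
  Y[cbind(seq_along(labels), match(labels, lv))] <- 1
  Y
}

#' Train a PVCNet
#'
#' Minimizes cross-entropy with Adam (step learning-rate schedule:
#' learning rate multiplied by \code{lrDropFactor} every
#' \code{lrDropPeriod} epochs), shuffling each epoch under the config seed.
#' Optionally applies inverse-frequency class weights. Training is
#' bit-reproducible for a fixed config on a fixed platform.
#'
#' @param model an untrained (or trained) \linkS4class{PVCNet}.
#' @param X numeric matrix (windows x 10) of normalized features in [0, 1].
#' @param labels character vector, "PVC" / "non-PVC", one per row of X.
#' @param normParams optional \linkS4class{NormalizationParams} to store
#'   with the model.
#' @param verbose print per-epoch progress.
#' @return The trained \linkS4class{PVCNet} with per-epoch history.
#' @export
trainModel <- function(model, X, labels, normParams = NULL,
                       verbose = FALSE) {
  stopifnot(is(model, "PVCNet"))
  cfg <- model@config
  X <- as.matrix(X)
  if (ncol(X) != cfg@inputLength)
    stop(sprintf("feature matrix must have %d columns, got %d",
                 cfg@inputLength, ncol(X)))
  if (nrow(X) == 0L) stop("training set is empty")
  if (nrow(X) != length(labels))
    stop("one label per feature row is required")
  lv <- pvcClassLevels()
  present <- lv %in% labels
  if (!all(present))
    stop(sprintf("training set lacks class '%s'", lv[!present][1]))
  Y <- oneHot(labels)

  classW <- if (cfg@classWeights) {
    cw <- nrow(X) / (2 * colSums(Y))
    as.numeric(Y %*% cw)
  } else NULL

  w <- model@weights
  mAdam <- lapply(w, function(p) p * 0)
  vAdam <- lapply(w, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; epsA <- 1e-8
  step <- 0L
  hist <- vector("list", cfg@maxEpochs)

  withSeed(deriveSeed(cfg@seed, 1L), {
    for (epoch in seq_len(cfg@maxEpochs)) {
      lr <- cfg@learningRate *
        cfg@lrDropFactor^((epoch - 1L) %/% cfg@lrDropPeriod)
      ord <- sample.int(nrow(X))
      starts <- seq(1L, nrow(X), by = cfg@batchSize)
      epochLoss <- 0; epochCorrect <- 0L
      for (s in starts) {
        idx <- ord[s:min(s + cfg@batchSize - 1L, nrow(X))]
        lg <- nnLossGrad(w, cfg, X[idx, , drop = FALSE],
                         Y[idx, , drop = FALSE],
                         if (is.null(classW)) NULL else classW[idx])
        step <- step + 1L
        for (nm in names(w)) {
          gN <- lg$grads[[nm]]
          mAdam[[nm]] <- b1 * mAdam[[nm]] + (1 - b1) * gN
          vAdam[[nm]] <- b2 * vAdam[[nm]] + (1 - b2) * gN^2
          mHat <- mAdam[[nm]] / (1 - b1^step)
          vHat <- vAdam[[nm]] / (1 - b2^step)
          w[[nm]] <- w[[nm]] - lr * mHat / (sqrt(vHat) + epsA)
        }
        epochLoss <- epochLoss + lg$loss * length(idx)
        epochCorrect <- epochCorrect +
          sum(max.col(lg$probs, ties.method = "first") ==
                max.col(Y[idx, , drop = FALSE], ties.method = "first"))
      }
      hist[[epoch]] <- data.frame(epoch = epoch,
                                  loss = epochLoss / nrow(X),
                                  accuracy = epochCorrect / nrow(X),
                                  lr = lr)
      if (verbose)
        message(sprintf("epoch %2d  loss %.5f  acc %.4f  lr %g", epoch,
                        epochLoss / nrow(X), epochCorrect / nrow(X), lr))
    }
  })

  initialize(model, weights = w, history = do.call(rbind, hist),
             normParams = normParams, trained = TRUE)
}

#' Predict PVC / non-PVC labels for feature windows
#'
#' Runs the forward pass and returns the argmax class per window together
#' with the softmax probabilities. A data.frame containing the raw feature
#' columns is normalized with the model's stored parameters; a numeric
#' matrix is taken as already normalized.
#'
#' @param object a trained \linkS4class{PVCNet}.
#' @param newdata numeric matrix (windows x 10, normalized) or a feature
#'   data.frame.
#' @return A list: \code{label} (character vector) and \code{prob} (matrix
#'   of class probabilities, columns "non-PVC", "PVC").
#' @export
setMethod("predict", "PVCNet", function(object, newdata) {
  if (!object@trained)
    warning("model has not been trained; predictions use initial weights")
  X <- if (is.data.frame(newdata)) {
    if (is.null(object@normParams))
      stop("model holds no normalization parameters; supply a normalized matrix")
    applyNormalization(newdata, object@normParams)
  } else as.matrix(newdata)
  if (ncol(X) != object@config@inputLength)
    stop(sprintf("feature matrix must have %d columns, got %d",
                 object@config@inputLength, ncol(X)))
  p <- nnForward(object@weights, object@config, X)$probs
  colnames(p) <- pvcClassLevels()
  list(label = pvcClassLevels()[max.col(p, ties.method = "first")],
       prob = p)
})
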