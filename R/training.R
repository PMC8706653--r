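#' @include model.R
NULL

CE_EPS <- 1e-12

#' Create a training configuration
#'
#' Defaults follow the published protocol: Adam at learning rate 0.001
#' with reduce-on-plateau decay (factor 0.5, patience 10 epochs) floored
#' at 1e-7, categorical cross-entropy, up to 1000 epochs, early stopping
#' with patience 50 on verification loss, and retention of the
#' best-verification-loss parameter state.
#'
#' @param learningRate initial Adam learning rate.
#' @param lrFloor minimum learning rate.
#' @param maxEpochs epoch cap.
#' @param batchSize minibatch size.
#' @param earlyStopPatience early-stopping patience in epochs.
#' @param lrDecayFactor plateau decay factor.
#' @param lrDecayPatience plateau patience in epochs.
#' @param seed RNG seed (shuffling, dropout).
#' @return A \linkS4class{TrainConfig}.
#' @export
trainConfig <- function(learningRate = 0.001, lrFloor = 1e-7,
                        maxEpochs = 1000L, batchSize = 64L,
                        earlyStopPatience = 50L, lrDecayFactor = 0.5,
                        lrDecayPatience = 10L, seed = 1L) {
  new("TrainConfig", learningRate = learningRate, lrFloor = lrFloor,
      maxEpochs = as.integer(maxEpochs), batchSize = as.integer(batchSize),
      earlyStopPatience = as.integer(earlyStopPatience),
      lrDecayFactor = lrDecayFactor,
      lrDecayPatience = as.integer(lrDecayPatience), seed = as.integer(seed))
}

#' Categorical cross-entropy
#'
#' Mean over rows of `-log p(true class)`, with probabilities clamped at
#' 1e-12 so a zero probability at the true class yields a large finite
#' loss rather than infinity. Zero iff every prediction is a confident
#' correct one-hot.
#'
#' @param probabilities `N x K` matrix with rows summing to 1.
#' @param labels integer true classes in 1..K.
#' @return Nonnegative scalar.
#' @export
#' @examples
#' crossEntropy(matrix(1/6, 2, 6), c(1, 5))  # log(6)
crossEntropy <- function(probabilities, labels) {
  stopifnot(nrow(probabilities) == length(labels))
  pTrue <- probabilities[cbind(seq_along(labels), labels)]
  mean(-log(pmax(pTrue, CE_EPS)))
}

#' Train a fusion model
#'
#' Minimizes categorical cross-entropy with Adam. After every epoch the
#' verification loss is computed in inference mode; the learning rate is
#' halved after `lrDecayPatience` epochs without improvement (never below
#' `lrFloor`), training stops after `earlyStopPatience` epochs without
#' improvement or at `maxEpochs`, and the returned model carries the
#' parameter state of the best verification-loss epoch. Deterministic for
#' a fixed seed and thread count.
#'
#' @param model a fresh or pre-trained \linkS4class{FusionModel}.
#' @param train,verification disjoint, normalized
#'   \linkS4class{WindowSet}s; the verification set drives decay and
#'   stopping and must be nonempty.
#' @param cfg a [trainConfig()].
#' @param verbose print one line per epoch.
#' @return List with the trained `model` and the `history` data frame
#'   (epoch, lr, train_loss, train_acc, ver_loss, ver_acc) carrying the
#'   best epoch in `attr(history, "bestEpoch")`.
#' @export
trainModel <- function(model, train, verification, cfg = trainConfig(),
                       verbose = FALSE) {
  stopifnot(is(model, "FusionModel"), is(train, "WindowSet"))
  validObject(cfg)
  if (nWindows(verification) == 0L)
    stop("verification set is empty; early stopping is undefined")
  nClasses <- model@config@nClasses
  Xtr <- asModelInput(train)
  ytr <- activityLabels(train)
  Xver <- asModelInput(verification)
  yver <- activityLabels(verification)
  n <- length(ytr)
  onehot <- diag(nClasses)

  p <- model@params
  m <- lapply(p, function(a) array(0, dim = dim(a) %||% length(a)))
  v <- m
  beta1 <- 0.9; beta2 <- 0.999; adamEps <- 1e-8
  tStep <- 0L
  lr <- cfg@learningRate

  best <- list(loss = Inf, params = p, state = model@state, epoch = 0L)
  sinceBest <- 0L
  sinceDecay <- 0L
  hist <- vector("list", cfg@maxEpochs)

  set.seed(cfg@seed)
  for (epoch in seq_len(cfg@maxEpochs)) {
    perm <- sample.int(n)
    epochLoss <- 0; epochCorrect <- 0
    for (s in seq.int(1L, n, by = cfg@batchSize)) {
      idx <- perm[s:min(s + cfg@batchSize - 1L, n)]
      B <- length(idx)
      Xb <- Xtr[, idx, , drop = FALSE]
      yb <- ytr[idx]
      fw <- fusionForward(model, Xb, training = TRUE)
      model@state <- fw$state
      loss <- crossEntropy(fw$probs, yb)
      if (!is.finite(loss))
        stop(sprintf("non-finite loss at epoch %d", epoch))
      epochLoss <- epochLoss + loss * B
      epochCorrect <- epochCorrect +
        sum(max.col(fw$probs, ties.method = "first") == yb)
      dLogits <- (fw$probs - onehot[yb, , drop = FALSE]) / B
      grads <- fusionBackward(model, fw$cache, dLogits)
      tStep <- tStep + 1L
      corr <- sqrt(1 - beta2^tStep) / (1 - beta1^tStep)
      for (nm in names(grads)) {
        g <- grads[[nm]]
        m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * g
        v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * g * g
        model@params[[nm]] <- model@params[[nm]] -
          lr * corr * m[[nm]] / (sqrt(v[[nm]]) + adamEps)
      }
    }
    verProbs <- predictProba(model, aperm(Xver, c(1, 3, 2)))
    verLoss <- crossEntropy(verProbs, yver)
    verAcc <- mean(max.col(verProbs, ties.method = "first") == yver)
    hist[[epoch]] <- data.frame(
      epoch = epoch, lr = lr, train_loss = epochLoss / n,
      train_acc = epochCorrect / n, ver_loss = verLoss, ver_acc = verAcc)
    if (verbose)
      message(sprintf(
        "epoch %3d lr %.2e train loss %.4f acc %.3f | ver loss %.4f acc %.3f",
        epoch, lr, epochLoss / n, epochCorrect / n, verLoss, verAcc))
    if (verLoss < best$loss - 1e-10) {
      best <- list(loss = verLoss, params = model@params,
                   state = model@state, epoch = epoch)
      sinceBest <- 0L
      sinceDecay <- 0L
    } else {
      sinceBest <- sinceBest + 1L
      sinceDecay <- sinceDecay + 1L
    }
    if (sinceDecay >= cfg@lrDecayPatience && lr > cfg@lrFloor) {
      lr <- max(lr * cfg@lrDecayFactor, cfg@lrFloor)
      sinceDecay <- 0L
    }
    if (sinceBest >= cfg@earlyStopPatience) break
  }
  history <- do.call(rbind, hist[!vapply(hist, is.null, TRUE)])
  attr(history, "bestEpoch") <- best$epoch
  attr(history, "finalLr") <- lr
  model@params <- best$params
  model@state <- best$state
  model@epochsTrained <- nrow(history)
  list(model = model, history = history)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save / load a model checkpoint
#'
#' `saveModel` writes the binary parameter state plus a sidecar JSON
#' manifest (architecture configuration, seed, epochs trained) sufficient
#' to rebuild the model; `loadModel` restores it.
#'
#' @param model a \linkS4class{FusionModel}.
#' @param path checkpoint path (`.rds`); the manifest is written next to
#'   it as `<path>.json`.
#' @return `saveModel`: `path` invisibly; `loadModel`: the model.
#' @export
saveModel <- function(model, path) {
  saveRDS(model, path)
  cfg <- model@config
  manifest <- list(
    class = "FusionModel",
    windowLen = cfg@windowLen, nChannels = cfg@nChannels,
    kernelSizes = cfg@kernelSizes, filters = cfg@filters,
    fcWidths = cfg@fcWidths, dropout = cfg@dropout,
    nClasses = cfg@nClasses, batchNorm = cfg@batchNorm,
    dropoutConv = cfg@dropoutConv, seed = model@seed,
    epochsTrained = model@epochsTrained, nParameters = nParameters(model))
  write_json(manifest, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  model <- readRDS(path)
  stopifnot(is(model, "FusionModel"))
  model
}
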