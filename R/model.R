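#' @include layers.R AllClasses.R
NULL

ZONES <- c("A", "B", "C")

#' Create a fusion-network configuration
#'
#' Defaults reproduce the published design: three zones with kernel sizes
#' 1/3/5, convolution stages of 32/64/128 filters at stride 1 with same
#' padding, batch normalization before each ReLU, dropout 0.3, fully
#' connected widths 256 and 512, and a 6-class softmax output. The
#' architecture is length-parametric: only the flatten/concatenation
#' widths depend on `windowLen`.
#'
#' @param windowLen window length L in samples.
#' @param nChannels input channels (6).
#' @param kernelSizes per-zone odd kernel sizes.
#' @param filters filters of the three convolution stages.
#' @param fcWidths the two fully connected widths.
#' @param dropout dropout rate.
#' @param nClasses output classes.
#' @param batchNorm use batch normalization.
#' @param dropoutConv apply dropout inside zones too (default), not only
#'   between the fully connected layers.
#' @return A \linkS4class{ModelConfig}.
#' @export
#' @examples
#' cfg <- modelConfig(windowLen = 150)
#' flattenWidths(cfg)
modelConfig <- function(windowLen, nChannels = 6, kernelSizes = c(1, 3, 5),
                        filters = c(32, 64, 128), fcWidths = c(256, 512),
                        dropout = 0.3, nClasses = 6, batchNorm = TRUE,
                        dropoutConv = TRUE) {
  new("ModelConfig", windowLen = as.integer(windowLen),
      nChannels = as.integer(nChannels),
      kernelSizes = as.integer(kernelSizes), filters = as.integer(filters),
      fcWidths = as.integer(fcWidths), dropout = dropout,
      nClasses = as.integer(nClasses), batchNorm = batchNorm,
      dropoutConv = dropoutConv)
}

#' Flatten and concatenation widths of a configuration
#'
#' With same padding every zone preserves the window length, so each
#' branch flattens to `windowLen * filters[3]` features and the fused
#' representation has `length(kernelSizes)` times that.
#'
#' @param cfg a \linkS4class{ModelConfig}.
#' @return List with `branch` and `concat` widths.
#' @export
flattenWidths <- function(cfg) {
  branch <- cfg@windowLen * cfg@filters[3]
  list(branch = branch, concat = length(cfg@kernelSizes) * branch)
}

initUniform <- function(dims, fanIn) {
  lim <- 1 / sqrt(fanIn)
  array(runif(prod(dims), -lim, lim), dim = dims)
}

#' Build an untrained fusion model
#'
#' Initializes all parameters with a uniform fan-in scheme under the
#' given seed; two models built with the same configuration and seed are
#' identical.
#'
#' @param cfg a \linkS4class{ModelConfig}.
#' @param seed initialization seed.
#' @return A \linkS4class{FusionModel}.
#' @export
buildModel <- function(cfg, seed = 1L) {
  validObject(cfg)
  params <- list()
  state <- list()
  withr_seed(seed, {
    for (z in seq_along(cfg@kernelSizes)) {
      zn <- ZONES[z]
      k <- cfg@kernelSizes[z]
      cin <- cfg@nChannels
      for (i in 1:3) {
        f <- cfg@filters[i]
        key <- sprintf("%s.conv%d", zn, i)
        params[[paste0(key, ".W")]] <- initUniform(c(cin * k, f), cin * k)
        params[[paste0(key, ".b")]] <- numeric(f)
        if (cfg@batchNorm) {
          params[[paste0(key, ".g")]] <- rep(1, f)
          params[[paste0(key, ".beta")]] <- numeric(f)
          state[[paste0(key, ".rmean")]] <- numeric(f)
          state[[paste0(key, ".rvar")]] <- rep(1, f)
        }
        cin <- f
      }
    }
    concat <- flattenWidths(cfg)$concat
    params[["fc1.W"]] <- initUniform(c(concat, cfg@fcWidths[1]), concat)
    params[["fc1.b"]] <- numeric(cfg@fcWidths[1])
    params[["fc2.W"]] <- initUniform(c(cfg@fcWidths[1], cfg@fcWidths[2]),
                                     cfg@fcWidths[1])
    params[["fc2.b"]] <- numeric(cfg@fcWidths[2])
    params[["out.W"]] <- initUniform(c(cfg@fcWidths[2], cfg@nClasses),
                                     cfg@fcWidths[2])
    params[["out.b"]] <- numeric(cfg@nClasses)
  })
  new("FusionModel", config = cfg, params = params, state = state,
      seed = as.integer(seed), epochsTrained = 0L)
}

#' Number of trainable parameters
#'
#' @param model a \linkS4class{FusionModel}.
#' @return Integer count over all weights, biases and batch-norm
#'   scale/shift terms (running statistics are not trainable).
#' @export
nParameters <- function(model) {
  sum(vapply(model@params, length, 1L))
}

setMethod("show", "FusionModel", function(object) {
  cfg <- object@config
  fw <- flattenWidths(cfg)
  cat(sprintf(
    "FusionModel: L=%d, zones k=(%s), filters (%s), fc (%s), %d classes\n",
    cfg@windowLen, paste(cfg@kernelSizes, collapse = ","),
    paste(cfg@filters, collapse = ","), paste(cfg@fcWidths, collapse = ","),
    cfg@nClasses))
  cat(sprintf("  fused width %d, %d trainable parameters, %d epochs trained\n",
              fw$concat, nParameters(object), object@epochsTrained))
})

# Forward pass. X is (L, B, nChannels). Returns probabilities and, when
# collectCache, everything backpropagation needs. In training mode
# dropout is active (global RNG) and batch-norm uses batch statistics;
# state carries the updated running statistics.
fusionForward <- function(model, X, training = FALSE, collectCache = training) {
  cfg <- model@config
  p <- model@params
  st <- model@state
  d <- dim(X)
  L <- d[1]; B <- d[2]
  cache <- list(branches = list())
  flats <- vector("list", length(cfg@kernelSizes))
  for (z in seq_along(cfg@kernelSizes)) {
    zn <- ZONES[z]
    k <- cfg@kernelSizes[z]
    h <- X
    layers <- list()
    for (i in 1:3) {
      key <- sprintf("%s.conv%d", zn, i)
      cv <- conv1dForward(h, p[[paste0(key, ".W")]], p[[paste0(key, ".b")]], k)
      Y <- cv$Y
      lay <- list(conv = cv[c("M", "L", "B", "Cin", "k")])
      if (cfg@batchNorm) {
        bn <- bnForward(Y, p[[paste0(key, ".g")]], p[[paste0(key, ".beta")]],
                        st[[paste0(key, ".rmean")]],
                        st[[paste0(key, ".rvar")]], training)
        Y <- bn$out
        if (training) {
          st[[paste0(key, ".rmean")]] <- bn$rmean
          st[[paste0(key, ".rvar")]] <- bn$rvar
        }
        lay$bn <- bn[c("xhat", "inv")]
      }
      mask <- Y > 0
      Y[!mask] <- 0
      lay$relu <- mask
      if (training && cfg@dropoutConv && cfg@dropout > 0) {
        dm <- dropoutMask(length(Y), cfg@dropout)
        Y <- Y * dm
        lay$drop <- dm
      }
      if (collectCache) layers[[i]] <- lay
      dim(Y) <- c(L, B, cfg@filters[i])
      h <- Y
    }
    # flatten: (L, B, F) -> B x (L*F), time fastest within each filter
    fl <- aperm(h, c(1, 3, 2))
    dim(fl) <- c(L * cfg@filters[3], B)
    flats[[z]] <- t(fl)
    if (collectCache) cache$branches[[zn]] <- layers
  }
  Z <- do.call(cbind, flats)
  if (collectCache) cache$concat <- Z

  denseStep <- function(Z, key, act = TRUE) {
    H <- addBias(Z %*% p[[paste0(key, ".W")]], p[[paste0(key, ".b")]])
    lay <- list(input = Z)
    if (act) {
      mask <- H > 0
      H[!mask] <- 0
      lay$relu <- mask
      if (training && cfg@dropout > 0) {
        dm <- dropoutMask(length(H), cfg@dropout)
        H <- H * dm
        lay$drop <- dm
      }
    }
    list(H = H, lay = lay)
  }
  s1 <- denseStep(Z, "fc1")
  s2 <- denseStep(s1$H, "fc2")
  so <- denseStep(s2$H, "out", act = FALSE)
  if (collectCache) {
    cache$fc1 <- s1$lay; cache$fc2 <- s2$lay; cache$out <- so$lay
    cache$dims <- c(L = L, B = B)
  }
  probs <- softmaxRows(so$H)
  list(probs = probs, logits = so$H, cache = if (collectCache) cache,
       state = st)
}

# Backward pass from dLogits (B x nClasses); returns gradients named like
# the parameters.
fusionBackward <- function(model, cache, dLogits) {
  cfg <- model@config
  p <- model@params
  g <- list()
  L <- cache$dims[["L"]]; B <- cache$dims[["B"]]

  denseBack <- function(dH, key, lay) {
    if (!is.null(lay$drop)) dH <- dH * lay$drop
    if (!is.null(lay$relu)) dH <- dH * lay$relu
    g[[paste0(key, ".W")]] <<- crossprod(lay$input, dH)
    g[[paste0(key, ".b")]] <<- colSums(dH)
    tcrossprod(dH, p[[paste0(key, ".W")]])
  }
  dZ2 <- denseBack(dLogits, "out", cache$out)
  dZ1 <- denseBack(dZ2, "fc2", cache$fc2)
  dZ0 <- denseBack(dZ1, "fc1", cache$fc1)

  bw <- flattenWidths(cfg)$branch
  for (z in seq_along(cfg@kernelSizes)) {
    zn <- ZONES[z]
    k <- cfg@kernelSizes[z]
    dFl <- dZ0[, ((z - 1) * bw + 1):(z * bw), drop = FALSE]
    dH <- t(dFl)
    dim(dH) <- c(L, cfg@filters[3], B)
    dH <- aperm(dH, c(1, 3, 2))
    dY <- dH
    dim(dY) <- c(L * B, cfg@filters[3])
    for (i in 3:1) {
      key <- sprintf("%s.conv%d", zn, i)
      lay <- cache$branches[[zn]][[i]]
      if (!is.null(lay$drop)) dY <- dY * lay$drop
      dY <- dY * lay$relu
      if (cfg@batchNorm) {
        bb <- bnBackward(dY, lay$bn$xhat, lay$bn$inv, p[[paste0(key, ".g")]])
        g[[paste0(key, ".g")]] <- bb$dgamma
        g[[paste0(key, ".beta")]] <- bb$dbeta
        dY <- bb$dY
      }
      cb <- conv1dBackward(dY, lay$conv, p[[paste0(key, ".W")]])
      g[[paste0(key, ".W")]] <- cb$dW
      g[[paste0(key, ".b")]] <- cb$db
      if (i > 1) {
        dY <- cb$dX
        dim(dY) <- c(L * B, cfg@filters[i - 1])
      }
    }
  }
  g
}

asModelInput <- function(x) {
  if (is(x, "WindowSet")) x <- windowArray(x)
  stopifnot(length(dim(x)) == 3L)
  aperm(x, c(1, 3, 2))                       # (L, 6, N) -> (L, N, 6)
}

#' Class probabilities for a batch of windows
#'
#' Runs the model in inference mode (dropout inactive, batch-norm running
#' statistics), in chunks to bound memory. Deterministic.
#'
#' @param model a \linkS4class{FusionModel}.
#' @param newdata a \linkS4class{WindowSet} or `L x 6 x N` array of
#'   normalized windows.
#' @param batchSize chunk size.
#' @return `N x nClasses` matrix; rows are nonnegative and sum to 1.
#' @export
predictProba <- function(model, newdata, batchSize = 256L) {
  X <- asModelInput(newdata)
  if (dim(X)[3] != model@config@nChannels) stop("wrong channel count")
  n <- dim(X)[2]
  out <- matrix(0, n, model@config@nClasses)
  for (s in seq.int(1L, n, by = batchSize)) {
    e <- min(s + batchSize - 1L, n)
    fw <- fusionForward(model, X[, s:e, , drop = FALSE], training = FALSE,
                        collectCache = FALSE)
    out[s:e, ] <- fw$probs
  }
  out
}

#' Predicted activity labels
#'
#' Argmax over class probabilities; ties break toward the lowest class
#' index.
#'
#' @param model a \linkS4class{FusionModel}.
#' @param newdata windows as in [predictProba()].
#' @param batchSize chunk size.
#' @return Integer label vector.
#' @export
predictActivities <- function(model, newdata, batchSize = 256L) {
  probs <- predictProba(model, newdata, batchSize)
  max.col(probs, ties.method = "first")
}
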