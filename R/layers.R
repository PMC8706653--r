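# Internal neural-network primitives. Activations flow as (L*B) x F
# matrices for convolution stages (row order: time fastest, then batch)
# and B x units matrices for dense stages; all heavy lifting is BLAS
# matrix multiplication via an im2col expansion.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

addBias <- function(Y, b) Y + rep(b, each = nrow(Y))

# Same-padded 1-D convolution over the time axis of X (L, B, Cin).
# W is (Cin*k) x F with rows grouped channel-major: row (c-1)*k + j is
# channel c, tap j. Returns Y as (L*B) x F plus the im2col matrix.
conv1dForward <- function(X, W, b, k) {
  d <- dim(X)
  L <- d[1]; B <- d[2]; Cin <- d[3]
  pad <- (k - 1L) %/% 2L
  if (k == 1L) {
    M <- X
    dim(M) <- c(L * B, Cin)
  } else {
    Xp <- array(0, dim = c(L + k - 1L, B, Cin))
    Xp[(pad + 1L):(pad + L), , ] <- X
    M <- matrix(0, L * B, Cin * k)
    for (j in seq_len(k)) {
      block <- Xp[j:(j + L - 1L), , , drop = FALSE]
      dim(block) <- c(L * B, Cin)
      M[, j + (seq_len(Cin) - 1L) * k] <- block
    }
  }
  list(Y = addBias(M %*% W, b), M = M, L = L, B = B, Cin = Cin, k = k)
}

conv1dBackward <- function(dY, cache, W) {
  L <- cache$L; B <- cache$B; Cin <- cache$Cin; k <- cache$k
  pad <- (k - 1L) %/% 2L
  dW <- crossprod(cache$M, dY)
  db <- colSums(dY)
  dM <- tcrossprod(dY, W)
  if (k == 1L) {
    dX <- dM
    dim(dX) <- c(L, B, Cin)
  } else {
    dXp <- array(0, dim = c(L + k - 1L, B, Cin))
    for (j in seq_len(k)) {
      blk <- dM[, j + (seq_len(Cin) - 1L) * k, drop = FALSE]
      dim(blk) <- c(L, B, Cin)
      dXp[j:(j + L - 1L), , ] <- dXp[j:(j + L - 1L), , , drop = FALSE] + blk
    }
    dX <- dXp[(pad + 1L):(pad + L), , , drop = FALSE]
    dim(dX) <- c(L, B, Cin)
  }
  list(dX = dX, dW = dW, db = db)
}

# Batch normalization over rows, per column (feature). In training mode
# batch statistics are used and running statistics updated; in inference
# mode the running statistics are used.
bnForward <- function(Y, gamma, beta, rmean, rvar, training) {
  if (training) {
    mu <- colMeans(Y)
    yc <- sweep(Y, 2L, mu)
    v <- colMeans(yc * yc)
    inv <- 1 / sqrt(v + BN_EPS)
    xhat <- sweep(yc, 2L, inv, "*")
    rmean <- BN_MOMENTUM * rmean + (1 - BN_MOMENTUM) * mu
    rvar <- BN_MOMENTUM * rvar + (1 - BN_MOMENTUM) * v
  } else {
    inv <- 1 / sqrt(rvar + BN_EPS)
    xhat <- sweep(sweep(Y, 2L, rmean), 2L, inv, "*")
  }
  out <- sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
  list(out = out, xhat = xhat, inv = inv, rmean = rmean, rvar = rvar)
}

bnBackward <- function(dOut, xhat, inv, gamma) {
  dgamma <- colSums(dOut * xhat)
  dbeta <- colSums(dOut)
  dxhat <- sweep(dOut, 2L, gamma, "*")
  t1 <- colMeans(dxhat)
  t2 <- colMeans(dxhat * xhat)
  dY <- sweep(sweep(dxhat, 2L, t1) - sweep(xhat, 2L, t2, "*"), 2L, inv, "*")
  list(dY = dY, dgamma = dgamma, dbeta = dbeta)
}

dropoutMask <- function(n, rate) {
  if (rate <= 0) return(NULL)
  (runif(n) >= rate) / (1 - rate)
}

softmaxRows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}
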