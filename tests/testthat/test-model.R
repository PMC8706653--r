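test_that("flatten/concat widths match hand-derived shape arithmetic", {
  # same padding preserves length: branch flatten = L * 128, concat = 3x
  w128 <- flattenWidths(modelConfig(windowLen = 128))
  expect_equal(w128$branch, 16384)
  expect_equal(w128$concat, 49152)
  w150 <- flattenWidths(modelConfig(windowLen = 150))
  expect_equal(w150$branch, 19200)
  expect_equal(w150$concat, 57600)
})

test_that("parameter count matches an independent layer-by-layer formula", {
  # oracle written from the architecture definition, not from the code:
  # conv stage: (Cin*k)*F weights + F bias + 2F batch-norm scale/shift;
  # dense: in*out + out.
  oracleCount <- function(L, kernels = c(1, 3, 5), filters = c(32, 64, 128),
                          fc = c(256, 512), nClasses = 6, bn = TRUE) {
    total <- 0
    for (k in kernels) {
      cin <- 6
      for (f in filters) {
        total <- total + cin * k * f + f + if (bn) 2 * f else 0
        cin <- f
      }
    }
    concat <- length(kernels) * L * filters[3]
    total + concat * fc[1] + fc[1] + fc[1] * fc[2] + fc[2] +
      fc[2] * nClasses + nClasses
  }
  for (L in c(128, 150)) {
    cfg <- modelConfig(windowLen = L)
    expect_equal(nParameters(buildModel(cfg, seed = 1)), oracleCount(L))
  }
  # tiny config too
  cfgT <- tinyModelConfig(L = 20)
  expect_equal(nParameters(buildModel(cfgT, seed = 2)),
               oracleCount(20, filters = c(4, 6, 8), fc = c(16, 24)))
  # without batch norm the scale/shift terms disappear
  cfgNb <- modelConfig(windowLen = 20, filters = c(4, 6, 8),
                       fcWidths = c(16, 24), batchNorm = FALSE)
  expect_equal(nParameters(buildModel(cfgNb, seed = 2)),
               oracleCount(20, filters = c(4, 6, 8), fc = c(16, 24),
                           bn = FALSE))
})

test_that("removing one zone removes exactly that branch's contribution", {
  branchContribution <- function(k, L, filters = c(4, 6, 8), fc1 = 16) {
    cin <- 6
    total <- 0
    for (f in filters) {
      total <- total + cin * k * f + f + 2 * f
      cin <- f
    }
    # the branch also feeds L*filters[3] inputs into the first dense layer
    total + L * filters[3] * fc1
  }
  L <- 18
  full <- nParameters(buildModel(tinyModelConfig(L), seed = 1))
  for (drop in 1:3) {
    kern <- c(1, 3, 5)
    reduced <- modelConfig(windowLen = L, kernelSizes = kern[-drop],
                           filters = c(4, 6, 8), fcWidths = c(16, 24))
    got <- nParameters(buildModel(reduced, seed = 1))
    expect_equal(full - got, branchContribution(kern[drop], L))
  }
})

test_that("forward pass yields valid, deterministic probabilities", {
  cfg <- tinyModelConfig(L = 16)
  model <- buildModel(cfg, seed = 10)
  set.seed(1)
  ws <- makeWindowSet(n = 7, L = 16, seed = 2)
  probs <- predictProba(model, ws)
  expect_equal(dim(probs), c(7, 6))
  expect_true(all(probs >= 0))
  expect_equal(rowSums(probs), rep(1, 7), tolerance = 1e-6)
  # inference is deterministic: identical inputs, identical outputs
  expect_identical(probs, predictProba(model, ws))
  # identical windows map to identical rows
  arr <- windowArray(ws)
  arr[, , 2] <- arr[, , 1]
  ws2 <- WindowSet(arr, labels = activityLabels(ws))
  p2 <- predictProba(model, ws2)
  expect_equal(p2[1, ], p2[2, ])
  expect_error(predictProba(model, array(0, dim = c(16, 4, 7))),
               "channel")
})

test_that("seeded initialization is reproducible and seed-sensitive", {
  cfg <- tinyModelConfig(L = 12)
  m1 <- buildModel(cfg, seed = 42)
  m2 <- buildModel(cfg, seed = 42)
  expect_identical(m1@params, m2@params)
  ws <- makeWindowSet(n = 4, L = 12, seed = 3)
  expect_identical(predictProba(m1, ws), predictProba(m2, ws))
  m3 <- buildModel(cfg, seed = 43)
  expect_false(identical(m1@params, m3@params))
})

test_that("length-parametric build works at 128 and 150 and guards zero input", {
  for (L in c(128, 150)) {
    model <- buildModel(modelConfig(windowLen = L, filters = c(4, 6, 8),
                                    fcWidths = c(8, 8)), seed = 1)
    zeros <- array(0, dim = c(L, 6, 2))
    probs <- predictProba(model, zeros)
    expect_true(all(is.finite(probs)))     # batch-norm epsilon guard
    expect_equal(rowSums(probs), rep(1, 2), tolerance = 1e-6)
  }
  expect_error(modelConfig(windowLen = 3), "largest kernel")
})

test_that("predictActivities takes the argmax with first-index tie-breaking", {
  # argmax contract checked against a brute-force oracle on random rows
  set.seed(6)
  probs <- matrix(runif(100 * 6), 100)
  probs <- probs / rowSums(probs)
  oracle <- apply(probs, 1, function(r) which(r == max(r))[1])
  expect_equal(max.col(probs, ties.method = "first"), oracle)
  # ties break to the lowest class index
  expect_equal(max.col(matrix(c(0.5, 0.5, 0, 0, 0, 0), 1),
                       ties.method = "first"), 1)
  # and the model path agrees with row-wise argmax of predictProba
  model <- buildModel(tinyModelConfig(L = 10), seed = 4)
  ws <- makeWindowSet(n = 20, L = 10, seed = 5)
  p <- predictProba(model, ws)
  expect_equal(predictActivities(model, ws),
               apply(p, 1, function(r) which(r == max(r))[1]))
})

test_that("backpropagation matches numerical gradients on a small model", {
  cfg <- modelConfig(windowLen = 8, filters = c(2, 3, 4), fcWidths = c(5, 6),
                     dropout = 0)
  model <- buildModel(cfg, seed = 3)
  set.seed(1)
  B <- 3
  X <- array(rnorm(8 * B * 6), dim = c(8, B, 6))
  y <- c(1, 3, 6)
  lossOf <- function(m) {
    fw <- harfusion:::fusionForward(m, X, training = TRUE,
                                    collectCache = FALSE)
    crossEntropy(fw$probs, y)
  }
  fw <- harfusion:::fusionForward(model, X, training = TRUE)
  dLogits <- (fw$probs - diag(6)[y, ]) / B
  grads <- harfusion:::fusionBackward(model, fw$cache, dLogits)
  eps <- 1e-6
  set.seed(2)
  for (nm in c("A.conv1.W", "B.conv2.g", "C.conv3.W", "C.conv1.b",
               "fc1.W", "out.b")) {
    g <- grads[[nm]]
    for (i in sample(length(g), min(3, length(g)))) {
      up <- model; up@params[[nm]][i] <- up@params[[nm]][i] + eps
      dn <- model; dn@params[[nm]][i] <- dn@params[[nm]][i] - eps
      num <- (lossOf(up) - lossOf(dn)) / (2 * eps)
      expect_equal(g[i], num, tolerance = 1e-4)
    }
  }
})
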