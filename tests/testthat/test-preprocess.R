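test_that("raw counts convert by the stated sensitivities", {
  counts <- rbind(c(2048, -4096, 1024, 16.4, -32.8, 0),
                  c(0, 2048, 4096, 164, 16.4, 8.2))
  phys <- convertRaw(counts, sensorSpec())
  expect_equal(phys[1, 1], 1.0)        # 2048 LSB -> 1 g
  expect_equal(phys[1, 2], -2.0)       # linearity
  expect_equal(phys[1, 4], 1.0)        # 16.4 LSB -> 1 deg/s
  expect_equal(phys[2, 4], 10.0)
  expect_equal(phys[2, 6], 0.5)
  expect_error(convertRaw(counts[, 1:5]), "6 columns")
})

test_that("precision calibration rounds to 7 significant digits, idempotently", {
  expect_equal(calibratePrecision(0.123456789), 0.1234568)
  expect_equal(calibratePrecision(1.0), 1.0)
  set.seed(4)
  x <- rnorm(1000) * 10^sample(-3:3, 1000, replace = TRUE)
  once <- calibratePrecision(x)
  expect_identical(calibratePrecision(once), once)
  expect_error(calibratePrecision(c(1, NaN, 2)), "index 2")
  expect_error(calibratePrecision(c(1, 2, Inf)), "index 3")
})

test_that("min-max normalization maps train to exactly [-1, 1] and clips test", {
  # hand case: channel values {0, 5, 10}
  arr <- array(0, dim = c(3, 6, 1))
  arr[, 1, 1] <- c(0, 5, 10)
  ws <- WindowSet(arr, labels = 1)
  p <- fitMinMax(ws)
  expect_equal(p@mins[1], 0)
  expect_equal(p@maxs[1], 10)
  out <- windowArray(normalizeWindows(ws, p))[, 1, 1]
  expect_equal(out, c(-1, 0, 1))
  expect_true(p@degenerate[2])                   # all-constant channel
  expect_equal(windowArray(normalizeWindows(ws, p))[, 2, 1], c(0, 0, 0))

  # clipping of out-of-range test values
  arr2 <- arr
  arr2[, 1, 1] <- c(-3, 5, 12)
  out2 <- windowArray(normalizeWindows(WindowSet(arr2, labels = 1), p))[, 1, 1]
  expect_equal(out2, c(-1, 0, 1))

  # property: per-channel extremes of the normalized training set are -1/+1
  for (seed in 1:3) {
    tr <- makeWindowSet(n = 8, L = 12, seed = seed)
    ntr <- windowArray(normalizeWindows(tr, fitMinMax(tr)))
    for (c in 1:6) {
      expect_equal(min(ntr[, c, ]), -1)
      expect_equal(max(ntr[, c, ]), 1)
    }
  }
})

test_that("normalization parameters never read test data", {
  tr <- makeWindowSet(n = 6, L = 12, seed = 1)
  te <- makeWindowSet(n = 6, L = 12, seed = 2)
  before <- fitMinMax(tr)
  # mutate the "test" object; refit on train must be unchanged
  te2 <- normalizeWindows(te, before)
  after <- fitMinMax(tr)
  expect_identical(before@mins, after@mins)
  expect_identical(before@maxs, after@maxs)
  # and the fit differs from one that did see test data
  both <- combineSets(tr, te)
  expect_false(identical(fitMinMax(both)@mins, before@mins))
})

test_that("segmentation enumerates sliding-window starts correctly", {
  # 2.56 s at 50 Hz -> 128-sample windows
  rec <- SixAxisRecording(matrix(rnorm(300 * 6), 300, 6), labels = 2L)
  ws <- segmentRecording(rec, 2.56, overlap = 0.5)
  expect_equal(windowLength(ws), 128)
  # brute-force oracle: starts s with s + L - 1 <= N at stride 64
  expect_equal(nWindows(ws), length(seq(1, 300 - 128 + 1, by = 64)))
  expect_equal(nWindows(ws), 3)
  # window content matches the stream at starts 1, 65, 129
  arr <- windowArray(ws)
  expect_equal(arr[, , 2], rec@signal[65:192, ], ignore_attr = TRUE)

  # 3 s at 50 Hz flattens to 900 features
  ws3 <- segmentRecording(rec, 3, overlap = 0)
  expect_equal(length(flattenWindow(windowArray(ws3)[, , 1])), 900)

  # windows straddling a label change are dropped
  rec2 <- SixAxisRecording(matrix(0, 100, 6),
                           labels = rep(c(1L, 2L), each = 50))
  ws2 <- segmentRecording(rec2, 0.5, overlap = 0)  # L = 25, 4 windows fit
  expect_equal(nWindows(ws2), 4)
  recMix <- SixAxisRecording(matrix(0, 100, 6),
                             labels = c(rep(1L, 60), rep(2L, 40)))
  wsMix <- segmentRecording(recMix, 0.5, overlap = 0)
  expect_equal(nWindows(wsMix), 3)                 # window 3 straddles
  expect_equal(activityLabels(wsMix), c(1L, 1L, 2L))

  # stream shorter than one window: empty set with warning
  expect_warning(out <- segmentRecording(rec, 10), "empty")
  expect_equal(nWindows(out), 0)
})

test_that("flatten is channel-blocked and invertible", {
  w <- matrix(1:12, nrow = 2, ncol = 6)      # [[1..6],[7..12]] row-wise
  w <- rbind(1:6, 7:12)
  v <- flattenWindow(w)
  expect_equal(v, c(1, 7, 2, 8, 3, 9, 4, 10, 5, 11, 6, 12))
  expect_equal(unflattenWindow(v, 2), w, ignore_attr = TRUE)
  set.seed(5)
  w150 <- matrix(rnorm(900), 150, 6)
  expect_length(flattenWindow(w150), 900)
  expect_equal(unflattenWindow(flattenWindow(w150), 150), w150,
               ignore_attr = TRUE)
})

test_that("splitDataset reproduces the recording protocol's bookkeeping", {
  # one class of 2,310 windows -> 1,293 train / 324 verification / 693 test
  ws <- WindowSet(array(0, dim = c(2, 6, 2310)), labels = rep(4L, 2310))
  parts <- splitDataset(ws, splitSpec(seed = 1))
  expect_equal(nWindows(parts$test), 693)
  expect_equal(nWindows(parts$verification), 324)
  expect_equal(nWindows(parts$train), 1293)

  # ceiling hold-out: 20% of a 7,352-entry pool is 1,471
  expect_equal(ceiling(0.2 * 7352), 1471)
  ws2 <- WindowSet(array(0, dim = c(2, 6, 7352)),
                   labels = rep(1L, 7352))
  spec2 <- splitSpec(trainFraction = 0.999999999, testFraction = 1e-9,
                     verificationFraction = 0.2, seed = 1)
  parts2 <- splitDataset(ws2, spec2)
  expect_equal(nWindows(parts2$verification), 1471)

  # 10 items unstratified at 70/30 -> 7 and 3
  ws10 <- WindowSet(array(0, dim = c(2, 6, 10)), labels = rep(3L, 10))
  p10 <- splitDataset(ws10, splitSpec(stratified = FALSE, seed = 2))
  expect_equal(nWindows(p10$test), 3)
  expect_equal(nWindows(p10$train) + nWindows(p10$verification), 7)
})

test_that("splits are disjoint, exhaustive and seed-deterministic", {
  ws <- makeWindowSet(n = 60, L = 6, labels = rep(1:6, each = 10), seed = 8)
  key <- function(part) sort(colSums(assaySignal(part)) +
                               activityLabels(part) * 1000)
  a <- splitDataset(ws, splitSpec(seed = 5))
  b <- splitDataset(ws, splitSpec(seed = 5))
  expect_identical(lapply(a, key), lapply(b, key))
  total <- sum(vapply(a, nWindows, 1L))
  expect_equal(total, 60)
  # disjoint + exhaustive via per-class counts
  cc <- Reduce(`+`, lapply(a, classCounts))
  expect_equal(unname(cc), rep(10L, 6))
  expect_error(splitDataset(ws[, 1:2], splitSpec()), ">= 3")
})
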