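#' @include windowset.R
NULL

#' Sensor specification for raw-count conversion
#'
#' The supported six-axis sensor reports signed integer counts; physical
#' units are counts divided by sensitivity. Defaults are the +/-16 g,
#' +/-2000 deg/s configuration: 2048 LSB/g and 16.4 LSB/(deg/s).
#'
#' @param accelSensitivity counts per g (default 2048).
#' @param gyroSensitivity counts per deg/s (default 16.4).
#' @param accelRange full accelerometer range in g (default 16).
#' @param gyroRange full gyroscope range in deg/s (default 2000).
#' @return A list of class `"SensorSpec"`.
#' @export
sensorSpec <- function(accelSensitivity = 2048, gyroSensitivity = 16.4,
                       accelRange = 16, gyroRange = 2000) {
  stopifnot(accelSensitivity > 0, gyroSensitivity > 0)
  structure(list(accelSensitivity = accelSensitivity,
                 gyroSensitivity = gyroSensitivity,
                 accelRange = accelRange, gyroRange = gyroRange),
            class = "SensorSpec")
}

#' Convert raw sensor counts to physical units
#'
#' Columns 1-3 are accelerometer counts (divided by the accelerometer
#' sensitivity, giving g), columns 4-6 gyroscope counts (divided by the
#' gyroscope sensitivity, giving deg/s).
#'
#' @param counts numeric matrix with 6 columns (AX..GZ order).
#' @param spec a [sensorSpec()].
#' @return Numeric matrix in physical units, same shape.
#' @export
#' @examples
#' convertRaw(matrix(c(2048, 0, 0, 16.4, 0, 0), 1), sensorSpec())
convertRaw <- function(counts, spec = sensorSpec()) {
  counts <- as.matrix(counts)
  if (ncol(counts) != 6L) stop("expected 6 columns (AX..GZ)")
  out <- counts
  out[, 1:3] <- counts[, 1:3] / spec$accelSensitivity
  out[, 4:6] <- counts[, 4:6] / spec$gyroSensitivity
  out
}

#' Calibrate numeric precision to 7 significant decimal digits
#'
#' Accelerometer and gyroscope channels have different native precisions;
#' before serialization every value is rounded to 7 significant decimal
#' digits (round-half-even, the IEEE default) so that all channels carry
#' the same precision. Idempotent.
#'
#' @param x numeric vector, matrix or array; all values must be finite.
#' @return Same shape, rounded.
#' @export
#' @examples
#' calibratePrecision(0.123456789)  # 0.1234568
calibratePrecision <- function(x) {
  bad <- which(!is.finite(x))
  if (length(bad))
    stop(sprintf("non-finite value at index %d", bad[1]))
  signif(x, 7L)
}

#' Fit per-channel min-max normalization parameters
#'
#' Extrema are computed per channel over all training windows only; test
#' data must never influence them. A channel whose max equals its min is
#' flagged degenerate and later normalizes to 0.
#'
#' @param train a nonempty training \linkS4class{WindowSet}.
#' @return A \linkS4class{NormalizationParams}.
#' @export
fitMinMax <- function(train) {
  stopifnot(is(train, "WindowSet"))
  if (nWindows(train) == 0L) stop("training set is empty")
  arr <- windowArray(train)
  mins <- unname(apply(arr, 2L, min))
  maxs <- unname(apply(arr, 2L, max))
  new("NormalizationParams", mins = mins, maxs = maxs,
      degenerate = maxs == mins)
}

#' Min-max normalize windows to [-1, 1]
#'
#' Applies `x' = 2 (x - min) / (max - min) - 1` per channel with the
#' training-fitted parameters, then clips to [-1, 1] (out-of-range test
#' values saturate). Degenerate channels (max == min on the training data)
#' map to 0.
#'
#' @param ws a \linkS4class{WindowSet}.
#' @param p a \linkS4class{NormalizationParams} from [fitMinMax()].
#' @return A normalized \linkS4class{WindowSet}.
#' @export
normalizeWindows <- function(ws, p) {
  stopifnot(is(ws, "WindowSet"), is(p, "NormalizationParams"))
  arr <- windowArray(ws)
  if (dim(arr)[2] != length(p@mins)) stop("channel-count mismatch")
  for (c in 1:6) {
    if (p@degenerate[c]) {
      arr[, c, ] <- 0
    } else {
      v <- 2 * (arr[, c, ] - p@mins[c]) / (p@maxs[c] - p@mins[c]) - 1
      arr[, c, ] <- pmin(1, pmax(-1, v))
    }
  }
  WindowSet(arr, labels = activityLabels(ws), subjects = subjectIds(ws),
            samplingRate = samplingRate(ws), source = metadata(ws)$source)
}

#' Segment a continuous recording into fixed-length windows
#'
#' Cuts a \linkS4class{SixAxisRecording} into windows of
#' `round(windowSeconds * samplingRate)` samples with stride
#' `round(L * (1 - overlap))`. A window's label is the single annotation
#' covering its whole span; windows straddling a label change (or covering
#' unannotated samples) are dropped so labels stay unambiguous.
#'
#' @param rec a \linkS4class{SixAxisRecording}.
#' @param windowSeconds window duration in seconds (2.56 s at 50 Hz gives
#'   the 128-sample public-dataset windows; 3 s gives the 150-sample
#'   device windows).
#' @param overlap fractional overlap in [0, 1); 0.5 halves the stride.
#' @return A \linkS4class{WindowSet} (empty, with a warning, if the
#'   recording is shorter than one window).
#' @export
segmentRecording <- function(rec, windowSeconds, overlap = 0) {
  stopifnot(is(rec, "SixAxisRecording"), overlap >= 0, overlap < 1)
  L <- as.integer(round(windowSeconds * rec@samplingRate))
  if (L < 1L) stop("window length must be at least one sample")
  n <- nrow(rec@signal)
  emptySet <- function() {
    warning("recording shorter than one window; returning empty WindowSet")
    WindowSet(array(numeric(0), dim = c(L, 6L, 0L)), labels = integer(0),
              subjects = character(0), samplingRate = rec@samplingRate,
              source = rec@source)
  }
  if (n < L) return(emptySet())
  stride <- max(1L, as.integer(round(L * (1 - overlap))))
  starts <- seq.int(1L, n - L + 1L, by = stride)
  keep <- logical(length(starts))
  labs <- integer(length(starts))
  for (i in seq_along(starts)) {
    span <- rec@labels[starts[i]:(starts[i] + L - 1L)]
    u <- unique(span)
    if (length(u) == 1L && !is.na(u)) {
      keep[i] <- TRUE
      labs[i] <- u
    }
  }
  starts <- starts[keep]
  labs <- labs[keep]
  arr <- array(0, dim = c(L, 6L, length(starts)))
  for (i in seq_along(starts))
    arr[, , i] <- rec@signal[starts[i]:(starts[i] + L - 1L), ]
  WindowSet(arr, labels = labs, subjects = rec@participant,
            samplingRate = rec@samplingRate, source = rec@source)
}

#' Flatten / unflatten one window
#'
#' `flattenWindow` concatenates the six channels of an `L x 6` window into
#' a `6L` vector in channel blocks (all L AX samples, then AY, AZ, GX, GY,
#' GZ) — for L = 150 this is the 1 x 900 device layout.
#' `unflattenWindow` is its exact inverse.
#'
#' @param w `L x 6` numeric matrix.
#' @param v length-`6L` numeric vector.
#' @param windowLen L.
#' @return A vector (`flattenWindow`) or an `L x 6` matrix
#'   (`unflattenWindow`).
#' @export
flattenWindow <- function(w) {
  w <- as.matrix(w)
  if (ncol(w) != 6L) stop("window must have 6 channels")
  as.vector(w)                              # column-major = channel-blocked
}

#' @rdname flattenWindow
#' @export
unflattenWindow <- function(v, windowLen) {
  if (length(v) != 6L * windowLen)
    stop("vector length must be 6 x windowLen")
  m <- matrix(v, nrow = windowLen, ncol = 6L)
  colnames(m) <- CHANNELS
  m
}

#' Train/verification/test split specification
#'
#' The recording protocol: 70% of the windows form the training pool and
#' 30% the test set (per class when stratified, with the test share
#' rounded to nearest); the verification set is then the ceiling of 20% of
#' the per-class training pool. With 2,310 windows per class this yields
#' 1,293 training, 693 test and 324 verification windows per class.
#'
#' @param trainFraction training-pool share (default 0.7).
#' @param testFraction test share (default 0.3); must sum to 1 with
#'   `trainFraction`.
#' @param verificationFraction share of the training pool held out for
#'   verification (default 0.2, taken with ceiling).
#' @param stratified split per class (default TRUE).
#' @param seed RNG seed making membership deterministic.
#' @return A list of class `"SplitSpec"`.
#' @export
splitSpec <- function(trainFraction = 0.7, testFraction = 0.3,
                      verificationFraction = 0.2, stratified = TRUE,
                      seed = 1L) {
  if (abs(trainFraction + testFraction - 1) > 1e-9)
    stop("train and test fractions must sum to 1")
  if (trainFraction <= 0 || trainFraction >= 1 ||
      verificationFraction <= 0 || verificationFraction >= 1)
    stop("fractions must lie in (0, 1)")
  structure(list(trainFraction = trainFraction, testFraction = testFraction,
                 verificationFraction = verificationFraction,
                 stratified = stratified, seed = as.integer(seed)),
            class = "SplitSpec")
}

# Split a vector of indices into (train, verification, test) by the
# protocol: round(n * testFraction) test, then ceiling(pool * verFraction)
# verification out of the remaining pool.
splitIndices <- function(idx, spec) {
  n <- length(idx)
  nTest <- as.integer(round(n * spec$testFraction))
  testIdx <- idx[sample.int(n, nTest)]      # safe for length-1 pools
  pool <- setdiff(idx, testIdx)
  nVer <- as.integer(ceiling(length(pool) * spec$verificationFraction))
  verIdx <- pool[sample.int(length(pool), nVer)]
  list(train = setdiff(pool, verIdx), verification = verIdx, test = testIdx)
}

#' Split a WindowSet into train / verification / test sets
#'
#' Deterministic under the spec's seed; partitions are disjoint and
#' exhaustive. When stratified (the default) the protocol is applied per
#' class, reproducing the per-class bookkeeping of the recording protocol;
#' stratification requires at least 3 windows per present class.
#'
#' @param ws a nonempty \linkS4class{WindowSet}.
#' @param spec a [splitSpec()].
#' @return A list with \linkS4class{WindowSet} elements `train`,
#'   `verification`, `test`.
#' @export
splitDataset <- function(ws, spec = splitSpec()) {
  stopifnot(is(ws, "WindowSet"))
  if (nWindows(ws) == 0L) stop("cannot split an empty WindowSet")
  labs <- activityLabels(ws)
  parts <- withr_seed(spec$seed, {
    if (spec$stratified) {
      acc <- list(train = integer(0), verification = integer(0),
                  test = integer(0))
      for (cl in sort(unique(labs))) {
        idx <- which(labs == cl)
        if (length(idx) < 3L)
          stop(sprintf("class %d has %d windows; stratification needs >= 3",
                       cl, length(idx)))
        p <- splitIndices(idx, spec)
        acc <- Map(c, acc, p)
      }
      acc
    } else splitIndices(seq_along(labs), spec)
  })
  lapply(parts, function(i) ws[, sort(i)])
}

# Evaluate expr with a local RNG seed, restoring the caller's RNG state.
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
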