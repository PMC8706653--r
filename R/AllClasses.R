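#' @include harfusion-package.R
NULL

CHANNELS <- c("AX", "AY", "AZ", "GX", "GY", "GZ")

#' WindowSet: a collection of fixed-length six-axis windows
#'
#' Extends \linkS4class{SummarizedExperiment}. The single assay `"signal"`
#' holds one column per window; each column is the channel-blocked
#' flattened window (all L AX samples, then AY, AZ, GX, GY, GZ — length
#' 6L). `colData` carries the integer activity `label` (1..6) and the
#' `subject` id. `metadata` records `samplingRate`, `windowLen`,
#' `channelNames` and `source` (`"uci"`, `"device"` or `"synthetic"`).
#'
#' Standard `SummarizedExperiment` subsetting applies: `ws[, idx]` selects
#' windows.
#'
#' @aliases WindowSet
#' @exportClass WindowSet
setClass("WindowSet", contains = "SummarizedExperiment")

setValidity("WindowSet", function(object) {
  md <- metadata(object)
  need <- c("samplingRate", "windowLen", "channelNames", "source")
  if (!all(need %in% names(md)))
    return(paste("metadata must contain", paste(need, collapse = ", ")))
  if (length(md$channelNames) != 6L || !identical(md$channelNames, CHANNELS))
    return("channelNames must be AX, AY, AZ, GX, GY, GZ in that order")
  if (!is.numeric(md$samplingRate) || md$samplingRate <= 0)
    return("samplingRate must be positive")
  L <- md$windowLen
  if (nrow(object) != 6L * L)
    return(sprintf("assay has %d rows; expected 6 x windowLen = %d",
                   nrow(object), 6L * L))
  cd <- colData(object)
  if (!all(c("label", "subject") %in% colnames(cd)))
    return("colData must contain 'label' and 'subject'")
  lab <- cd$label
  if (ncol(object) > 0L) {
    if (anyNA(lab) || any(lab < 1L | lab > 6L))
      return("labels must be integers in 1..6 with no missing values")
    if (anyNA(assay(object, "signal")))
      return("windows must not contain missing values")
  }
  TRUE
})

#' SixAxisRecording: a continuous six-channel inertial stream
#'
#' A raw (unsegmented) recording: an N x 6 signal matrix in physical units
#' (accelerometer in g, gyroscope in deg/s, columns AX..GZ), a sampling
#' rate, a participant id, a source tag, and a per-sample integer activity
#' annotation (NA where unannotated).
#'
#' @slot signal numeric matrix, N x 6, columns AX, AY, AZ, GX, GY, GZ.
#' @slot samplingRate samples per second (50 for the supported devices).
#' @slot participant opaque participant id.
#' @slot source one of `"uci"`, `"device"`, `"synthetic"`.
#' @slot labels integer vector of length N; activity class per sample.
#' @exportClass SixAxisRecording
setClass("SixAxisRecording",
  representation(signal = "matrix", samplingRate = "numeric",
                 participant = "character", source = "character",
                 labels = "integer"))

setValidity("SixAxisRecording", function(object) {
  if (ncol(object@signal) != 6L) return("signal must have 6 columns")
  if (length(object@samplingRate) != 1L || object@samplingRate <= 0)
    return("samplingRate must be a positive scalar")
  if (length(object@labels) != nrow(object@signal))
    return("labels must have one entry per sample")
  ok <- object@labels[!is.na(object@labels)]
  if (length(ok) && any(ok < 1L | ok > 6L))
    return("annotated labels must lie in 1..6")
  TRUE
})

#' ActivityProfile: simulator parameters for one activity class
#'
#' Parameterizes the synthetic generator for a single activity: gait
#' frequency (0 for postures, which instead sway at a slow fixed
#' frequency), per-axis acceleration amplitudes, harmonic weights of the
#' gait waveform, gravity orientation in the device frame (x right, y
#' down, z front), gyroscope amplitude, and noise/drift scales.
#'
#' @slot label integer class in 1..6.
#' @slot name activity name.
#' @slot gaitFreq fundamental gait frequency in Hz; 0 for static postures.
#' @slot accelAmp per-axis acceleration amplitude in g (length 3).
#' @slot harmonics relative weights of gait harmonics (first = fundamental).
#' @slot gravity unit 3-vector; gravity direction in the device frame.
#' @slot gyroAmp peak angular rate in deg/s of the periodic gyro component.
#' @slot noiseSd accelerometer white-noise standard deviation in g.
#' @slot gyroNoiseSd gyroscope white-noise standard deviation in deg/s.
#' @slot driftSd standard deviation in g of the slow baseline wander.
#' @exportClass ActivityProfile
setClass("ActivityProfile",
  representation(label = "integer", name = "character", gaitFreq = "numeric",
                 accelAmp = "numeric", harmonics = "numeric",
                 gravity = "numeric", gyroAmp = "numeric", noiseSd = "numeric",
                 gyroNoiseSd = "numeric", driftSd = "numeric"))

setValidity("ActivityProfile", function(object) {
  if (object@noiseSd < 0 || object@gyroNoiseSd < 0 || object@driftSd < 0)
    return("noise scales must be nonnegative")
  if (length(object@gravity) != 3L ||
      abs(sqrt(sum(object@gravity^2)) - 1) > 1e-8)
    return("gravity must be a unit 3-vector")
  if (length(object@accelAmp) != 3L)
    return("accelAmp must have one entry per axis")
  TRUE
})

#' NormalizationParams: per-channel min-max fitted on training windows
#'
#' @slot mins,maxs numeric length-6 per-channel extrema.
#' @slot degenerate logical length-6; TRUE where max == min (such channels
#'   normalize to 0).
#' @exportClass NormalizationParams
setClass("NormalizationParams",
  representation(mins = "numeric", maxs = "numeric", degenerate = "logical"))

setValidity("NormalizationParams", function(object) {
  if (length(object@mins) != 6L || length(object@maxs) != 6L)
    return("need 6 per-channel (min, max) pairs")
  if (any(object@maxs < object@mins)) return("max must be >= min per channel")
  TRUE
})

#' ModelConfig: hyperparameters of the three-zone fusion network
#'
#' Complete architecture record: three parallel convolutional branches
#' ("zones") distinguished only by kernel size (defaults 1, 3, 5), each
#' with three length-preserving (same-padded) convolution stages of 32, 64
#' and 128 filters at stride 1, batch normalization before ReLU, and
#' dropout; branch outputs are flattened and concatenated, then passed
#' through fully connected layers of 256 and 512 units to a softmax over
#' the classes.
#'
#' @slot windowLen window length L in samples (128 or 150 typically).
#' @slot nChannels input channels; always 6 here.
#' @slot kernelSizes odd kernel size per zone (default 1, 3, 5).
#' @slot filters filters of the three convolution stages (32, 64, 128).
#' @slot fcWidths widths of the two fully connected layers (256, 512).
#' @slot dropout dropout rate in [0, 1); default 0.3.
#' @slot nClasses number of output classes; 6 activities by default.
#' @slot batchNorm whether batch normalization is used (on by default).
#' @slot dropoutConv whether dropout is also applied inside the zones
#'   (after each convolution's activation), not only between the fully
#'   connected layers. Default TRUE.
#' @exportClass ModelConfig
setClass("ModelConfig",
  representation(windowLen = "integer", nChannels = "integer",
                 kernelSizes = "integer", filters = "integer",
                 fcWidths = "integer", dropout = "numeric",
                 nClasses = "integer", batchNorm = "logical",
                 dropoutConv = "logical"))

setValidity("ModelConfig", function(object) {
  if (object@nChannels != 6L) return("nChannels must be 6")
  if (any(object@kernelSizes %% 2L == 0L))
    return("kernel sizes must be odd (same padding)")
  if (length(object@filters) != 3L || any(diff(object@filters) <= 0))
    return("filters must be a strictly increasing triple")
  if (object@dropout < 0 || object@dropout >= 1)
    return("dropout must lie in [0, 1)")
  if (object@nClasses < 2L) return("need at least 2 classes")
  if (object@windowLen < max(object@kernelSizes))
    return("window length must be at least the largest kernel")
  TRUE
})

#' TrainConfig: the training protocol
#'
#' Adam at learning rate 0.001 with reduce-on-plateau decay (factor 0.5,
#' patience 10) floored at 1e-7, categorical cross-entropy, up to 1000
#' epochs with early stopping (patience 50) on verification loss, and
#' best-verification-loss model retention.
#'
#' @slot learningRate initial Adam learning rate (0.001).
#' @slot lrFloor minimum learning rate (1e-7).
#' @slot maxEpochs epoch cap (1000).
#' @slot batchSize minibatch size (64).
#' @slot earlyStopPatience epochs without verification-loss improvement
#'   before training stops (50).
#' @slot lrDecayFactor multiplicative decay on plateau (0.5).
#' @slot lrDecayPatience plateau length in epochs that triggers decay (10).
#' @slot seed RNG seed controlling shuffling, dropout and initialization.
#' @exportClass TrainConfig
setClass("TrainConfig",
  representation(learningRate = "numeric", lrFloor = "numeric",
                 maxEpochs = "integer", batchSize = "integer",
                 earlyStopPatience = "integer", lrDecayFactor = "numeric",
                 lrDecayPatience = "integer", seed = "integer"))

setValidity("TrainConfig", function(object) {
  if (object@lrFloor > object@learningRate)
    return("lrFloor must not exceed learningRate")
  if (object@earlyStopPatience < 1L || object@lrDecayPatience < 1L)
    return("patience values must be >= 1")
  if (object@maxEpochs < 1L || object@batchSize < 1L)
    return("maxEpochs and batchSize must be >= 1")
  TRUE
})

#' FusionModel: a built (possibly trained) three-zone fusion network
#'
#' Holds the architecture config, all trainable parameters (flat named
#' list of arrays), batch-normalization running statistics, the
#' initialization seed and the number of completed training epochs.
#'
#' @slot config a \linkS4class{ModelConfig}.
#' @slot params named list of parameter arrays.
#' @slot state named list of batch-norm running means/variances.
#' @slot seed initialization seed.
#' @slot epochsTrained completed training epochs (0 for a fresh model).
#' @exportClass FusionModel
setClass("FusionModel",
  representation(config = "ModelConfig", params = "list", state = "list",
                 seed = "integer", epochsTrained = "integer"))

#' ActivityConfusion: a multiclass confusion matrix
#'
#' Counts of (true class i, predicted class j) pairs; rows are true
#' classes. Per-class one-vs-rest TP/FP/FN/TN are derived by
#' [binaryCounts()].
#'
#' @slot counts nonnegative integer matrix, rows = true, cols = predicted.
#' @exportClass ActivityConfusion
setClass("ActivityConfusion", representation(counts = "matrix"))

setValidity("ActivityConfusion", function(object) {
  cm <- object@counts
  if (nrow(cm) != ncol(cm)) return("confusion matrix must be square")
  if (any(cm < 0)) return("counts must be nonnegative")
  TRUE
})
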