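#' @include AllGenerics.R
NULL

#' Construct a WindowSet
#'
#' Builds the canonical in-memory window container from either an
#' `L x 6 x N` array of windows or a `6L x N` matrix of channel-blocked
#' flattened windows (all L AX samples, then AY, ..., then GZ per column).
#'
#' @param samples `L x 6 x N` numeric array or `6L x N` numeric matrix.
#' @param labels integer activity labels in 1..6, one per window.
#' @param subjects participant ids, one per window (recycled if scalar).
#' @param samplingRate samples per second; default 50.
#' @param source one of `"uci"`, `"device"`, `"synthetic"`.
#' @param windowLen window length L; required when `samples` is a flat
#'   matrix, inferred from the array otherwise.
#' @return A \linkS4class{WindowSet}.
#' @export
#' @examples
#' arr <- array(rnorm(10 * 6 * 3), dim = c(10, 6, 3))
#' ws <- WindowSet(arr, labels = c(1, 4, 6), subjects = "s1")
#' classCounts(ws)
WindowSet <- function(samples, labels, subjects = "unknown",
                      samplingRate = 50, source = "synthetic",
                      windowLen = NULL) {
  if (is.array(samples) && length(dim(samples)) == 3L) {
    d <- dim(samples)
    if (d[2] != 6L) stop("window array must be L x 6 x N")
    windowLen <- d[1]
    flat <- samples
    dim(flat) <- c(d[1] * 6L, d[3])
  } else if (is.matrix(samples)) {
    if (is.null(windowLen)) stop("windowLen is required for flat input")
    if (nrow(samples) != 6L * windowLen)
      stop("flat matrix must have 6 x windowLen rows")
    flat <- samples
  } else stop("samples must be an L x 6 x N array or a 6L x N matrix")
  n <- ncol(flat)
  if (length(labels) != n) stop("need one label per window")
  labels <- as.integer(labels)
  subjects <- as.character(rep_len(subjects, n))
  se <- SummarizedExperiment(
    assays = list(signal = flat),
    colData = DataFrame(label = labels, subject = subjects)
  )
  metadata(se) <- list(samplingRate = samplingRate,
                       windowLen = as.integer(windowLen),
                       channelNames = CHANNELS, source = source)
  new("WindowSet", se)
}

#' Accessors for WindowSet objects
#'
#' `windowLength` gives L in samples; `samplingRate` the rate in Hz;
#' `activityLabels` the integer labels; `subjectIds` the participant ids;
#' `classCounts` a named count per class 1..6; `windowArray` the windows
#' as an `L x 6 x N` array; `nWindows` the number of windows.
#'
#' @param x a \linkS4class{WindowSet}.
#' @return See each description.
#' @name windowSet-accessors
NULL

#' @rdname windowSet-accessors
#' @export
setMethod("windowLength", "WindowSet", function(x) metadata(x)$windowLen)

#' @rdname windowSet-accessors
#' @export
setMethod("samplingRate", "WindowSet", function(x) metadata(x)$samplingRate)

#' @rdname windowSet-accessors
#' @export
setMethod("channelNames", "WindowSet", function(x) metadata(x)$channelNames)

#' @rdname windowSet-accessors
#' @export
setMethod("activityLabels", "WindowSet", function(x) colData(x)$label)

#' @rdname windowSet-accessors
#' @export
setMethod("subjectIds", "WindowSet", function(x) colData(x)$subject)

#' @rdname windowSet-accessors
#' @export
setMethod("classCounts", "WindowSet", function(x) {
  tab <- tabulate(activityLabels(x), nbins = 6L)
  setNames(tab, activityNames())
})

#' @rdname windowSet-accessors
#' @export
setMethod("windowArray", "WindowSet", function(x) {
  arr <- assay(x, "signal")
  dim(arr) <- c(windowLength(x), 6L, ncol(x))
  dimnames(arr) <- list(NULL, CHANNELS, NULL)
  arr
})

#' @rdname windowSet-accessors
#' @export
setMethod("nWindows", "WindowSet", function(x) ncol(x))

setMethod("show", "WindowSet", function(object) {
  cat(sprintf("WindowSet: %d windows of %d samples x 6 channels (%g Hz, %s)\n",
              ncol(object), windowLength(object), samplingRate(object),
              metadata(object)$source))
  cc <- classCounts(object)
  cat("class counts:", paste(sprintf("%s=%d", names(cc), cc), collapse = " "),
      "\n")
})

setMethod("show", "SixAxisRecording", function(object) {
  n <- nrow(object@signal)
  cat(sprintf("SixAxisRecording: %d samples (%.1f s at %g Hz), participant %s, %s\n",
              n, n / object@samplingRate, object@samplingRate,
              object@participant, object@source))
})

setMethod("show", "ActivityProfile", function(object) {
  cat(sprintf("ActivityProfile '%s' (class %d): gait %g Hz, noise %g g\n",
              object@name, object@label, object@gaitFreq, object@noiseSd))
})

#' Construct a SixAxisRecording
#'
#' @param signal N x 6 numeric matrix (AX, AY, AZ in g; GX, GY, GZ in
#'   deg/s).
#' @param samplingRate samples per second.
#' @param participant participant id.
#' @param source provenance tag.
#' @param labels per-sample integer activity annotation (NA where
#'   unannotated); recycled if scalar.
#' @return A \linkS4class{SixAxisRecording}.
#' @export
SixAxisRecording <- function(signal, samplingRate = 50,
                             participant = "unknown", source = "synthetic",
                             labels = NA_integer_) {
  signal <- as.matrix(signal)
  colnames(signal) <- CHANNELS
  new("SixAxisRecording", signal = signal, samplingRate = samplingRate,
      participant = as.character(participant), source = source,
      labels = as.integer(rep_len(labels, nrow(signal))))
}

# rbind-like combination of WindowSets (same L); used by the simulator.
combineWindowSets <- function(sets) {
  stopifnot(length(sets) > 0L)
  L <- windowLength(sets[[1]])
  if (!all(vapply(sets, windowLength, 1L) == L))
    stop("all WindowSets must share the same window length")
  flat <- do.call(cbind, lapply(sets, assay, "signal"))
  WindowSet(flat,
            labels = unlist(lapply(sets, activityLabels), use.names = FALSE),
            subjects = unlist(lapply(sets, subjectIds), use.names = FALSE),
            samplingRate = samplingRate(sets[[1]]),
            source = metadata(sets[[1]])$source, windowLen = L)
}
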