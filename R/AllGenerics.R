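#' @include AllClasses.R
NULL

#' @rdname windowSet-accessors
#' @export
setGeneric("windowLength", function(x) standardGeneric("windowLength"))

#' @rdname windowSet-accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname windowSet-accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname windowSet-accessors
#' @export
setGeneric("activityLabels", function(x) standardGeneric("activityLabels"))

#' @rdname windowSet-accessors
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' @rdname windowSet-accessors
#' @export
setGeneric("classCounts", function(x) standardGeneric("classCounts"))

#' @rdname windowSet-accessors
#' @export
setGeneric("windowArray", function(x) standardGeneric("windowArray"))

#' @rdname windowSet-accessors
#' @export
setGeneric("nWindows", function(x) standardGeneric("nWindows"))

#' @rdname activityConfusion
#' @export
setGeneric("confusionCounts", function(x) standardGeneric("confusionCounts"))

#' @rdname activityConfusion
#' @export
setGeneric("binaryCounts", function(x) standardGeneric("binaryCounts"))
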