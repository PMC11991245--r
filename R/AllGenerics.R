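#' Accessors for EcgRecord
#'
#' @param object an [EcgRecord-class].
#' @return `samplingRate`: the sampling rate in Hz; `ecgSamples`: the
#'   amplitude series in mV; `recordId`: the record identifier; `startClock`:
#'   seconds since midnight of sample 0; `leadName`: the lead label.
#' @name EcgRecord-accessors
NULL

#' @rdname EcgRecord-accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname EcgRecord-accessors
#' @export
setGeneric("ecgSamples", function(object) standardGeneric("ecgSamples"))
#' @rdname EcgRecord-accessors
#' @export
setGeneric("recordId", function(object) standardGeneric("recordId"))
#' @rdname EcgRecord-accessors
#' @export
setGeneric("startClock", function(object) standardGeneric("startClock"))
#' @rdname EcgRecord-accessors
#' @export
setGeneric("leadName", function(object) standardGeneric("leadName"))

#' @rdname EcgRecord-accessors
setMethod("samplingRate", "EcgRecord", function(object) object@fs)
#' @rdname EcgRecord-accessors
setMethod("ecgSamples", "EcgRecord", function(object) object@samples)
#' @rdname EcgRecord-accessors
setMethod("recordId", "EcgRecord", function(object) object@recordId)
#' @rdname EcgRecord-accessors
setMethod("startClock", "EcgRecord", function(object) object@startClock)
#' @rdname EcgRecord-accessors
setMethod("leadName", "EcgRecord", function(object) object@lead)

#' Accessors for SelectionResult
#'
#' @param object a [SelectionResult-class].
#' @return `selectedTriad`: the 3 chosen feature names; `featurePValues`: the
#'   named rank-sum p-value vector; `rhoMatrix`: the Spearman matrix.
#' @name SelectionResult-accessors
NULL

#' @rdname SelectionResult-accessors
#' @export
setGeneric("selectedTriad", function(object) standardGeneric("selectedTriad"))
#' @rdname SelectionResult-accessors
#' @export
setGeneric("featurePValues", function(object) standardGeneric("featurePValues"))
#' @rdname SelectionResult-accessors
#' @export
setGeneric("rhoMatrix", function(object) standardGeneric("rhoMatrix"))

#' @rdname SelectionResult-accessors
setMethod("selectedTriad", "SelectionResult", function(object) object@selected)
#' @rdname SelectionResult-accessors
setMethod("featurePValues", "SelectionResult", function(object) object@pValues)
#' @rdname SelectionResult-accessors
setMethod("rhoMatrix", "SelectionResult", function(object) object@rhoMatrix)
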