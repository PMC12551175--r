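#' @rdname MediationData-class
#' @param object a `MediationData`
#' @export
setGeneric("exposures", function(object) standardGeneric("exposures"))

#' @rdname MediationData-class
#' @export
setGeneric("mediators", function(object) standardGeneric("mediators"))

#' @rdname MediationData-class
#' @export
setGeneric("outcome", function(object) standardGeneric("outcome"))

#' @rdname MediationData-class
#' @export
setGeneric("covariates", function(object) standardGeneric("covariates"))

#' @rdname MediationData-class
#' @export
setGeneric("sampleIds", function(object) standardGeneric("sampleIds"))

#' @rdname DecorrelatedDesign-class
#' @param object a `DecorrelatedDesign`
#' @export
setGeneric("trimmed", function(object) standardGeneric("trimmed"))

#' @rdname DecorrelatedDesign-class
#' @export
setGeneric("singularValues", function(object) standardGeneric("singularValues"))

#' @rdname DecorrelatedDesign-class
#' @export
setGeneric("numFactors", function(object) standardGeneric("numFactors"))

#' Apply the decorrelating projector to new data
#'
#' Applies \eqn{F_{dc} = I - U_s U_s^T} (with \eqn{U_s} the top-s left
#' singular vectors of the decorrelated design's source matrix) to a vector
#' or matrix sharing the design's sample axis. This is how the response and
#' further columns are transformed consistently with the trimmed design.
#'
#' @param object a [DecorrelatedDesign-class]
#' @param a numeric vector of length n or matrix with n rows
#' @return the projected vector or matrix, same shape as `a`
#' @export
setGeneric("applyDecorrelation",
           function(object, a) standardGeneric("applyDecorrelation"))

#' @rdname DecorrelatedDesign-class
#' @export
setGeneric("factorScores", function(object) standardGeneric("factorScores"))
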