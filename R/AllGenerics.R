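#' Accessor generics
#'
#' Small accessor generics for the result classes in this package.
#'
#' @param object a result object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("growthRate", function(object) standardGeneric("growthRate"))

#' @rdname accessors
#' @export
setGeneric("wavelength", function(object) standardGeneric("wavelength"))

#' @rdname accessors
#' @export
setGeneric("peakFrequency", function(object) standardGeneric("peakFrequency"))

#' @rdname accessors
#' @export
setGeneric("gStatistic", function(object) standardGeneric("gStatistic"))

#' @rdname accessors
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))

#' @rdname accessors
#' @export
setGeneric("alphaSlope", function(object) standardGeneric("alphaSlope"))

#' @rdname accessors
#' @export
setGeneric("epistasisClass", function(object) standardGeneric("epistasisClass"))

#' @rdname accessors
#' @export
setGeneric("moduleLabels", function(object) standardGeneric("moduleLabels"))

#' @rdname accessors
#' @export
setGeneric("moduleSizes", function(object) standardGeneric("moduleSizes"))

#' @rdname accessors
#' @export
setGeneric("eigengenes", function(object) standardGeneric("eigengenes"))

#' @rdname accessors
#' @export
setGeneric("moduleClasses", function(object) standardGeneric("moduleClasses"))

#' @rdname accessors
#' @export
setGeneric("traitCorrelation", function(object) standardGeneric("traitCorrelation"))

#' @rdname accessors
#' @export
setGeneric("conditionLabels", function(object) standardGeneric("conditionLabels"))

#' @rdname accessors
#' @export
setGeneric("isNormalized", function(object) standardGeneric("isNormalized"))
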