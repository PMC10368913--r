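#' @rdname gridSpec
#' @export
setGeneric("gridSpec", function(x) standardGeneric("gridSpec"))

#' @rdname rasterValues
#' @export
setGeneric("rasterValues", function(x) standardGeneric("rasterValues"))

#' @rdname classLegend
#' @export
setGeneric("classLegend", function(x) standardGeneric("classLegend"))

#' @rdname areaByClass
#' @export
setGeneric("areaByClass", function(x, ...) standardGeneric("areaByClass"))

#' @rdname transitionCounts
#' @export
setGeneric("transitionCounts", function(x) standardGeneric("transitionCounts"))

#' @rdname transitionProbabilities
#' @export
setGeneric("transitionProbabilities",
           function(x) standardGeneric("transitionProbabilities"))
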