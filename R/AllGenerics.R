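#' @rdname classStats
#' @export
setGeneric("classStats", function(x, ...) standardGeneric("classStats"))

#' @rdname classStats
#' @export
setGeneric("overallStats", function(x, ...) standardGeneric("overallStats"))

#' @rdname indexX
#' @export
setGeneric("indexX", function(x, ...) standardGeneric("indexX"))

#' @rdname indexY
#' @export
setGeneric("indexY", function(x, ...) standardGeneric("indexY"))

#' @rdname sexCalls
#' @export
setGeneric("sexCalls", function(x, ...) standardGeneric("sexCalls"))

#' @rdname sexCalls
#' @export
setGeneric("cohortSummary", function(x, ...) standardGeneric("cohortSummary"))

#' @rdname contigClass
#' @export
setGeneric("contigClass", function(x, contigs) standardGeneric("contigClass"))
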