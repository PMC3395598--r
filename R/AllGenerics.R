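#' Accessors for scfluor result objects
#'
#' Small accessor generics for the S4 result classes; prefer these over
#' direct slot access.
#'
#' @param x an scfluor object.
#' @param ... passed to methods.
#' @return the corresponding component (numeric scalar or vector unless noted).
#' @name scfluor-accessors
NULL

#' @rdname scfluor-accessors
#' @export
setGeneric("agv", function(x, ...) standardGeneric("agv"))

#' @rdname scfluor-accessors
#' @export
setGeneric("cellData", function(x, ...) standardGeneric("cellData"))

#' @rdname scfluor-accessors
#' @export
setGeneric("channelNames", function(x, ...) standardGeneric("channelNames"))

#' @rdname scfluor-accessors
#' @export
setGeneric("fractionOn", function(x, ...) standardGeneric("fractionOn"))

#' @rdname scfluor-accessors
#' @export
setGeneric("breakpointAGV", function(x, ...) standardGeneric("breakpointAGV"))

#' @rdname scfluor-accessors
#' @export
setGeneric("breakpointPercentile",
    function(x, ...) standardGeneric("breakpointPercentile"))

#' @rdname scfluor-accessors
#' @export
setGeneric("meanOnAGV", function(x, ...) standardGeneric("meanOnAGV"))

#' @rdname scfluor-accessors
#' @export
setGeneric("resultFlags", function(x, ...) standardGeneric("resultFlags"))

#' @rdname scfluor-accessors
#' @export
setGeneric("etaInt", function(x, ...) standardGeneric("etaInt"))

#' @rdname scfluor-accessors
#' @export
setGeneric("etaExt", function(x, ...) standardGeneric("etaExt"))

#' @rdname scfluor-accessors
#' @export
setGeneric("etaTot", function(x, ...) standardGeneric("etaTot"))

#' @rdname scfluor-accessors
#' @export
setGeneric("bootMean", function(x, ...) standardGeneric("bootMean"))

#' @rdname scfluor-accessors
#' @export
setGeneric("bootSD", function(x, ...) standardGeneric("bootSD"))

#' @rdname scfluor-accessors
#' @export
setGeneric("quadrantFractions",
    function(x, ...) standardGeneric("quadrantFractions"))

#' @rdname scfluor-accessors
#' @export
setGeneric("quadrantCounts", function(x, ...) standardGeneric("quadrantCounts"))

#' @rdname scfluor-accessors
#' @export
setGeneric("quadrantBoundaries",
    function(x, ...) standardGeneric("quadrantBoundaries"))

#' @rdname scfluor-accessors
#' @export
setGeneric("transferFreq", function(x, ...) standardGeneric("transferFreq"))
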