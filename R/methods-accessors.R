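#' @describeIn scfluor-accessors observed AGV matrix (channels x cells), or a
#'   single channel's vector when \code{channel} is given.
#' @param channel optional channel name.
#' @export
setMethod("agv", "FluorCellSet", function(x, channel = NULL) {
    a <- SummarizedExperiment::assay(x, "agv")
    if (is.null(channel)) return(a)
    if (!channel %in% rownames(a))
        stop("unknown channel '", channel, "'", call. = FALSE)
    a[channel, ]
})

#' @describeIn scfluor-accessors per-cell metadata (a \code{DataFrame}).
#' @export
setMethod("cellData", "FluorCellSet",
    function(x) SummarizedExperiment::colData(x))

#' @describeIn scfluor-accessors channel names of a cell set.
#' @export
setMethod("channelNames", "FluorCellSet", function(x) rownames(x))

#' @describeIn scfluor-accessors ON-subpopulation size (percent).
#' @export
setMethod("fractionOn", "BreakpointResult", function(x) x@fraction_on)

#' @describeIn scfluor-accessors AGV at the breakpoint.
#' @export
setMethod("breakpointAGV", "BreakpointResult", function(x) x@breakpoint_agv)

#' @describeIn scfluor-accessors percentile of the breakpoint.
#' @export
setMethod("breakpointPercentile", "BreakpointResult",
    function(x) x@breakpoint_percentile)

#' @describeIn scfluor-accessors mean AGV of the ON subpopulation.
#' @export
setMethod("meanOnAGV", "BreakpointResult", function(x) x@mean_on_agv)

#' @describeIn scfluor-accessors diagnostic flags of a breakpoint result.
#' @export
setMethod("resultFlags", "BreakpointResult", function(x) x@flags)

#' @describeIn scfluor-accessors diagnostic flags of a transfer result.
#' @export
setMethod("resultFlags", "TransferResult", function(x) x@flags)

#' @describeIn scfluor-accessors intrinsic noise point estimate.
#' @export
setMethod("etaInt", "NoiseEstimate", function(x) x@eta_int)

#' @describeIn scfluor-accessors extrinsic noise point estimate (signed root).
#' @param signed_sq return the signed variance ratio instead of the root.
#' @export
setMethod("etaExt", "NoiseEstimate", function(x, signed_sq = FALSE) {
    if (signed_sq) x@eta_ext_sq_signed else x@eta_ext
})

#' @describeIn scfluor-accessors total noise point estimate.
#' @export
setMethod("etaTot", "NoiseEstimate", function(x) x@eta_tot)

#' @describeIn scfluor-accessors bootstrap means (named numeric).
#' @export
setMethod("bootMean", "NoiseEstimate", function(x) x@boot_mean)

#' @describeIn scfluor-accessors bootstrap standard deviations (named numeric).
#' @export
setMethod("bootSD", "NoiseEstimate", function(x) x@boot_sd)

#' @describeIn scfluor-accessors per-quadrant activation fractions.
#' @export
setMethod("quadrantFractions", "QuadrantResult", function(x) {
    f <- x@fractions
    names(f) <- c("Q1st", "Q2nd", "Q3rd", "Q4th")
    f
})

#' @describeIn scfluor-accessors per-quadrant cell counts.
#' @export
setMethod("quadrantCounts", "QuadrantResult", function(x) {
    n <- x@counts
    names(n) <- c("Q1st", "Q2nd", "Q3rd", "Q4th")
    n
})

#' @describeIn scfluor-accessors the three quadrant cut values.
#' @export
setMethod("quadrantBoundaries", "QuadrantResult", function(x) {
    b <- x@boundaries
    names(b) <- c("mean_minus_sd", "mean", "mean_plus_sd")
    b
})

#' @describeIn scfluor-accessors transconjugants per donor CFU.
#' @export
setMethod("transferFreq", "TransferResult", function(x) x@frequency)
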