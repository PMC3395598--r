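#' @import methods
#' @importFrom stats aov TukeyHSD t.test anova cor median quantile rbinom
#'   rlnorm rnorm runif sd var setNames
#' @importFrom utils read.csv write.csv
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame metadata
NULL

#' Parameters of the threshold-activation simulator
#'
#' Full parameterization of the generative model for bistable activation of a
#' mobile genetic element gated by the cellular level of a global sigma factor
#' (RpoS). Each cell draws an RpoS level \eqn{R} from a truncated normal
#' distribution; cells with \eqn{R \ge \theta} are \emph{permissive} and
#' activate the reporter cascade with probability \code{p_act} (the unknown
#' "factor X"). Observed per-channel intensities carry shared (extrinsic) and
#' channel-specific (intrinsic) multiplicative lognormal noise, additive
#' camera background, and are clipped to the sensor range.
#'
#' @slot n_cells number of cells to simulate.
#' @slot mu_R mean RpoS level per chromosomal gene copy (arbitrary
#'   fluorescence units, AFU).
#' @slot sigma_R standard deviation of the RpoS level (AFU); held fixed when
#'   the copy number changes.
#' @slot copy_number positive integer number of gene copies; multiplies
#'   \code{mu_R} only.
#' @slot theta activation threshold on the RpoS level (AFU).
#' @slot p_act probability in [0,1] that a permissive cell actually activates.
#' @slot basal OFF-state reporter intensity (AFU).
#' @slot amplitude ON-state intensity increment (AFU).
#' @slot sigma_E lognormal shape of the shared extrinsic factor.
#' @slot sigma_I lognormal shape of each channel's intrinsic factor.
#' @slot background_mean,background_sd additive camera background (gray
#'   levels).
#' @slot bit_depth sensor bit depth, 8 or 16.
#' @slot seed RNG seed recorded with every simulation.
#'
#' @seealso [simulationParams()] for the user-facing constructor with presets,
#'   [simulatePopulation()].
#' @export
setClass("SimulationParams",
    representation(
        n_cells = "integer",
        mu_R = "numeric",
        sigma_R = "numeric",
        copy_number = "integer",
        theta = "numeric",
        p_act = "numeric",
        basal = "numeric",
        amplitude = "numeric",
        sigma_E = "numeric",
        sigma_I = "numeric",
        background_mean = "numeric",
        background_sd = "numeric",
        bit_depth = "integer",
        seed = "integer"
    )
)

setValidity("SimulationParams", function(object) {
    msgs <- character()
    chk <- function(cond, msg) if (!isTRUE(cond)) msgs <<- c(msgs, msg)
    chk(length(object@n_cells) == 1L && object@n_cells >= 1L,
        "n_cells must be a single integer >= 1")
    chk(length(object@mu_R) == 1L && is.finite(object@mu_R) &&
        object@mu_R >= 0, "mu_R must be a single non-negative number")
    chk(length(object@sigma_R) == 1L && is.finite(object@sigma_R) &&
        object@sigma_R >= 0, "sigma_R must be >= 0")
    chk(length(object@copy_number) == 1L && object@copy_number >= 1L,
        "copy_number must be an integer >= 1")
    chk(length(object@theta) == 1L && is.finite(object@theta),
        "theta must be a single finite number")
    chk(length(object@p_act) == 1L && is.finite(object@p_act) &&
        object@p_act >= 0 && object@p_act <= 1,
        "p_act must be a probability in [0, 1]")
    chk(length(object@basal) == 1L && is.finite(object@basal) &&
        object@basal >= 0, "basal must be >= 0")
    chk(length(object@amplitude) == 1L && is.finite(object@amplitude) &&
        object@amplitude >= 0, "amplitude must be >= 0")
    chk(length(object@sigma_E) == 1L && is.finite(object@sigma_E) &&
        object@sigma_E >= 0, "sigma_E must be >= 0")
    chk(length(object@sigma_I) == 1L && is.finite(object@sigma_I) &&
        object@sigma_I >= 0, "sigma_I must be >= 0")
    chk(length(object@background_sd) == 1L && is.finite(object@background_sd) &&
        object@background_sd >= 0, "background_sd must be >= 0")
    chk(length(object@bit_depth) == 1L && object@bit_depth %in% c(8L, 16L),
        "bit_depth must be 8 or 16")
    if (length(msgs)) msgs else TRUE
})

#' Per-cell fluorescence measurements for a simulated or measured population
#'
#' A thin extension of
#' \linkS4class{SummarizedExperiment}
#' holding one \code{"agv"} assay (channels in rows, cells in columns;
#' observed average gray values) together with per-cell metadata in
#' \code{colData}: identity, replicate/image provenance, and — for simulated
#' populations — the ground-truth fields (RpoS level \code{R},
#' \code{permissive}, \code{active}, extrinsic factor \code{E}, per-channel
#' saturation flags).
#'
#' @seealso [simulatePopulation()], [agv()], [cellData()], [cellTable()]
#' @export
setClass("FluorCellSet", contains = "SummarizedExperiment")

setValidity("FluorCellSet", function(object) {
    if (!"agv" %in% SummarizedExperiment::assayNames(object))
        return("assay 'agv' is required")
    a <- SummarizedExperiment::assay(object, "agv")
    if (any(!is.finite(a))) return("assay 'agv' must be finite")
    if (any(a < 0)) return("assay 'agv' must be non-negative")
    if (is.null(rownames(object))) return("channel (row) names are required")
    TRUE
})

#' Result of breakpoint detection on a cumulative AGV curve
#'
#' Produced by [findBreakpoint()]. The breakpoint separates the large OFF
#' subpopulation from the minority ON subpopulation on the cumulative ranked
#' fluorescence curve; the ON fraction is \code{100 - breakpoint_percentile}
#' by definition.
#'
#' @slot breakpoint_percentile percentile of the breakpoint, in [0, 100].
#' @slot breakpoint_agv AGV at the breakpoint (gray levels).
#' @slot fraction_on ON-subpopulation size, percent of cells.
#' @slot mean_on_agv mean AGV of cells above the breakpoint percentile.
#' @slot n_cells number of cells in the curve.
#' @slot fit_quality mean squared residual of the optimal two-segment fit.
#' @slot flags zero or more of \code{"no_subpopulation"},
#'   \code{"below_detection"}.
#' @export
setClass("BreakpointResult",
    representation(
        breakpoint_percentile = "numeric",
        breakpoint_agv = "numeric",
        fraction_on = "numeric",
        mean_on_agv = "numeric",
        n_cells = "integer",
        fit_quality = "numeric",
        flags = "character"
    )
)

setValidity("BreakpointResult", function(object) {
    msgs <- character()
    p <- object@breakpoint_percentile
    f <- object@fraction_on
    if (!(p >= 0 && p <= 100)) msgs <- c(msgs, "percentile outside [0, 100]")
    if (!(f >= 0 && f <= 100)) msgs <- c(msgs, "fraction_on outside [0, 100]")
    if (abs(f - (100 - p)) > 1e-9)
        msgs <- c(msgs, "fraction_on must equal 100 - breakpoint_percentile")
    if (is.finite(object@mean_on_agv) && is.finite(object@breakpoint_agv) &&
        object@mean_on_agv < object@breakpoint_agv - 1e-9)
        msgs <- c(msgs, "mean_on_agv must be >= breakpoint_agv")
    if (length(msgs)) msgs else TRUE
})

#' Intrinsic/extrinsic/total expression-noise estimates
#'
#' Produced by [noiseDecomposition()] and [bootstrapNoise()]. All components
#' are dimensionless. \code{eta_ext} is reported as the signed root
#' \eqn{sign(\eta_{ext}^2)\sqrt{|\eta_{ext}^2|}} and the signed variance ratio
#' is kept in \code{eta_ext_sq_signed}, so the identity
#' \eqn{\eta_{tot}^2 = \eta_{int}^2 + \eta_{ext}^2} stays exact even when the
#' sample extrinsic variance is negative.
#'
#' @slot eta_int,eta_ext,eta_tot point estimates.
#' @slot eta_ext_sq_signed signed extrinsic variance ratio before the root.
#' @slot n_cells cells used.
#' @slot boot_mean,boot_sd named numerics (\code{eta_int}, \code{eta_ext},
#'   \code{eta_tot}); \code{NA} until [bootstrapNoise()] fills them.
#' @slot n_boot number of bootstrap resamples (0 for a plain point estimate).
#' @slot boot_retries resamples that had to be redrawn (degenerate channel
#'   mean).
#' @slot seed RNG seed used for the bootstrap (\code{NA} if none).
#' @export
setClass("NoiseEstimate",
    representation(
        eta_int = "numeric",
        eta_ext = "numeric",
        eta_tot = "numeric",
        eta_ext_sq_signed = "numeric",
        n_cells = "integer",
        boot_mean = "numeric",
        boot_sd = "numeric",
        n_boot = "integer",
        boot_retries = "integer",
        seed = "integer"
    )
)

setValidity("NoiseEstimate", function(object) {
    msgs <- character()
    if (object@eta_int < 0) msgs <- c(msgs, "eta_int must be >= 0")
    if (object@eta_tot < 0) msgs <- c(msgs, "eta_tot must be >= 0")
    resid <- object@eta_tot^2 - (object@eta_int^2 + object@eta_ext_sq_signed)
    scale <- max(object@eta_tot^2, 1)
    if (abs(resid) / scale > 1e-8)
        msgs <- c(msgs, "eta_tot^2 != eta_int^2 + signed eta_ext^2")
    if (length(msgs)) msgs else TRUE
})

#' Quadrant-conditioned activation result
#'
#' Produced by [quadrantActivation()]. The conditioning-channel distribution
#' (e.g. RpoS-mCherry intensity) is cut at mean-SD, mean and mean+SD into four
#' quadrants Q1st..Q4th; per quadrant the fraction of cells whose reporter
#' value is at or above the threshold is recorded.
#'
#' @slot boundaries the three cut values (conditioning-channel units).
#' @slot fractions four activation fractions in [0, 1] (\code{NaN} for an
#'   empty quadrant).
#' @slot counts cells per quadrant.
#' @slot threshold reporter threshold used.
#' @export
setClass("QuadrantResult",
    representation(
        boundaries = "numeric",
        fractions = "numeric",
        counts = "integer",
        threshold = "numeric"
    )
)

setValidity("QuadrantResult", function(object) {
    msgs <- character()
    if (length(object@boundaries) != 3L) msgs <- c(msgs, "need 3 boundaries")
    if (length(object@fractions) != 4L) msgs <- c(msgs, "need 4 fractions")
    if (length(object@counts) != 4L) msgs <- c(msgs, "need 4 counts")
    ok <- object@fractions[!is.nan(object@fractions)]
    if (any(ok < 0 | ok > 1)) msgs <- c(msgs, "fractions outside [0, 1]")
    if (length(msgs)) msgs else TRUE
})

#' Conjugative transfer-frequency result
#'
#' Transfer frequency is the number of transconjugant colony-forming units
#' per donor CFU. Zero transconjugants are reported as frequency 0 with a
#' \code{"detection_limit"} flag.
#'
#' @slot donor_cfu,transconjugant_cfu colony counts.
#' @slot frequency transconjugants per donor.
#' @slot flags \code{"detection_limit"} when no transconjugants were observed.
#' @export
setClass("TransferResult",
    representation(
        donor_cfu = "numeric",
        transconjugant_cfu = "numeric",
        frequency = "numeric",
        flags = "character"
    )
)

setValidity("TransferResult", function(object) {
    msgs <- character()
    if (object@donor_cfu <= 0) msgs <- c(msgs, "donor_cfu must be > 0")
    if (object@transconjugant_cfu < 0)
        msgs <- c(msgs, "transconjugant_cfu must be >= 0")
    expected <- object@transconjugant_cfu / object@donor_cfu
    if (abs(object@frequency - expected) > 1e-12 * max(1, expected))
        msgs <- c(msgs, "frequency must equal transconjugant_cfu / donor_cfu")
    if (length(msgs)) msgs else TRUE
})
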