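#' Cumulative ranked AGV curve
#'
#' Sorts per-cell AGVs ascending and attaches percentiles: the i-th of n
#' sorted values gets percentile \eqn{100 i / n}. Ties keep their stable
#' (input) order.
#'
#' @param values numeric vector of per-cell AGVs (length >= 2).
#' @return data.frame with columns \code{percentile}, \code{agv}, ordered by
#'   AGV (monotone non-decreasing).
#' @examples
#' cumulativeCurve(c(5, 1, 3))
#' @export
cumulativeCurve <- function(values) {
    if (length(values) < 2L)
        stop("need at least 2 values to build a cumulative curve",
            call. = FALSE)
    if (any(!is.finite(values)))
        stop("values must be finite", call. = FALSE)
    n <- length(values)
    data.frame(percentile = 100 * seq_len(n) / n,
        agv = sort(values, method = "radix"))
}

#' Locate the OFF/ON breakpoint on a cumulative AGV curve
#'
#' Automated replacement for manually placing slope lines on the linear
#' parts of the cumulative curve: every candidate split percentile (grid of
#' data percentiles within \code{split_range}) divides the curve into a left
#' and a right segment; ordinary least-squares lines are fitted to each side
#' and the split minimizing the total squared residual is selected. The
#' breakpoint is the intersection of the two fitted lines, clamped into the
#' interval spanned by the optimal split and mapped to the nearest data
#' percentile (the clamping keeps the estimate at the changepoint when the
#' two subpopulations are separated by a wide intensity gap, where the
#' unconstrained intersection would drift into the OFF segment).
#'
#' The ON-subpopulation size is \code{100 - breakpoint_percentile}; its mean
#' expression is the mean AGV over the percentile range above the
#' breakpoint. A zero-variance curve yields \code{fraction_on = 0} with flag
#' \code{"no_subpopulation"}; the same flag marks curves whose upper tail is
#' not separated from the bulk (ON mean within twice the population median,
#' i.e. no bistable mode). An ON subpopulation whose mean AGV falls below
#' \code{detection_floor} is flagged \code{"below_detection"}.
#'
#' @param curve data.frame from [cumulativeCurve()] (>= 20 points).
#' @param split_range percentile window searched for the split; the ON
#'   subpopulation is assumed to be the minority, so the window starts at 50.
#' @param min_right minimum number of points above a candidate split.
#' @param detection_floor AGV below which an ON subpopulation is reported as
#'   below the detection threshold.
#' @return a \linkS4class{BreakpointResult}.
#' @examples
#' vals <- c(rnorm(970, 10, 1), rnorm(30, 200, 10))
#' findBreakpoint(cumulativeCurve(vals))
#' @export
findBreakpoint <- function(curve, split_range = c(50, 99.9),
        min_right = 3L, detection_floor = 10) {
    stopifnot(is.data.frame(curve),
        all(c("percentile", "agv") %in% names(curve)))
    x <- curve$percentile
    y <- curve$agv
    n <- length(x)
    if (n < 20L)
        stop("need at least 20 points to fit a breakpoint", call. = FALSE)

    if (var(y) == 0) {
        return(new("BreakpointResult",
            breakpoint_percentile = 100, breakpoint_agv = y[n],
            fraction_on = 0, mean_on_agv = y[n], n_cells = n,
            fit_quality = 0, flags = "no_subpopulation"))
    }

    # O(n) two-segment least squares via prefix sums
    cx <- cumsum(x); cy <- cumsum(y)
    cxx <- cumsum(x * x); cyy <- cumsum(y * y); cxy <- cumsum(x * y)
    seg_stats <- function(sx, sy, sxx, syy, sxy, m) {
        vx <- sxx - sx^2 / m
        vy <- syy - sy^2 / m
        vxy <- sxy - sx * sy / m
        slope <- ifelse(vx > 0, vxy / vx, 0)
        sse <- pmax(vy - ifelse(vx > 0, vxy^2 / vx, 0), 0)
        list(slope = slope, intercept = sy / m - slope * sx / m, sse = sse)
    }
    cand <- which(x >= split_range[1] & x <= split_range[2] &
        seq_len(n) >= 2L & seq_len(n) <= n - min_right)
    if (!length(cand))
        stop("no admissible split percentiles in range", call. = FALSE)
    i <- cand
    left <- seg_stats(cx[i], cy[i], cxx[i], cyy[i], cxy[i], i)
    right <- seg_stats(cx[n] - cx[i], cy[n] - cy[i], cxx[n] - cxx[i],
        cyy[n] - cyy[i], cxy[n] - cxy[i], n - i)
    total <- left$sse + right$sse
    best <- which.min(total)
    i_star <- cand[best]

    m1 <- left$slope[best]; b1 <- left$intercept[best]
    m2 <- right$slope[best]; b2 <- right$intercept[best]
    x_int <- if (isTRUE(all.equal(m1, m2))) x[i_star]
        else (b1 - b2) / (m2 - m1)
    # refine within the split interval only
    x_int <- min(max(x_int, x[i_star]), x[i_star + 1L])
    k <- if (abs(x_int - x[i_star]) <= abs(x[i_star + 1L] - x_int))
        i_star else i_star + 1L

    on_idx <- if (k < n) seq.int(k + 1L, n) else integer()
    mean_on <- if (length(on_idx)) mean(y[on_idx]) else y[n]
    flags <- character()
    if (mean_on < detection_floor) flags <- c(flags, "below_detection")
    # bistable ON cells are far brighter than the OFF mode; an "ON" mean
    # within 2x of the population median is just the tail of a unimodal curve
    if (mean_on < 2 * median(y)) flags <- c(flags, "no_subpopulation")
    new("BreakpointResult",
        breakpoint_percentile = x[k], breakpoint_agv = y[k],
        fraction_on = 100 - x[k], mean_on_agv = mean_on,
        n_cells = n, fit_quality = total[best] / n, flags = flags)
}

#' Summarize ON-subpopulation estimates across biological replicates
#'
#' Collects per-replicate breakpoint results into the "value +/- SD across
#' biological triplicates" table convention. With a single replicate the SD
#' is reported as 0 with flag \code{"single_replicate"}.
#'
#' @param results a list of \linkS4class{BreakpointResult} objects (one per
#'   replicate), or a single result.
#' @return data.frame with one row: \code{n_replicates},
#'   \code{fraction_on_mean}, \code{fraction_on_sd}, \code{mean_on_agv_mean},
#'   \code{mean_on_agv_sd}, \code{flags} (collapsed, comma separated).
#' @examples
#' vals <- lapply(1:3, function(s) {
#'     set.seed(s); c(rnorm(970, 10, 1), rnorm(30, 200, 10))
#' })
#' subpopulationSummary(lapply(vals, function(v)
#'     findBreakpoint(cumulativeCurve(v))))
#' @export
subpopulationSummary <- function(results) {
    if (is(results, "BreakpointResult")) results <- list(results)
    stopifnot(length(results) >= 1L,
        all(vapply(results, is, logical(1), "BreakpointResult")))
    fr <- vapply(results, fractionOn, numeric(1))
    mo <- vapply(results, meanOnAGV, numeric(1))
    flags <- unique(unlist(lapply(results, resultFlags)))
    if (length(results) == 1L) flags <- c(flags, "single_replicate")
    sd0 <- function(v) if (length(v) > 1L) sd(v) else 0
    data.frame(
        n_replicates = length(results),
        fraction_on_mean = mean(fr), fraction_on_sd = sd0(fr),
        mean_on_agv_mean = mean(mo), mean_on_agv_sd = sd0(mo),
        flags = paste(flags, collapse = ","))
}
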