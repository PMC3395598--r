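#' Scale and normalize paired-reporter AGVs
#'
#' Per channel: subtract the image background AGV, floor at 0, and normalize
#' to the highest AGV in the population (= 100). Channels are normalized
#' independently, which makes the two reporters comparable despite different
#' gains.
#'
#' @param raw_g,raw_c equal-length paired raw AGV vectors (one pair per
#'   cell).
#' @param background_g,background_c per-channel background AGVs.
#' @return list with normalized \code{g} and \code{c} in [0, 100].
#' @examples
#' scaleAndNormalize(c(12, 22, 112), c(14, 54, 104),
#'     background_g = 12, background_c = 4)
#' @export
scaleAndNormalize <- function(raw_g, raw_c, background_g = 0,
        background_c = 0) {
    if (length(raw_g) != length(raw_c))
        stop("raw_g and raw_c must be paired (equal length)", call. = FALSE)
    norm1 <- function(v, bg, name) {
        v <- pmax(v - bg, 0)
        m <- max(v)
        if (!is.finite(m) || m <= 0)
            stop("no signal in channel ", name,
                " after background subtraction", call. = FALSE)
        100 * v / m
    }
    list(g = norm1(raw_g, background_g, "g"),
        c = norm1(raw_c, background_c, "c"))
}

#' Gate paired reporters to the active subpopulation
#'
#' Retains cells above the breakpoint in \emph{either} channel's cumulative
#' curve (union, the default) or in both (intersection). Both channel values
#' are kept for retained cells. Saturated cells can be excluded before
#' gating.
#'
#' @param g,c paired per-cell values.
#' @param breakpoint_g,breakpoint_c per-channel breakpoints: a
#'   \linkS4class{BreakpointResult} or a breakpoint percentile in [0, 100].
#' @param mode \code{"union"} (cells ON in g or c) or
#'   \code{"intersection"}.
#' @param saturated optional logical vector; when given and
#'   \code{exclude_saturated}, flagged cells are dropped first.
#' @param exclude_saturated drop saturated cells (default TRUE).
#' @return list with gated \code{g}, \code{c} and the retained cell indices
#'   \code{idx} (relative to the input).
#' @export
selectActive <- function(g, c, breakpoint_g, breakpoint_c,
        mode = c("union", "intersection"), saturated = NULL,
        exclude_saturated = TRUE) {
    mode <- match.arg(mode)
    if (length(g) != length(c))
        stop("g and c must be paired (equal length)", call. = FALSE)
    keep0 <- rep(TRUE, length(g))
    if (!is.null(saturated) && exclude_saturated) {
        stopifnot(length(saturated) == length(g))
        keep0 <- !saturated
    }
    pct <- function(bp) {
        if (is(bp, "BreakpointResult")) breakpointPercentile(bp)
        else check_scalar(bp, "breakpoint percentile", 0, 100)
    }
    above <- function(v, p) {
        # ON set = values above the breakpoint percentile of this channel's
        # cumulative ranking (stable ties, as in cumulativeCurve)
        n <- length(v)
        rank(v, ties.method = "first") > n * p / 100
    }
    on_g <- above(g, pct(breakpoint_g))
    on_c <- above(c, pct(breakpoint_c))
    keep <- keep0 & if (mode == "union") (on_g | on_c) else (on_g & on_c)
    idx <- which(keep)
    if (length(idx) < 2L)
        stop(sprintf("noise undefined: only %d cell(s) retained after gating",
            length(idx)), call. = FALSE)
    list(g = g[idx], c = c[idx], idx = idx)
}

#' Intrinsic/extrinsic/total noise decomposition of paired reporters
#'
#' Moment-based two-reporter decomposition:
#' \deqn{\eta_{int}^2 = \frac{\langle (g - c)^2 \rangle}
#'   {2 \langle g \rangle \langle c \rangle}, \quad
#'   \eta_{ext}^2 = \frac{\langle g c \rangle -
#'   \langle g \rangle \langle c \rangle}{\langle g \rangle \langle c
#'   \rangle}, \quad
#'   \eta_{tot}^2 = \frac{(\langle g^2 \rangle + \langle c^2 \rangle)/2 -
#'   \langle g \rangle \langle c \rangle}{\langle g \rangle \langle c
#'   \rangle},}
#' where angled brackets are sample means. The identity
#' \eqn{\eta_{tot}^2 = \eta_{int}^2 + \eta_{ext}^2} is exact by
#' construction. A negative sample \eqn{\eta_{ext}^2} (possible at small n)
#' is preserved as a signed quantity; \code{eta_ext} is its signed root.
#'
#' @param g,c paired normalized reporter values (n >= 2, positive means).
#' @return a \linkS4class{NoiseEstimate} (bootstrap fields empty).
#' @examples
#' ne <- noiseDecomposition(c(1, 2), c(2, 1))
#' etaInt(ne)^2      # 0.2222
#' etaExt(ne, signed_sq = TRUE)  # -0.1111
#' @export
noiseDecomposition <- function(g, c) {
    if (length(g) != length(c))
        stop("g and c must be paired (equal length)", call. = FALSE)
    if (length(g) < 2L)
        stop("need at least 2 cells", call. = FALSE)
    mg <- mean(g); mc <- mean(c)
    if (!(mg > 0) || !(mc > 0))
        stop("channel means must be positive", call. = FALSE)
    denom <- mg * mc
    int2 <- mean((g - c)^2) / (2 * denom)
    ext2 <- mean(g * c) / denom - 1
    tot2 <- (mean(g^2) + mean(c^2)) / (2 * denom) - 1
    new("NoiseEstimate",
        eta_int = sqrt(int2),
        eta_ext = sign(ext2) * sqrt(abs(ext2)),
        eta_tot = sqrt(max(tot2, 0)),
        eta_ext_sq_signed = ext2,
        n_cells = length(g),
        boot_mean = c(eta_int = NA_real_, eta_ext = NA_real_,
            eta_tot = NA_real_),
        boot_sd = c(eta_int = NA_real_, eta_ext = NA_real_,
            eta_tot = NA_real_),
        n_boot = 0L, boot_retries = 0L, seed = NA_integer_)
}

#' Bootstrap uncertainty for the noise decomposition
#'
#' Resamples cells with replacement \code{n_boot} times (1000 by default),
#' recomputes the decomposition on each resample, and reports the mean and
#' SD of each component over the resamples. A degenerate resample (zero
#' channel mean) is redrawn, with a bounded retry budget, and counted.
#' Deterministic given \code{seed}.
#'
#' @param g,c paired reporter values.
#' @param n_boot number of resamples.
#' @param seed RNG seed.
#' @param max_retries retry budget per degenerate resample.
#' @return a \linkS4class{NoiseEstimate} with \code{boot_mean} /
#'   \code{boot_sd} filled.
#' @export
bootstrapNoise <- function(g, c, n_boot = 1000L, seed = NULL,
        max_retries = 100L) {
    point <- noiseDecomposition(g, c)
    n_boot <- check_count(n_boot, "n_boot")
    n <- length(g)
    retries <- 0L
    comp <- matrix(NA_real_, nrow = n_boot, ncol = 3L,
        dimnames = list(NULL, c("eta_int", "eta_ext", "eta_tot")))
    with_seed(seed, {
        for (b in seq_len(n_boot)) {
            for (try in seq_len(max_retries)) {
                idx <- sample.int(n, n, replace = TRUE)
                if (mean(g[idx]) > 0 && mean(c[idx]) > 0) break
                retries <- retries + 1L
                if (try == max_retries)
                    stop("bootstrap resampling kept producing zero-mean ",
                        "channels", call. = FALSE)
            }
            ne <- noiseDecomposition(g[idx], c[idx])
            comp[b, ] <- c(ne@eta_int, ne@eta_ext, ne@eta_tot)
        }
    })
    point@boot_mean <- colMeans(comp)
    point@boot_sd <- apply(comp, 2L, sd)
    if (n_boot == 1L) point@boot_sd[] <- 0
    point@n_boot <- n_boot
    point@boot_retries <- retries
    point@seed <- if (is.null(seed)) NA_integer_ else as.integer(seed)
    point
}

#' Total noise implied by intrinsic and extrinsic components
#'
#' Quadrature helper: \eqn{\eta_{tot} = \sqrt{\eta_{int}^2 +
#' \eta_{ext}^2}}. Vectorized; useful for checking the internal consistency
#' of reported noise triples.
#'
#' @param eta_int,eta_ext non-negative noise components.
#' @return implied total noise.
#' @examples
#' totalNoiseFromComponents(0.547, 0.553)
#' @export
totalNoiseFromComponents <- function(eta_int, eta_ext) {
    stopifnot(all(eta_int >= 0), all(eta_ext >= 0))
    sqrt(eta_int^2 + eta_ext^2)
}
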