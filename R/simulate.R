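#' Construct simulator parameters, optionally from a named preset
#'
#' The generative model: each cell draws an RpoS level
#' \eqn{R \sim N(copy\_number \cdot \mu_R, \sigma_R)} truncated at 0. Cells
#' with \eqn{R \ge \theta} are permissive; a permissive cell activates with
#' probability \code{p_act}. The expected activated fraction is therefore the
#' Gaussian upper-tail probability
#' \eqn{p_{act}\,\Phi((copy\_number\cdot\mu_R - \theta)/\sigma_R)}.
#'
#' Presets state the two headline population structures as emergent tail
#' probabilities:
#' \describe{
#'   \item{\code{"wildtype"}}{single copy, \eqn{\theta = \mu_R + 1.881
#'     \sigma_R}: ~3\% of cells activate, the wild-type bistable fraction.}
#'   \item{\code{"rpos_double"}}{two gene copies (mean RpoS doubles,
#'     \eqn{\sigma_R} fixed), \eqn{\theta = 2\mu_R + 0.915\sigma_R}: ~18\% of
#'     cells activate, as observed when the gene dose of the sigma factor is
#'     doubled.}
#' }
#'
#' @param preset \code{"wildtype"} (default) or \code{"rpos_double"}.
#' @param n_cells,mu_R,sigma_R,copy_number,theta,p_act,basal,amplitude
#'   override individual parameters; see \linkS4class{SimulationParams}.
#' @param sigma_E,sigma_I,background_mean,background_sd,bit_depth,seed idem.
#' @return a validated \linkS4class{SimulationParams} object.
#' @examples
#' p <- simulationParams("wildtype", n_cells = 1000, seed = 7)
#' p
#' @export
simulationParams <- function(preset = c("wildtype", "rpos_double"),
        n_cells = 10000, mu_R = 50, sigma_R = 10, copy_number = NULL,
        theta = NULL, p_act = 1, basal = 5, amplitude = 150,
        sigma_E = 0.3, sigma_I = 0.3, background_mean = 10,
        background_sd = 2, bit_depth = 8, seed = 1) {
    preset <- match.arg(preset)
    if (is.null(copy_number))
        copy_number <- if (preset == "rpos_double") 2L else 1L
    if (is.null(theta)) {
        z <- if (preset == "rpos_double") 0.915 else 1.881
        theta <- copy_number * mu_R + z * sigma_R
    }
    new("SimulationParams",
        n_cells = check_count(n_cells, "n_cells"),
        mu_R = check_scalar(mu_R, "mu_R", min = 0),
        sigma_R = check_scalar(sigma_R, "sigma_R", min = 0),
        copy_number = check_count(copy_number, "copy_number"),
        theta = check_scalar(theta, "theta"),
        p_act = check_prob(p_act, "p_act"),
        basal = check_scalar(basal, "basal", min = 0),
        amplitude = check_scalar(amplitude, "amplitude", min = 0),
        sigma_E = check_scalar(sigma_E, "sigma_E", min = 0),
        sigma_I = check_scalar(sigma_I, "sigma_I", min = 0),
        background_mean = check_scalar(background_mean, "background_mean"),
        background_sd = check_scalar(background_sd, "background_sd", min = 0),
        bit_depth = check_count(bit_depth, "bit_depth"),
        seed = check_count(seed, "seed", min = -2^31 + 1))
}

# Normal(mean, sd) truncated at 0 by resampling; negligible correction for
# the default parameter regime (mean >> sd).
rnorm_trunc0 <- function(n, mean, sd) {
    x <- rnorm(n, mean, sd)
    if (sd == 0) {
        if (mean < 0) stop("truncated normal with sd = 0 and mean < 0")
        return(x)
    }
    while (any(bad <- x < 0)) x[bad] <- rnorm(sum(bad), mean, sd)
    x
}

# Unit-mean lognormal draws with shape (sdlog) sigma.
rlnorm_unit <- function(n, sigma) {
    if (sigma == 0) return(rep(1, n))
    rlnorm(n, meanlog = -sigma^2 / 2, sdlog = sigma)
}

#' Simulate a clonal population under the threshold-activation model
#'
#' Draws per-cell RpoS levels, applies the activation gate (threshold plus
#' the Bernoulli "factor X"), and produces observed AGVs in two reporter
#' channels (\code{egfp}, \code{echerry}). Both channels share the per-cell
#' extrinsic factor \eqn{E} (unit-mean lognormal, shape \code{sigma_E}) and
#' carry independent intrinsic factors (shape \code{sigma_I}):
#' \deqn{raw = E \cdot \epsilon_{ch} \cdot (basal + amplitude \cdot active)
#'   + N(bg_{mean}, bg_{sd}),}
#' clipped to the sensor range \eqn{[0, 2^{bit\_depth}-1]}. Cells whose
#' pre-clip value reaches the sensor maximum are flagged saturated per
#' channel. Deterministic given \code{params@seed}.
#'
#' @param params a \linkS4class{SimulationParams} object.
#' @param replicate replicate label stored in the per-cell metadata.
#' @return a \linkS4class{FluorCellSet}; ground truth (R, permissive, active,
#'   E, saturation flags) in \code{colData}, parameters in \code{metadata}.
#' @examples
#' cells <- simulatePopulation(simulationParams(n_cells = 2000, seed = 3))
#' mean(cells$active)           # ~ pnorm(-1.881) = 3%
#' head(agv(cells, "egfp"))
#' @export
simulatePopulation <- function(params, replicate = "rep1") {
    stopifnot(is(params, "SimulationParams"))
    validObject(params)
    n <- params@n_cells
    smax <- sensor_max(params@bit_depth)
    with_seed(params@seed, {
        R <- rnorm_trunc0(n, params@copy_number * params@mu_R, params@sigma_R)
        permissive <- R >= params@theta
        active <- permissive & (runif(n) < params@p_act)
        E <- rlnorm_unit(n, params@sigma_E)
        signal <- params@basal + params@amplitude * active
        channel_obs <- function() {
            eps <- rlnorm_unit(n, params@sigma_I)
            raw <- E * eps * signal +
                rnorm(n, params@background_mean, params@background_sd)
            list(val = pmin(pmax(raw, 0), smax), sat = raw >= smax)
        }
        g <- channel_obs()
        c_ <- channel_obs()
        a <- rbind(egfp = g$val, echerry = c_$val)
        colnames(a) <- sprintf("cell_%05d", seq_len(n))
        cd <- S4Vectors::DataFrame(
            cell_id = colnames(a),
            replicate = replicate,
            R = R, permissive = permissive, active = active, E = E,
            saturated_egfp = g$sat, saturated_echerry = c_$sat,
            row.names = colnames(a))
        se <- SummarizedExperiment::SummarizedExperiment(
            assays = list(agv = a), colData = cd,
            metadata = list(params = params, seed = params@seed))
        new("FluorCellSet", se)
    })
}

#' Simulate a paired dual-reporter sample with known noise components
#'
#' Generates \eqn{g_i = E_i a_i}, \eqn{c_i = E_i b_i} where \eqn{E} is the
#' shared (extrinsic) unit-mean lognormal factor with shape \code{sigma_E}
#' and \eqn{a, b} are independent intrinsic factors with shape
#' \code{sigma_I}. The closed-form population truths are returned alongside
#' the sample:
#' \deqn{\eta_{ext} = CV_E = \sqrt{e^{\sigma_E^2} - 1}, \qquad
#'   \eta_{int} = CV_a \sqrt{1 + CV_E^2}.}
#'
#' @param n number of cells (>= 2).
#' @param sigma_E,sigma_I lognormal shapes (>= 0).
#' @param seed RNG seed (optional).
#' @return list with \code{g}, \code{c}, \code{eta_ext_true},
#'   \code{eta_int_true}, \code{n}, \code{seed}.
#' @examples
#' s <- simulateDualReporter(5000, 0.5, 0.3, seed = 1)
#' s$eta_ext_true
#' @export
simulateDualReporter <- function(n, sigma_E, sigma_I, seed = NULL) {
    n <- check_count(n, "n", min = 2L)
    check_scalar(sigma_E, "sigma_E", min = 0)
    check_scalar(sigma_I, "sigma_I", min = 0)
    cv_e <- sqrt(exp(sigma_E^2) - 1)
    cv_a <- sqrt(exp(sigma_I^2) - 1)
    with_seed(seed, {
        E <- rlnorm_unit(n, sigma_E)
        a <- rlnorm_unit(n, sigma_I)
        b <- rlnorm_unit(n, sigma_I)
        list(g = E * a, c = E * b,
            eta_ext_true = cv_e,
            eta_int_true = cv_a * sqrt(1 + cv_e^2),
            n = n, seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
    })
}

#' Simulate a conjugative transfer (mating) assay
#'
#' Each donor cell yields a transconjugant with probability
#' \code{activation_fraction * p_transfer_given_active}; transconjugant
#' counts are binomial.
#'
#' @param n_donors donor CFU count.
#' @param activation_fraction fraction of donors with an activated element.
#' @param p_transfer_given_active transfer probability for an activated donor.
#' @param seed RNG seed (optional).
#' @return list with \code{donor_cfu}, \code{transconjugant_cfu} and the
#'   realized \code{frequency}.
#' @examples
#' simulateTransferAssay(1e6, 0.03, 1e-2, seed = 1)
#' @export
simulateTransferAssay <- function(n_donors, activation_fraction,
        p_transfer_given_active, seed = NULL) {
    n_donors <- check_count(n_donors, "n_donors")
    check_prob(activation_fraction, "activation_fraction")
    check_prob(p_transfer_given_active, "p_transfer_given_active")
    p <- activation_fraction * p_transfer_given_active
    with_seed(seed, {
        t_cfu <- rbinom(1L, n_donors, p)
        list(donor_cfu = n_donors, transconjugant_cfu = t_cfu,
            frequency = t_cfu / n_donors)
    })
}
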