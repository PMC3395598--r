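test_that("parameter validation rejects bad values naming the field", {
    expect_error(simulationParams(p_act = 1.5), "p_act")
    expect_error(simulationParams(p_act = -0.1), "p_act")
    expect_error(simulationParams(sigma_E = -1), "sigma_E")
    expect_error(simulationParams(sigma_R = -2), "sigma_R")
    expect_error(simulationParams(n_cells = 0), "n_cells")
    expect_error(simulationParams(bit_depth = 12), "bit_depth")
    expect_error(simulationParams(copy_number = 0), "copy_number")
})

test_that("no cell activates without factor X, and active implies permissive", {
    cs <- simulatePopulation(simulationParams(n_cells = 3000, p_act = 0,
        seed = 2))
    expect_identical(sum(cs$active), 0L)
    # property: active => permissive across a sweep of regimes
    for (s in 1:5) {
        p <- simulationParams(n_cells = 500, p_act = runif(1),
            theta = runif(1, 30, 90), seed = s)
        cs <- simulatePopulation(p)
        expect_true(all(!cs$active | cs$permissive))
        expect_true(all(agv(cs) >= 0 & agv(cs) <= 255))
    }
})

test_that("activated fraction matches the Gaussian upper-tail oracle", {
    # theta = mu + 1.881 sigma, p_act = 1: expected fraction pnorm(-1.881)
    p <- simulationParams(n_cells = 1e5, mu_R = 50, sigma_R = 10,
        theta = 50 + 1.881 * 10, p_act = 1, seed = 7)
    frac <- 100 * mean(simulatePopulation(p)$active)
    expect_equal(frac, 100 * pnorm(-1.881), tolerance = 0.2 / 3)
    expect_lt(abs(frac - 3.0), 0.2)
    # partial factor X scales the tail probability
    p2 <- simulationParams(n_cells = 1e5, theta = 50 + 1.881 * 10,
        p_act = 0.5, seed = 8)
    expect_lt(abs(100 * mean(simulatePopulation(p2)$active) -
        50 * pnorm(-1.881)), 0.2)
})

test_that("doubling the gene copy number doubles the mean RpoS level", {
    p1 <- simulationParams(n_cells = 2e4, copy_number = 1, seed = 5)
    p2 <- simulationParams(n_cells = 2e4, copy_number = 2,
        theta = p1@theta, seed = 5)
    ratio <- mean(simulatePopulation(p2)$R) / mean(simulatePopulation(p1)$R)
    expect_lt(abs(ratio - 2), 0.05)
})

test_that("the rpos_double preset yields the enlarged ON subpopulation", {
    pd <- simulationParams("rpos_double", n_cells = 5e4, seed = 6)
    expect_identical(pd@copy_number, 2L)
    frac <- 100 * mean(simulatePopulation(pd)$active)
    expect_equal(frac, 100 * pnorm(-0.915), tolerance = 0.05)
})

test_that("simulation is deterministic given the seed", {
    p <- simulationParams(n_cells = 1000, seed = 42)
    a1 <- agv(simulatePopulation(p))
    a2 <- agv(simulatePopulation(p))
    expect_identical(a1, a2)
    a3 <- agv(simulatePopulation(simulationParams(n_cells = 1000,
        seed = 43)))
    expect_false(identical(a1, a3))
})

test_that("saturation clips at the sensor maximum and is flagged", {
    p <- simulationParams(n_cells = 500, amplitude = 5000, p_act = 1,
        theta = 0, sigma_E = 0, sigma_I = 0, seed = 3)
    cs <- simulatePopulation(p)
    expect_true(all(agv(cs, "echerry") <= 255))
    expect_true(all(cs$saturated_egfp))
    expect_true(all(agv(cs, "egfp")[cs$saturated_egfp] == 255))
    # 16-bit sensor does not clip the same signal
    p16 <- simulationParams(n_cells = 500, amplitude = 5000, p_act = 1,
        theta = 0, sigma_E = 0, sigma_I = 0, bit_depth = 16, seed = 3)
    expect_false(any(simulatePopulation(p16)$saturated_egfp))
})

test_that("dual-reporter sample matches its returned closed-form truths", {
    # sigma_I = 0: the channels are identical
    s0 <- simulateDualReporter(100, sigma_E = 0.4, sigma_I = 0, seed = 1)
    expect_identical(s0$g, s0$c)
    expect_equal(s0$eta_int_true, 0)
    # sigma_E = 0: estimated extrinsic noise vanishes with n
    s1 <- simulateDualReporter(5e4, sigma_E = 0, sigma_I = 0.4, seed = 2)
    expect_equal(s1$eta_ext_true, 0)
    # on the variance scale: the signed extrinsic ratio fluctuates ~ 1/sqrt(n)
    expect_lt(abs(etaExt(noiseDecomposition(s1$g, s1$c),
        signed_sq = TRUE)), 0.005)
    # reference shapes: truths from the lognormal CV formulas
    s <- simulateDualReporter(5e4, sigma_E = 0.5164, sigma_I = 0.4542,
        seed = 3)
    expect_equal(s$eta_ext_true, sqrt(exp(0.5164^2) - 1), tolerance = 1e-12)
    expect_equal(s$eta_int_true,
        sqrt(exp(0.4542^2) - 1) * sqrt(exp(0.5164^2)), tolerance = 1e-12)
    ne <- noiseDecomposition(s$g, s$c)
    expect_lt(abs(etaExt(ne) - s$eta_ext_true), 0.01)
    expect_lt(abs(etaInt(ne) - s$eta_int_true), 0.01)
    expect_error(simulateDualReporter(1, 0.1, 0.1), "n")
})

test_that("transfer assay follows the product of probabilities", {
    expect_identical(
        simulateTransferAssay(1e6, 0, 0.5, seed = 1)$transconjugant_cfu, 0L)
    full <- simulateTransferAssay(1e6, 1, 1, seed = 1)
    expect_equal(full$frequency, 1)
    # expected frequency = activation_fraction * p_transfer
    s <- simulateTransferAssay(1e9, 0.03, 1e-4, seed = 4)
    expect_equal(s$frequency, 3e-6, tolerance = 0.1)
    expect_error(simulateTransferAssay(1e6, 1.2, 0.5), "activation_fraction")
})
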