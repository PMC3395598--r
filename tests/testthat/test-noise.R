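test_that("scaling/normalization maps each channel onto [0, 100]", {
    nz <- scaleAndNormalize(c(12, 22, 112), c(14, 54, 104),
        background_g = 12, background_c = 4)
    expect_equal(nz$g, c(0, 10, 100))
    expect_equal(nz$c, c(10, 50, 100))
    # channel maximum maps to exactly 100; joint rescaling cancels
    expect_equal(max(nz$g), 100)
    lam <- 3.7
    nz2 <- scaleAndNormalize(lam * c(12, 22, 112), lam * c(14, 54, 104),
        background_g = lam * 12, background_c = lam * 4)
    expect_equal(nz2$g, nz$g)
    expect_equal(nz2$c, nz$c)
    expect_error(scaleAndNormalize(c(1, 2), c(5, 5), background_c = 10),
        "no signal")
    expect_error(scaleAndNormalize(1:3, 1:4), "paired")
})

test_that("active-cell gating takes the union of per-channel ON sets", {
    g <- c(1, 2, 3, 100, 90, 80)
    c_ <- c(1, 2, 95, 3, 85, 70)
    # breakpoints at percentile 0: everything retained
    all_in <- selectActive(g, c_, 0, 0)
    expect_identical(all_in$idx, 1:6)
    # 50th-percentile breakpoints: top-3 of each channel, union
    un <- selectActive(g, c_, 50, 50)
    expect_identical(un$idx, c(3L, 4L, 5L, 6L))
    # intersection mode keeps only cells ON in both channels
    int <- selectActive(g, c_, 50, 50, mode = "intersection")
    expect_identical(int$idx, c(5L, 6L))
    # one channel entirely below its breakpoint: union = other ON set
    only_g <- selectActive(g, rep(1, 6), 50, 100)
    expect_identical(only_g$idx, c(4L, 5L, 6L))
    # saturated cells are dropped before gating
    no_sat <- selectActive(g, c_, 50, 50,
        saturated = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE))
    expect_identical(no_sat$idx, c(4L, 5L, 6L))
    expect_error(selectActive(g, c_, 100, 100), "0 cell")
})

test_that("gated fraction of a correlated bimodal pair sits in [3%, 6%]", {
    cs <- simulatePopulation(simulationParams(n_cells = 2e4, seed = 12))
    nz <- scaleAndNormalize(agv(cs, "egfp"), agv(cs, "echerry"),
        background_g = 10, background_c = 10)
    bp_g <- findBreakpoint(cumulativeCurve(nz$g))
    bp_c <- findBreakpoint(cumulativeCurve(nz$c))
    gated <- selectActive(nz$g, nz$c, bp_g, bp_c,
        exclude_saturated = FALSE)
    frac <- 100 * length(gated$idx) / length(nz$g)
    expect_gte(frac, 0.9 * min(fractionOn(bp_g), fractionOn(bp_c)))
    expect_lte(frac, 1.1 * (fractionOn(bp_g) + fractionOn(bp_c)))
})

test_that("noise decomposition reproduces hand-computed moments", {
    # identical channels: all variability is extrinsic
    g <- c(1, 5, 9, 2)
    same <- noiseDecomposition(g, g)
    expect_equal(etaInt(same), 0)
    expect_equal(etaTot(same), etaExt(same))
    # two-cell example, moments by hand: <g>=<c>=1.5, <gc>=2, <(g-c)^2>=1
    ne <- noiseDecomposition(c(1, 2), c(2, 1))
    expect_equal(etaInt(ne)^2, 1 / (2 * 2.25), tolerance = 1e-12)
    expect_equal(etaExt(ne, signed_sq = TRUE), (2 - 2.25) / 2.25,
        tolerance = 1e-12)
    expect_equal(etaTot(ne)^2, (2.5 - 2.25) / 2.25, tolerance = 1e-12)
    expect_equal(etaExt(ne), -sqrt(1 / 9), tolerance = 1e-12)
    expect_error(noiseDecomposition(c(1, 2), c(1, 2, 3)), "paired")
    expect_error(noiseDecomposition(1, 1), "at least 2")
    expect_error(noiseDecomposition(c(0, 0), c(1, 2)), "positive")
})

test_that("eta_tot^2 = eta_int^2 + signed eta_ext^2 on every sample", {
    set.seed(99)
    for (case in 1:100) {
        n <- sample(2:50, 1)
        g <- rlnorm(n, 0, runif(1, 0.1, 1))
        c_ <- rlnorm(n, 0, runif(1, 0.1, 1))
        ne <- noiseDecomposition(g, c_)
        resid <- etaTot(ne)^2 -
            (etaInt(ne)^2 + etaExt(ne, signed_sq = TRUE))
        expect_lt(abs(resid) / max(etaTot(ne)^2, .Machine$double.eps),
            1e-10)
    }
})

test_that("noise components are invariant to a common positive rescaling", {
    set.seed(3)
    g <- rlnorm(500, 0, 0.5); c_ <- rlnorm(500, 0, 0.5)
    a <- noiseDecomposition(g, c_)
    b <- noiseDecomposition(13.7 * g, 13.7 * c_)
    expect_equal(etaInt(b), etaInt(a), tolerance = 1e-12)
    expect_equal(etaExt(b), etaExt(a), tolerance = 1e-12)
    expect_equal(etaTot(b), etaTot(a), tolerance = 1e-12)
})

test_that("estimators converge to the generative closed forms", {
    s <- simulateDualReporter(5e4, sigma_E = 0.5164, sigma_I = 0.4542,
        seed = 17)
    ne <- noiseDecomposition(s$g, s$c)
    expect_lt(abs(etaExt(ne) - s$eta_ext_true), 0.01)
    expect_lt(abs(etaInt(ne) - s$eta_int_true), 0.01)
})

test_that("bootstrap is seeded, consistent, and exact on constant data", {
    # constant sample: every resample equals the original, boot mean =
    # point estimate, boot SD = 0
    const <- bootstrapNoise(rep(2, 10), rep(2, 10), n_boot = 20, seed = 1)
    expect_equal(unname(bootMean(const)),
        c(etaInt(const), etaExt(const), etaTot(const)))
    expect_true(all(bootSD(const) == 0))

    s <- simulateDualReporter(1e4, 0.4, 0.3, seed = 5)
    b1 <- bootstrapNoise(s$g, s$c, n_boot = 200, seed = 8)
    b2 <- bootstrapNoise(s$g, s$c, n_boot = 200, seed = 8)
    expect_identical(bootSD(b1), bootSD(b2))
    expect_identical(bootMean(b1), bootMean(b2))
    expect_equal(b1@n_boot, 200L)
    # bootstrap mean close to the point estimate at this n
    expect_lt(abs(bootMean(b1)[["eta_int"]] - etaInt(b1)), 0.02)
    expect_lt(abs(bootMean(b1)[["eta_tot"]] - etaTot(b1)), 0.02)
    # different seed moves the resampling
    b3 <- bootstrapNoise(s$g, s$c, n_boot = 200, seed = 9)
    expect_false(identical(bootSD(b1), bootSD(b3)))
})

test_that("quadrature helper matches the exact identity", {
    expect_equal(totalNoiseFromComponents(0.3, 0.4), 0.5)
    ne <- noiseDecomposition(c(1, 2, 4), c(2, 1, 5))
    if (etaExt(ne, signed_sq = TRUE) >= 0)
        expect_equal(totalNoiseFromComponents(etaInt(ne), etaExt(ne)),
            etaTot(ne), tolerance = 1e-12)
})
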