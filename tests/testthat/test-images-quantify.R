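test_that("rendering honours background, interior means and clipping", {
    # zero cells: pure background, mask all zero
    r0 <- renderImages(numeric(), image_shape = c(64, 64),
        background_mean = 10, background_sd = 2, seed = 1)
    expect_length(r0$images, 1)
    expect_true(all(r0$masks[[1]] == 0L))
    expect_lt(abs(mean(r0$images[[1]]) - 10), 0.5)

    # one cell at 200 on background 10: interior mean ~ 200 (shot noise)
    r1 <- renderImages(200, image_shape = c(64, 64), cells_per_image = 1,
        background_mean = 10, seed = 2)
    inside <- r1$masks[[1]] == 1L
    expect_gt(sum(inside), 10)
    expect_lt(abs(mean(r1$images[[1]][inside]) - 200),
        4 * sqrt(200) / sqrt(sum(inside)) + 1)

    # 8-bit clipping: a 300-value cell renders entirely <= 255
    r2 <- renderImages(300, image_shape = c(64, 64), cells_per_image = 1,
        bit_depth = 8, seed = 3)
    expect_true(all(r2$images[[1]] <= 255))
    expect_true(all(r2$images[[1]][r2$masks[[1]] == 1L] <= 255))

    # deterministic placement and pixels given seed
    ra <- renderImages(c(50, 90), image_shape = c(64, 64), seed = 11)
    rb <- renderImages(c(50, 90), image_shape = c(64, 64), seed = 11)
    expect_identical(ra$images, rb$images)
    expect_identical(ra$placements, rb$placements)

    # impossible placement errors out reporting the achievable count
    expect_error(
        renderImages(rep(100, 50), image_shape = c(20, 20),
            cells_per_image = 50, cell_radius_range = c(4, 6), seed = 1,
            max_retries = 20),
        "could not place")
})

test_that("ASCII PGM round-trips integer images", {
    img <- matrix(sample(0:255, 30 * 20, replace = TRUE), 30, 20)
    f <- withr::local_tempfile(fileext = ".pgm")
    writePGM(img, f)
    back <- readPGM(f)
    expect_identical(dim(back), dim(img))
    expect_equal(back, matrix(as.numeric(img), 30, 20))
    expect_error(readPGM(withr::local_tempfile(lines = "P5 2 2 255")),
        "P2")
})

test_that("segmentation recovers synthetic cells and ignores blank images", {
    # blank/constant image: zero objects, not an error
    expect_identical(max(segmentObjects(matrix(7, 32, 32))), 0L)
    expect_error(segmentObjects(array(1, c(4, 4, 2))), "matrix")

    # 50 bright cells, default pipeline: 50 +/- 2 objects, each overlapping
    # its ground-truth label by >= 70%
    set.seed(20)
    vals <- runif(50, 60, 240)
    r <- renderImages(vals, image_shape = c(256, 256),
        cells_per_image = 13, background_mean = 10, background_sd = 2,
        seed = 21)
    found <- 0L
    matched <- list()
    for (i in seq_along(r$images)) {
        seg <- segmentObjects(r$images[[i]])
        found <- found + max(seg)
        matched[[i]] <- match_objects(r$images[[i]], seg, r$masks[[i]])
    }
    matched <- do.call(rbind, matched)
    expect_lte(abs(found - 50L), 2L)
    expect_true(all(matched$overlap >= 0.7))

    # measured AGVs track ground truth closely
    expect_gt(cor(vals[matched$truth_label], matched$measured_raw), 0.98)
})

test_that("AGV measurement subtracts background and flags saturation", {
    # uniform object on uniform background: agv exact
    img <- matrix(10, 40, 40)
    img[10:14, 10:14] <- 200
    mask <- matrix(0L, 40, 40)
    mask[10:14, 10:14] <- 1L
    rec <- measureAGV(img, mask)
    expect_equal(rec$raw_agv, 200)
    expect_equal(rec$agv, 190)
    expect_equal(rec$area, 25L)
    expect_false(rec$saturated)

    # background estimate: median of Gaussian noise within 10 +/- 0.1
    set.seed(5)
    noise <- matrix(rnorm(120 * 120, 10, 2), 120, 120)
    rec2 <- measureAGV(noise, mask = {
        m <- matrix(0L, 120, 120); m[1:3, 1:3] <- 1L; m
    })
    expect_lt(abs(rec2$background - 10), 0.1)

    # saturated object: flag set, corrected AGV bounded by 255 - background
    img3 <- matrix(10, 40, 40)
    img3[5:9, 5:9] <- 255
    mask3 <- matrix(0L, 40, 40); mask3[5:9, 5:9] <- 1L
    rec3 <- measureAGV(img3, mask3)
    expect_true(rec3$saturated)
    expect_lte(rec3$agv, 255 - rec3$background)

    # empty label set: empty output
    expect_identical(nrow(measureAGV(img, matrix(0L, 40, 40))), 0L)
    expect_error(measureAGV(img, matrix(0L, 2, 2)), "aligned")
})

test_that("quantification is invariant to a uniform intensity offset", {
    set.seed(9)
    r <- renderImages(c(80, 150, 220), image_shape = c(96, 96),
        cells_per_image = 3, seed = 10)
    img <- r$images[[1]]
    seg <- segmentObjects(img)
    base <- measureAGV(img, seg)
    shifted <- measureAGV(img + 17, seg)
    expect_equal(shifted$agv, base$agv, tolerance = 1e-12)
})
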