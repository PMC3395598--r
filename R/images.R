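#' Render cells as synthetic grayscale micrographs with ground-truth masks
#'
#' Emulates epifluorescence image acquisition: each cell is drawn as a
#' randomly oriented ellipse whose interior pixel mean equals the cell's
#' channel value before clipping (pixels carry shot noise with SD
#' \eqn{\sqrt{value}}); background pixels are
#' \eqn{N(background\_mean, background\_sd)}; all pixels are clipped to the
#' sensor range. Placement is non-overlapping (disjoint bounding boxes) and
#' deterministic given \code{seed}.
#'
#' @param cells a \linkS4class{FluorCellSet} (values taken from
#'   \code{channel}) or a plain numeric vector of cell intensities.
#' @param channel channel to render when \code{cells} is a
#'   \linkS4class{FluorCellSet}.
#' @param image_shape integer \code{c(rows, cols)} of each image.
#' @param cells_per_image number of cells placed per image (the last image
#'   may hold fewer).
#' @param cell_radius_range range of ellipse half-axes, pixels.
#' @param background_mean,background_sd camera background (gray levels).
#' @param bit_depth sensor bit depth (8 or 16).
#' @param seed RNG seed for placement and pixel noise.
#' @param max_retries placement attempts per cell before giving up.
#' @return list with \code{images} (list of numeric matrices), \code{masks}
#'   (integer label matrices; label = index into \code{placements}), and
#'   \code{placements} (data.frame: cell, image, center, axes, angle, value).
#' @examples
#' r <- renderImages(c(120, 200, 80), image_shape = c(64, 64),
#'     cells_per_image = 3, seed = 1)
#' range(r$images[[1]])
#' @export
renderImages <- function(cells, channel = "egfp", image_shape = c(192, 192),
        cells_per_image = 25, cell_radius_range = c(3, 6),
        background_mean = 10, background_sd = 2, bit_depth = 8,
        seed = NULL, max_retries = 500) {
    values <- if (is(cells, "FluorCellSet")) agv(cells, channel)
        else as.numeric(cells)
    if (any(!is.finite(values)) || any(values < 0))
        stop("cell values must be finite and non-negative", call. = FALSE)
    stopifnot(length(image_shape) == 2L, all(image_shape >= 8))
    cells_per_image <- check_count(cells_per_image, "cells_per_image")
    stopifnot(length(cell_radius_range) == 2L,
        all(cell_radius_range >= 1),
        diff(cell_radius_range) >= 0)
    if (2 * max(cell_radius_range) + 2 >= min(image_shape))
        stop("image_shape too small for the requested cell radii",
            call. = FALSE)
    smax <- sensor_max(check_count(bit_depth, "bit_depth"))

    n <- length(values)
    n_images <- if (n == 0L) 1L else ceiling(n / cells_per_image)
    nr <- image_shape[1]; nc <- image_shape[2]

    with_seed(seed, {
        images <- vector("list", n_images)
        masks <- vector("list", n_images)
        placements <- vector("list", n)
        idx <- 0L
        for (im in seq_len(n_images)) {
            img <- matrix(rnorm(nr * nc, background_mean, background_sd),
                nr, nc)
            mask <- matrix(0L, nr, nc)
            occupied <- matrix(FALSE, nr, nc)  # dilated bounding boxes
            take <- if (n == 0L) integer() else
                seq.int(idx + 1L, min(idx + cells_per_image, n))
            for (ci in take) {
                placed <- FALSE
                for (try in seq_len(max_retries)) {
                    a <- runif(1, cell_radius_range[1], cell_radius_range[2])
                    b <- runif(1, cell_radius_range[1], cell_radius_range[2])
                    phi <- runif(1, 0, pi)
                    r_ext <- ceiling(max(a, b)) + 1L
                    cy <- sample.int(nr - 2L * r_ext, 1L) + r_ext
                    cx <- sample.int(nc - 2L * r_ext, 1L) + r_ext
                    rows <- (cy - r_ext):(cy + r_ext)
                    cols <- (cx - r_ext):(cx + r_ext)
                    if (any(occupied[rows, cols])) next
                    # interior pixels of the rotated ellipse
                    dy <- rep(rows - cy, times = length(cols))
                    dx <- rep(cols - cx, each = length(rows))
                    u <- (dx * cos(phi) + dy * sin(phi)) / a
                    v <- (-dx * sin(phi) + dy * cos(phi)) / b
                    inside <- u * u + v * v <= 1
                    px_r <- rep(rows, times = length(cols))[inside]
                    px_c <- rep(cols, each = length(rows))[inside]
                    pix <- cbind(px_r, px_c)
                    val <- values[ci]
                    img[pix] <- val + rnorm(nrow(pix), 0, sqrt(max(val, 1)))
                    mask[pix] <- ci
                    occupied[rows, cols] <- TRUE
                    placements[[ci]] <- data.frame(cell = ci, image = im,
                        row = cy, col = cx, a = a, b = b, phi = phi,
                        value = val)
                    placed <- TRUE
                    break
                }
                if (!placed)
                    stop(sprintf(paste0("could not place cell %d without ",
                        "overlap after %d retries (placed %d of %d)"),
                        ci, max_retries, ci - 1L, n), call. = FALSE)
            }
            idx <- idx + length(take)
            images[[im]] <- pmin(pmax(img, 0), smax)
            masks[[im]] <- mask
        }
        list(images = images, masks = masks,
            placements = do.call(rbind, placements))
    })
}

#' Read and write plain-text PGM (P2) grayscale images
#'
#' Minimal ASCII PGM support used to serialize synthetic micrographs as
#' plain text; pixel values are rounded to integers on write.
#'
#' @param x numeric matrix of pixel values.
#' @param path file path.
#' @param maxval maximum gray value declared in the header.
#' @return \code{readPGM} returns a numeric matrix; \code{writePGM} returns
#'   \code{path} invisibly.
#' @examples
#' f <- tempfile(fileext = ".pgm")
#' writePGM(matrix(0:24, 5, 5), f, maxval = 255)
#' readPGM(f)[1, 1]
#' @export
writePGM <- function(x, path, maxval = 255) {
    stopifnot(is.matrix(x))
    vals <- round(pmin(pmax(x, 0), maxval))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(ncol(x), nrow(x)), as.character(maxval)), con)
    # row-major pixel order, one image row per line
    writeLines(apply(vals, 1L, paste, collapse = " "), con)
    invisible(path)
}

#' @rdname writePGM
#' @export
readPGM <- function(path) {
    toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
    if (length(toks) < 4L || toks[1] != "P2")
        stop("not an ASCII PGM (P2) file: ", path, call. = FALSE)
    nc <- as.integer(toks[2]); nr <- as.integer(toks[3])
    vals <- as.numeric(toks[-(1:4)])
    if (length(vals) != nr * nc)
        stop("PGM pixel count mismatch in ", path, call. = FALSE)
    matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
}
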