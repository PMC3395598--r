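#' Read and write per-cell record tables (CSV)
#'
#' The interchange format for per-cell measurements: a CSV with required
#' columns \code{cell_id}, \code{image_id}, \code{replicate},
#' \code{channel}, \code{raw_agv}; any further columns are preserved.
#'
#' @param path CSV file path.
#' @return \code{readCellTable} returns a data.frame (zero rows for an
#'   empty file with a header); \code{writeCellTable} returns \code{path}
#'   invisibly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' df <- data.frame(cell_id = "c1", image_id = "i1", replicate = "r1",
#'     channel = "egfp", raw_agv = 42)
#' writeCellTable(df, f)
#' readCellTable(f)
#' @export
readCellTable <- function(path) {
    required <- c("cell_id", "image_id", "replicate", "channel", "raw_agv")
    df <- read.csv(path, stringsAsFactors = FALSE)
    missing <- setdiff(required, names(df))
    if (length(missing))
        stop("missing required column(s): ", paste(missing, collapse = ", "),
            call. = FALSE)
    if (nrow(df)) {
        agv_num <- suppressWarnings(as.numeric(df$raw_agv))
        bad <- which(is.na(agv_num) & !is.na(df$raw_agv))
        if (length(bad))
            stop(sprintf("non-numeric raw_agv in row %d ('%s')", bad[1],
                df$raw_agv[bad[1]]), call. = FALSE)
        df$raw_agv <- agv_num
    } else {
        df$raw_agv <- as.numeric(df$raw_agv)
    }
    df
}

#' @rdname readCellTable
#' @param df data.frame holding at least the required columns.
#' @export
writeCellTable <- function(df, path) {
    required <- c("cell_id", "image_id", "replicate", "channel", "raw_agv")
    missing <- setdiff(required, names(df))
    if (length(missing))
        stop("missing required column(s): ", paste(missing, collapse = ", "),
            call. = FALSE)
    write.csv(df, path, row.names = FALSE)
    invisible(path)
}

#' Long-format per-cell table of a FluorCellSet
#'
#' One row per cell and channel, in the cell-table interchange schema
#' (simulated sets carry no image provenance, so \code{image_id} is
#' \code{"simulated"}); ground-truth columns are appended when present.
#'
#' @param x a \linkS4class{FluorCellSet}.
#' @return data.frame with columns \code{cell_id}, \code{image_id},
#'   \code{replicate}, \code{channel}, \code{raw_agv}, plus truth columns.
#' @export
cellTable <- function(x) {
    stopifnot(is(x, "FluorCellSet"))
    a <- agv(x)
    cd <- as.data.frame(cellData(x))
    rows <- lapply(rownames(a), function(ch) {
        out <- data.frame(
            cell_id = colnames(a),
            image_id = "simulated",
            replicate = if ("replicate" %in% names(cd)) cd$replicate
                else "rep1",
            channel = ch,
            raw_agv = a[ch, ])
        truth <- setdiff(names(cd), c("cell_id", "replicate"))
        if (length(truth)) out <- cbind(out, cd[truth])
        out
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Read and write a pipeline run configuration (JSON)
#'
#' A run configuration is a plain named list: simulator parameters (any
#' subset of the [simulationParams()] arguments under \code{$params},
#' including \code{$params$preset}), \code{n_replicates}, \code{n_boot},
#' \code{gate} (\code{"union"}/\code{"intersection"}) and \code{seed}.
#' Configurations round-trip losslessly through JSON.
#'
#' @param config named list.
#' @param path JSON file path.
#' @return \code{readRunConfig} returns the configuration list;
#'   \code{writeRunConfig} returns \code{path} invisibly.
#' @export
writeRunConfig <- function(config, path) {
    stopifnot(is.list(config))
    jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
        pretty = TRUE)
    invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
    jsonlite::read_json(path, simplifyVector = TRUE)
}

default_config <- function() {
    list(params = list(preset = "wildtype", n_cells = 10000),
        n_replicates = 3L, n_boot = 1000L, gate = "union", seed = 1L)
}

#' Run the end-to-end analysis on simulated populations
#'
#' Composes the pipeline stages in acquisition order: simulate replicate
#' populations, build per-channel cumulative curves and breakpoints,
#' summarize subpopulations across replicates, scale/normalize and gate the
#' paired reporters, decompose noise with bootstrap uncertainty,
#' quadrant-condition activation on the simulated RpoS level, and compare
#' the per-channel subpopulation sizes. Writes per-stage CSV outputs and a
#' markdown report; fully reproducible (byte-identical) from config + seed.
#'
#' @param config configuration list (see [writeRunConfig()]); missing
#'   entries take defaults. May also be a path to a JSON config.
#' @param out_dir output directory (created if needed); \code{NULL} skips
#'   all file output.
#' @return (invisibly) a list bundle: \code{config}, \code{cells} (list of
#'   \linkS4class{FluorCellSet}), \code{breakpoints}, \code{subpop}
#'   (per-channel summary data.frame), \code{noise} (per-replicate
#'   \linkS4class{NoiseEstimate}), \code{quadrant}, \code{stats},
#'   \code{flags}.
#' @examples
#' res <- runPipeline(list(params = list(n_cells = 2000), n_boot = 50,
#'     n_replicates = 2, seed = 4), out_dir = NULL)
#' res$subpop
#' @export
runPipeline <- function(config = list(), out_dir = NULL) {
    if (is.character(config)) config <- readRunConfig(config)
    cfg <- utils::modifyList(default_config(), config)
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop(sprintf("stage '%s' failed: %s", name,
                conditionMessage(e)), call. = FALSE))
    }

    base_seed <- check_count(cfg$seed, "seed", min = -2^31 + 1)
    n_rep <- check_count(cfg$n_replicates, "n_replicates")
    channels <- c("egfp", "echerry")

    cells <- stage("simulate", {
        lapply(seq_len(n_rep), function(r) {
            pars <- cfg$params
            preset <- pars$preset %||% "wildtype"
            pars$preset <- NULL
            pars$seed <- (base_seed + r - 1L) %% .Machine$integer.max
            do.call(simulationParams, c(list(preset = preset), pars)) |>
                simulatePopulation(replicate = sprintf("rep%d", r))
        })
    })
    params1 <- S4Vectors::metadata(cells[[1]])$params

    breakpoints <- stage("breakpoint", {
        lapply(cells, function(cs)
            lapply(setNames(channels, channels), function(ch)
                findBreakpoint(cumulativeCurve(agv(cs, ch)))))
    })

    subpop <- stage("subpop_summary", {
        do.call(rbind, lapply(channels, function(ch) {
            s <- subpopulationSummary(lapply(breakpoints, `[[`, ch))
            cbind(channel = ch, s)
        }))
    })

    noise <- stage("noise", {
        lapply(seq_len(n_rep), function(r) {
            cs <- cells[[r]]
            nz <- scaleAndNormalize(agv(cs, "egfp"), agv(cs, "echerry"),
                background_g = params1@background_mean,
                background_c = params1@background_mean)
            bp_g <- findBreakpoint(cumulativeCurve(nz$g))
            bp_c <- findBreakpoint(cumulativeCurve(nz$c))
            gated <- selectActive(nz$g, nz$c, bp_g, bp_c, mode = cfg$gate,
                saturated = cs$saturated_egfp | cs$saturated_echerry)
            bootstrapNoise(gated$g, gated$c, n_boot = cfg$n_boot,
                seed = (base_seed + 1000L + r) %% .Machine$integer.max)
        })
    })

    quadrant <- stage("quadrant", {
        lapply(seq_len(n_rep), function(r) {
            cs <- cells[[r]]
            quadrantActivation(cs$R, agv(cs, "egfp"),
                threshold = breakpointAGV(breakpoints[[r]]$egfp))
        })
    })

    stats_out <- stage("stats", {
        if (n_rep >= 2L) {
            fr <- lapply(setNames(channels, channels), function(ch)
                vapply(breakpoints, function(b) fractionOn(b[[ch]]),
                    numeric(1)))
            compareGroups(fr, method = "ttest")
        } else NULL
    })

    flags <- unique(unlist(lapply(breakpoints, function(b)
        lapply(b, resultFlags))))
    bundle <- list(config = cfg, cells = cells, breakpoints = breakpoints,
        subpop = subpop, noise = noise, quadrant = quadrant,
        stats = stats_out, flags = flags)

    if (!is.null(out_dir)) {
        dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
        stage("write", write_bundle(bundle, out_dir))
    }
    invisible(bundle)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Serialize the pipeline bundle: per-stage CSVs plus a markdown report.
# All numeric formatting is explicit so identical seeds give byte-identical
# files.
write_bundle <- function(bundle, out_dir) {
    fmt <- function(x, d = 6) formatC(x, digits = d, format = "g")
    writeCellTable(do.call(rbind, lapply(bundle$cells, cellTable)),
        file.path(out_dir, "cells.csv"))
    write.csv(bundle$subpop, file.path(out_dir, "subpop.csv"),
        row.names = FALSE)

    noise_df <- do.call(rbind, lapply(seq_along(bundle$noise), function(r) {
        ne <- bundle$noise[[r]]
        data.frame(replicate = sprintf("rep%d", r), n_cells = ne@n_cells,
            eta_int = ne@eta_int, eta_ext = ne@eta_ext,
            eta_tot = ne@eta_tot,
            boot_mean_int = ne@boot_mean[["eta_int"]],
            boot_sd_int = ne@boot_sd[["eta_int"]],
            boot_mean_ext = ne@boot_mean[["eta_ext"]],
            boot_sd_ext = ne@boot_sd[["eta_ext"]],
            boot_mean_tot = ne@boot_mean[["eta_tot"]],
            boot_sd_tot = ne@boot_sd[["eta_tot"]],
            n_boot = ne@n_boot, seed = ne@seed)
    }))
    write.csv(noise_df, file.path(out_dir, "noise.csv"), row.names = FALSE)

    quad_df <- do.call(rbind, lapply(seq_along(bundle$quadrant),
        function(r) {
            q <- bundle$quadrant[[r]]
            data.frame(replicate = sprintf("rep%d", r),
                quadrant = c("Q1st", "Q2nd", "Q3rd", "Q4th"),
                count = quadrantCounts(q),
                activation_fraction = quadrantFractions(q))
        }))
    write.csv(quad_df, file.path(out_dir, "quadrant.csv"),
        row.names = FALSE)

    lines <- c("# scfluor pipeline report", "",
        sprintf("seed: %d; replicates: %d; gate: %s",
            bundle$config$seed, length(bundle$cells), bundle$config$gate),
        "", "## ON subpopulations (percent of cells, mean +/- SD)", "")
    for (i in seq_len(nrow(bundle$subpop)))
        lines <- c(lines, with(bundle$subpop[i, ], sprintf(
            "- %s: %s +/- %s %%, mean ON AGV %s +/- %s%s",
            channel, fmt(fraction_on_mean), fmt(fraction_on_sd),
            fmt(mean_on_agv_mean), fmt(mean_on_agv_sd),
            ifelse(nzchar(flags), paste0(" [", flags, "]"), ""))))
    lines <- c(lines, "", "## Noise decomposition (gated cells)", "")
    for (r in seq_along(bundle$noise)) {
        ne <- bundle$noise[[r]]
        lines <- c(lines, sprintf(
            paste0("- rep%d (n = %d): eta_int %s +/- %s, eta_ext %s +/- ",
                "%s, eta_tot %s +/- %s"),
            r, ne@n_cells,
            fmt(ne@boot_mean[["eta_int"]]), fmt(ne@boot_sd[["eta_int"]]),
            fmt(ne@boot_mean[["eta_ext"]]), fmt(ne@boot_sd[["eta_ext"]]),
            fmt(ne@boot_mean[["eta_tot"]]), fmt(ne@boot_sd[["eta_tot"]])))
    }
    lines <- c(lines, "", "## Quadrant-conditioned activation", "")
    for (r in seq_along(bundle$quadrant)) {
        f <- quadrantFractions(bundle$quadrant[[r]])
        lines <- c(lines, sprintf("- rep%d: %s", r,
            paste(sprintf("%s %s", names(f), fmt(f, 4)), collapse = ", ")))
    }
    if (length(bundle$flags))
        lines <- c(lines, "", paste("flags:",
            paste(bundle$flags, collapse = ", ")))
    writeLines(lines, file.path(out_dir, "report.md"))
    invisible(out_dir)
}
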