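setMethod("show", "SimulationParams", function(object) {
    cat("SimulationParams\n")
    cat(sprintf("  n_cells: %d  copy_number: %d  seed: %d\n",
        object@n_cells, object@copy_number, object@seed))
    cat(sprintf("  RpoS: Normal(%g x %g, %g) truncated at 0; theta = %g\n",
        object@copy_number, object@mu_R, object@sigma_R, object@theta))
    cat(sprintf("  p_act: %g  reporter: basal %g + amplitude %g\n",
        object@p_act, object@basal, object@amplitude))
    cat(sprintf("  noise shapes: sigma_E %g, sigma_I %g\n",
        object@sigma_E, object@sigma_I))
    cat(sprintf("  camera: background %g +/- %g, %d-bit (max %d)\n",
        object@background_mean, object@background_sd, object@bit_depth,
        sensor_max(object@bit_depth)))
    invisible(NULL)
})

setMethod("show", "FluorCellSet", function(object) {
    cat(sprintf("FluorCellSet: %d cells x %d channel(s) [%s]\n",
        ncol(object), nrow(object),
        paste(rownames(object), collapse = ", ")))
    truth <- intersect(c("R", "permissive", "active"),
        colnames(SummarizedExperiment::colData(object)))
    if (length(truth))
        cat("  ground truth:", paste(truth, collapse = ", "), "\n")
    if ("active" %in% truth)
        cat(sprintf("  active cells: %d (%.2f%%)\n",
            sum(object$active), 100 * mean(object$active)))
    invisible(NULL)
})

setMethod("show", "BreakpointResult", function(object) {
    cat("BreakpointResult\n")
    cat(sprintf("  breakpoint: percentile %.3f, AGV %.3f\n",
        object@breakpoint_percentile, object@breakpoint_agv))
    cat(sprintf("  ON subpopulation: %.3f%% of %d cells, mean AGV %.3f\n",
        object@fraction_on, object@n_cells, object@mean_on_agv))
    if (length(object@flags))
        cat("  flags:", paste(object@flags, collapse = ", "), "\n")
    invisible(NULL)
})

setMethod("show", "NoiseEstimate", function(object) {
    cat(sprintf("NoiseEstimate (n = %d cells)\n", object@n_cells))
    cat(sprintf("  eta_int %.4f  eta_ext %.4f  eta_tot %.4f\n",
        object@eta_int, object@eta_ext, object@eta_tot))
    if (object@n_boot > 0L) {
        cat(sprintf("  bootstrap (%d resamples, seed %s):\n", object@n_boot,
            ifelse(is.na(object@seed), "none", object@seed)))
        for (k in names(object@boot_mean))
            cat(sprintf("    %s: %.4f +/- %.4f\n", k,
                object@boot_mean[[k]], object@boot_sd[[k]]))
    }
    invisible(NULL)
})

setMethod("show", "QuadrantResult", function(object) {
    cat("QuadrantResult (reporter threshold", format(object@threshold), ")\n")
    q <- c("Q1st", "Q2nd", "Q3rd", "Q4th")
    for (i in 1:4)
        cat(sprintf("  %s: %d cells, activation fraction %s\n", q[i],
            object@counts[i], format(object@fractions[i], digits = 4)))
    invisible(NULL)
})

setMethod("show", "TransferResult", function(object) {
    cat(sprintf("TransferResult: %g transconjugant / %g donor CFU = %g\n",
        object@transconjugant_cfu, object@donor_cfu, object@frequency))
    if (length(object@flags))
        cat("  flags:", paste(object@flags, collapse = ", "), "\n")
    invisible(NULL)
})
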