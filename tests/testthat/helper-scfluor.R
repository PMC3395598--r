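# Shared fixtures, built in code.

# Two-component OFF/ON mixture with a clear intensity gap; fraction_on in
# percent of n.
make_mixture <- function(n = 1000, fraction_on = 3, off_mean = 10,
        off_sd = 1, on_mean = 200, on_sd = 10, seed = 1) {
    set.seed(seed)
    n_on <- round(n * fraction_on / 100)
    vals <- c(rnorm(n - n_on, off_mean, off_sd), rnorm(n_on, on_mean, on_sd))
    sample(vals)  # order must not matter
}

# Match segmented objects to ground-truth labels by majority mask overlap;
# returns data.frame(truth_label, seg_label, overlap, measured_raw).
match_objects <- function(image, seg, gt) {
    labs <- sort(unique(gt[gt > 0]))
    do.call(rbind, lapply(labs, function(l) {
        px <- gt == l
        hit <- table(seg[px])
        hit <- hit[names(hit) != "0"]
        if (!length(hit))
            return(data.frame(truth_label = l, seg_label = NA_integer_,
                overlap = 0, measured_raw = NA_real_))
        best <- as.integer(names(which.max(hit)))
        data.frame(truth_label = l, seg_label = best,
            overlap = max(hit) / sum(px),
            measured_raw = mean(image[seg == best]))
    }))
}
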