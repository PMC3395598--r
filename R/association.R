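#' Quadrant-conditioned activation analysis
#'
#' Cuts the conditioning-channel distribution (e.g. RpoS-mCherry intensity)
#' at its empirical mean-SD, mean and mean+SD into quadrants Q1st (minimum
#' to mean-SD), Q2nd, Q3rd and Q4th (mean+SD to maximum), and reports per
#' quadrant the fraction of cells whose reporter value is at or above
#' \code{threshold}.
#'
#' @param conditioning per-cell conditioning-channel values.
#' @param reporter paired per-cell reporter values.
#' @param threshold reporter threshold defining "expressing"; by default the
#'   breakpoint AGV of the reporter's cumulative curve.
#' @return a \linkS4class{QuadrantResult}. Empty quadrants get fraction
#'   \code{NaN} and count 0.
#' @examples
#' set.seed(1)
#' r <- rnorm(5000, 50, 10)
#' rep_on <- ifelse(r > 65, 100, 5)
#' quadrantActivation(r, rep_on, threshold = 50)
#' @export
quadrantActivation <- function(conditioning, reporter, threshold = NULL) {
    if (length(conditioning) != length(reporter))
        stop("conditioning and reporter must be paired", call. = FALSE)
    if (length(conditioning) < 4L)
        stop("need at least 4 cells", call. = FALSE)
    if (is.null(threshold))
        threshold <- breakpointAGV(findBreakpoint(cumulativeCurve(reporter)))
    check_scalar(threshold, "threshold")
    m <- mean(conditioning); s <- sd(conditioning)
    b <- c(m - s, m, m + s)
    q <- findInterval(conditioning, b) + 1L  # 1..4
    counts <- tabulate(q, 4L)
    on <- reporter >= threshold
    fractions <- vapply(1:4, function(k)
        if (counts[k] == 0L) NaN else mean(on[q == k]), numeric(1))
    new("QuadrantResult", boundaries = b, fractions = fractions,
        counts = counts, threshold = threshold)
}

#' Reporter-reporter Pearson correlation across replicates
#'
#' Pearson correlation between the paired reporters, per replicate, with
#' the across-replicate mean +/- SD ("value +/- SD across biological
#' triplicates" convention). A zero-variance channel in a replicate gives
#' \code{NA} with flag \code{"zero_variance"}.
#'
#' @param g,c paired per-cell reporter values.
#' @param replicate replicate label per cell; \code{NULL} treats all cells
#'   as a single replicate.
#' @return list with \code{per_replicate} (data.frame: replicate, n, r),
#'   \code{mean}, \code{sd}, \code{flags}.
#' @export
reporterCorrelation <- function(g, c, replicate = NULL) {
    if (length(g) != length(c))
        stop("g and c must be paired", call. = FALSE)
    if (is.null(replicate)) replicate <- rep("rep1", length(g))
    stopifnot(length(replicate) == length(g))
    reps <- unique(replicate)
    flags <- character()
    rows <- lapply(reps, function(r) {
        i <- replicate == r
        if (sum(i) < 2L)
            stop("replicate '", r, "' has fewer than 2 cells", call. = FALSE)
        if (var(g[i]) == 0 || var(c[i]) == 0) {
            flags <<- unique(c(flags, "zero_variance"))
            return(data.frame(replicate = r, n = sum(i), r = NA_real_))
        }
        data.frame(replicate = r, n = sum(i), r = cor(g[i], c[i]))
    })
    per <- do.call(rbind, rows)
    ok <- per$r[!is.na(per$r)]
    list(per_replicate = per,
        mean = if (length(ok)) mean(ok) else NA_real_,
        sd = if (length(ok) > 1L) sd(ok) else 0,
        flags = flags)
}

#' Conjugative transfer frequency
#'
#' @param transconjugant_cfu,donor_cfu colony-forming-unit counts; the
#'   frequency is transconjugants per donor. Zero transconjugants give
#'   frequency 0 with a \code{"detection_limit"} flag.
#' @return a \linkS4class{TransferResult}.
#' @examples
#' transferFreq(transferFrequency(50, 1e9))   # 5e-08
#' @export
transferFrequency <- function(transconjugant_cfu, donor_cfu) {
    check_scalar(transconjugant_cfu, "transconjugant_cfu", min = 0)
    check_scalar(donor_cfu, "donor_cfu")
    if (donor_cfu <= 0)
        stop("donor_cfu must be > 0", call. = FALSE)
    flags <- if (transconjugant_cfu == 0) "detection_limit" else character()
    new("TransferResult", donor_cfu = donor_cfu,
        transconjugant_cfu = transconjugant_cfu,
        frequency = transconjugant_cfu / donor_cfu, flags = flags)
}

#' Compare groups by ANOVA/Tukey or pairwise t-test
#'
#' One-way ANOVA followed by Tukey's HSD post-hoc test, with a compact
#' letter display at \code{alpha} (groups sharing a letter are not
#' significantly different) — the "(A)/(B)" annotation convention of
#' replicate summary tables. \code{method = "ttest"} performs the pairwise
#' homoscedastic t-test between exactly two groups.
#'
#' @param groups named list of numeric vectors (>= 2 values each for
#'   ANOVA).
#' @param method \code{"tukey"} or \code{"ttest"}.
#' @param alpha significance level for the letter display.
#' @return for \code{"tukey"}: list with \code{anova_p}, \code{f},
#'   \code{pairwise} (data.frame: group1, group2, p), \code{letters} (named
#'   character). For \code{"ttest"}: list with \code{p}.
#' @examples
#' compareGroups(list(a = c(1, 2, 3), b = c(1.1, 2.1, 3.1),
#'     d = c(10, 11, 12)))$letters
#' @export
compareGroups <- function(groups, method = c("tukey", "ttest"),
        alpha = 0.05) {
    method <- match.arg(method)
    stopifnot(is.list(groups), !is.null(names(groups)),
        all(nzchar(names(groups))))
    sizes <- lengths(groups)
    if (method == "ttest") {
        if (length(groups) != 2L)
            stop("ttest mode needs exactly 2 groups", call. = FALSE)
        if (any(sizes < 2L))
            stop("each group needs >= 2 values", call. = FALSE)
        p <- t.test(groups[[1]], groups[[2]], var.equal = TRUE)$p.value
        return(list(method = "ttest", p = p))
    }
    if (length(groups) < 2L)
        stop("need >= 2 groups", call. = FALSE)
    if (any(sizes < 2L))
        stop("each group needs >= 2 values for ANOVA", call. = FALSE)
    df <- data.frame(
        value = unlist(groups, use.names = FALSE),
        group = factor(rep(names(groups), sizes)))
    fit <- aov(value ~ group, data = df)
    an <- anova(fit)
    tk <- TukeyHSD(fit)$group
    pair_names <- strsplit(rownames(tk), "-", fixed = TRUE)
    pairwise <- data.frame(
        group1 = vapply(pair_names, `[`, character(1), 1L),
        group2 = vapply(pair_names, `[`, character(1), 2L),
        p = tk[, "p adj"])
    rownames(pairwise) <- NULL
    list(method = "tukey",
        anova_p = an[["Pr(>F)"]][1], f = an[["F value"]][1],
        pairwise = pairwise,
        letters = compactLetters(pairwise, names(groups), alpha))
}

#' Compact letter display from a pairwise p-value table
#'
#' Insert-and-absorb letter assignment: starting from one set holding all
#' groups, every significant pair splits the sets containing both members;
#' subset sets are absorbed. Groups sharing a letter are not significantly
#' different at \code{alpha}. The resulting partition is independent of the
#' order in which groups are supplied (pairs are processed in canonical
#' sorted order, letters assigned by sorted group name).
#'
#' @param pairwise data.frame with columns \code{group1}, \code{group2},
#'   \code{p}.
#' @param group_names all group names.
#' @param alpha significance level.
#' @return named character vector of letter strings, in \code{group_names}
#'   order.
#' @export
compactLetters <- function(pairwise, group_names, alpha = 0.05) {
    canonical <- sort(group_names)
    sets <- list(canonical)
    sig <- pairwise[!is.na(pairwise$p) & pairwise$p < alpha, , drop = FALSE]
    if (nrow(sig)) {
        key <- paste(pmin(sig$group1, sig$group2),
            pmax(sig$group1, sig$group2))
        sig <- sig[order(key), , drop = FALSE]
    }
    for (r in seq_len(nrow(sig))) {
        a <- sig$group1[r]; b <- sig$group2[r]
        new_sets <- list()
        for (s in sets) {
            if (a %in% s && b %in% s)
                new_sets <- c(new_sets, list(setdiff(s, a)),
                    list(setdiff(s, b)))
            else new_sets <- c(new_sets, list(s))
        }
        # absorb: drop sets contained in another set
        new_sets <- unique(lapply(new_sets, sort))
        keep <- vapply(seq_along(new_sets), function(i)
            !any(vapply(seq_along(new_sets), function(j)
                i != j && all(new_sets[[i]] %in% new_sets[[j]]) &&
                    (length(new_sets[[i]]) < length(new_sets[[j]]) || i > j),
                logical(1))), logical(1))
        sets <- new_sets[keep]
    }
    # stable ordering of sets by their first (sorted) member
    sets <- sets[order(vapply(sets, function(s)
        match(s[1], canonical), integer(1)))]
    out <- setNames(rep("", length(group_names)), group_names)
    for (i in seq_along(sets))
        for (gname in sets[[i]])
            out[gname] <- paste0(out[gname], letters[i])
    out
}
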