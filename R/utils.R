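# Internal helpers: seeded evaluation and argument checks.

# Evaluate `code` under set.seed(seed), restoring the caller's RNG state.
# seed = NULL leaves the RNG stream untouched.
with_seed <- function(seed, code) {
    if (is.null(seed)) return(force(code))
    if (!is.finite(seed)) stop("seed must be a finite number", call. = FALSE)
    env <- globalenv()
    had <- exists(".Random.seed", envir = env, inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
    on.exit({
        if (had) assign(".Random.seed", old, envir = env)
        else if (exists(".Random.seed", envir = env, inherits = FALSE))
            rm(".Random.seed", envir = env)
    })
    set.seed(as.integer(seed))
    force(code)
}

check_scalar <- function(x, name, min = -Inf, max = Inf) {
    if (length(x) != 1L || !is.numeric(x) || !is.finite(x))
        stop(sprintf("'%s' must be a single finite number", name),
            call. = FALSE)
    if (x < min || x > max)
        stop(sprintf("'%s' must be in [%s, %s] (got %s)", name,
            format(min), format(max), format(x)), call. = FALSE)
    invisible(x)
}

check_prob <- function(x, name) check_scalar(x, name, 0, 1)

check_count <- function(x, name, min = 1L) {
    check_scalar(x, name, min = min)
    if (x != as.integer(x))
        stop(sprintf("'%s' must be a whole number", name), call. = FALSE)
    invisible(as.integer(x))
}

# Sensor maximum for a given bit depth.
sensor_max <- function(bit_depth) 2^bit_depth - 1
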