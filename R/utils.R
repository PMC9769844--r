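# Internal helpers.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so simulation calls never leak global state.
withSeed <- function(seed, expr) {
    if (!is.null(seed)) {
        if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
            stop("'seed' must be a single finite number")
        has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
        if (has) {
            old <- get(".Random.seed", envir = globalenv())
            on.exit(assign(".Random.seed", old, envir = globalenv()))
        } else {
            on.exit(rm(".Random.seed", envir = globalenv()))
        }
        set.seed(as.integer(seed))
    }
    force(expr)
}

# 1-based index of the window containing genomic position x.
windowIndex <- function(x, window, nWindows) {
    i <- floor(x / window) + 1L
    i <- pmin(pmax(i, 1L), nWindows)
    as.integer(i)
}
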