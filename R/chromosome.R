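#' Replication time of a genomic position
#'
#' Under synchronous origin firing with forks that annihilate where they
#' meet, the time at which position `x` is replicated is the minimum over
#' origins of the shorter circular arc to `x` divided by the fork speed.
#' The function is continuous and piecewise linear in `x`, zero exactly at
#' every origin, and maximal at fork-meeting points.
#'
#' @param spec a [ChromosomeSpec-class].
#' @param x genomic position(s) in bp, each in `[0, genome length)`.
#' @return replication time(s) in minutes.
#' @examples
#' spec <- ChromosomeSpec(4e6, origins = 0, forkSpeed = 1000)
#' replicationTime(spec, c(0, 2e6))
#' @export
replicationTime <- function(spec, x) {
    stopifnot(is(spec, "ChromosomeSpec"))
    if (any(!is.finite(x)) || any(x < 0) || any(x >= spec@length))
        stop("positions must lie in [0, genome length)")
    L <- spec@length
    d <- vapply(x, function(xi) {
        a <- abs(xi - spec@origins)
        min(pmin(a, L - a))
    }, numeric(1))
    d / spec@forkSpeed
}

#' Maximum replication time (C period) of a chromosome
#'
#' The time at which the last locus is replicated: half the largest arc
#' between adjacent origins, divided by the fork speed.  For a single
#' origin this is the classical C period `(L/2)/v`.
#'
#' @param spec a [ChromosomeSpec-class].
#' @return time in minutes.
#' @export
maxReplicationTime <- function(spec) {
    stopifnot(is(spec, "ChromosomeSpec"))
    o <- sort(spec@origins)
    gaps <- if (length(o) == 1L) spec@length
            else c(diff(o), spec@length - (o[length(o)] - o[1L]))
    max(gaps) / 2 / spec@forkSpeed
}

.dupMultiplier <- function(spec, x) {
    m <- rep(1, length(x))
    if (length(spec@duplication) == 3L) {
        s <- spec@duplication[1L]; e <- spec@duplication[2L]
        mul <- spec@duplication[3L]
        inside <- if (s <= e) x >= s & x < e else x >= s | x < e
        m[inside] <- mul
    }
    m
}

#' Expected steady-state copy number of a genomic position
#'
#' In an exponentially growing culture with doubling time `tau`, the
#' expected relative copy number of a locus replicated at time `t(x)` is
#' `2^((tmax - t(x)) / tau)`, where `tmax` is the replication time of the
#' last-replicated locus: loci near an origin are present in more cells
#' of the (age-structured) population than loci near the terminus, and the
#' ori/ter ratio equals `2^(C/tau)`.  A segmental duplication multiplies
#' the copy number of the affected interval.
#'
#' Only ratios of copy numbers are meaningful; the returned scale anchors
#' the latest-replicated locus at 1.
#'
#' @param spec a [ChromosomeSpec-class].
#' @param x genomic position(s) in bp.
#' @return relative copy number(s).
#' @examples
#' # single origin with C = tau: ori/ter ratio is exactly 2
#' spec <- ChromosomeSpec(4.6e6, 2.3e6, forkSpeed = 30000,
#'                        doublingTime = 2.3e6 / 2 / 30000)
#' expectedCopyNumber(spec, 2.3e6) / expectedCopyNumber(spec, 0)
#' @export
expectedCopyNumber <- function(spec, x) {
    t <- replicationTime(spec, x)
    tmax <- maxReplicationTime(spec)
    .dupMultiplier(spec, x) * 2^((tmax - t) / spec@doublingTime)
}

#' Analytic noiseless copy-number profile
#'
#' Evaluates [expectedCopyNumber()] at every window midpoint and normalizes
#' to a [NormalizedProfile-class].  This is the infinite-read-depth limit
#' of [simulateCoverage()] followed by [normalizeCoverage()].
#'
#' @param spec a [ChromosomeSpec-class].
#' @param window window width in bp (default 1000).
#' @return a [NormalizedProfile-class].
#' @export
expectedProfile <- function(spec, window = 1000) {
    nw <- ceiling(spec@length / window)
    st <- seq(0, by = window, length.out = nw)
    en <- pmin(st + window, spec@length)
    c0 <- expectedCopyNumber(spec, (st + en) / 2)
    new("NormalizedProfile", genomeLength = spec@length,
        window = as.numeric(window), values = c0 / sum(c0))
}
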