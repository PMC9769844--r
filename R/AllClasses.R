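#' @import methods
NULL

# ---------------------------------------------------------------------------
# ChromosomeSpec
# ---------------------------------------------------------------------------

#' Circular chromosome with one or more replication origins
#'
#' `ChromosomeSpec` describes the replication geometry of a circular
#' bacterial chromosome growing at steady state: its length, the positions
#' of its replication origins, the replication-fork speed, the culture
#' doubling time, and optionally a segmental duplication carried by (part
#' of) the population.  It is the ground-truth object behind the analytic
#' copy-number landscape and the coverage simulator.
#'
#' All origins are assumed to fire synchronously once per cell cycle and
#' forks annihilate where they meet, so the replication time of a locus is
#' the minimum over origins of the shorter circular arc distance divided by
#' the fork speed.
#'
#' @slot length chromosome length in bp.
#' @slot origins 0-based origin positions in bp, all in `[0, length)`.
#' @slot forkSpeed replication fork speed in bp/min.
#' @slot doublingTime culture doubling time in minutes.
#' @slot duplication numeric of length 0 (no duplication) or 3:
#'   `c(start, end, multiplier)`, a half-open interval in bp (wrap around
#'   the origin of coordinates is allowed, i.e. `start > end`) whose copy
#'   number is multiplied by `multiplier`.
#'
#' @seealso [replicationTime()], [expectedCopyNumber()], [simulateCoverage()]
#' @export
setClass("ChromosomeSpec",
    representation(
        length = "numeric",
        origins = "numeric",
        forkSpeed = "numeric",
        doublingTime = "numeric",
        duplication = "numeric"
    )
)

setValidity("ChromosomeSpec", function(object) {
    msg <- character()
    L <- object@length
    if (length(L) != 1L || !is.finite(L) || L <= 0)
        msg <- c(msg, "'length' must be a single positive finite number")
    if (length(object@origins) < 1L)
        msg <- c(msg, "at least one origin is required")
    else {
        if (any(!is.finite(object@origins)) ||
            any(object@origins < 0) || any(object@origins >= L))
            msg <- c(msg, "origins must lie in [0, length)")
        if (anyDuplicated(object@origins))
            msg <- c(msg, "origins must be distinct")
    }
    if (length(object@forkSpeed) != 1L || !is.finite(object@forkSpeed) ||
        object@forkSpeed <= 0)
        msg <- c(msg, "'forkSpeed' must be a single positive finite number")
    if (length(object@doublingTime) != 1L ||
        !is.finite(object@doublingTime) || object@doublingTime <= 0)
        msg <- c(msg, "'doublingTime' must be a single positive finite number")
    dup <- object@duplication
    if (!length(dup) %in% c(0L, 3L))
        msg <- c(msg, "'duplication' must be numeric(0) or c(start, end, multiplier)")
    if (length(dup) == 3L) {
        if (any(!is.finite(dup)))
            msg <- c(msg, "duplication values must be finite")
        else {
            if (dup[1L] < 0 || dup[1L] >= L || dup[2L] < 0 || dup[2L] > L)
                msg <- c(msg, "duplication interval must lie within [0, length)")
            if (dup[3L] < 1)
                msg <- c(msg, "duplication multiplier must be >= 1")
        }
    }
    if (length(msg)) msg else TRUE
})

#' Construct a ChromosomeSpec
#'
#' @param length chromosome length in bp.
#' @param origins numeric vector of 0-based origin positions in bp.
#' @param forkSpeed fork speed in bp/min.  The default, 30 kb/min
#'   (500 nt/s), is within the range reported for *E. coli* growing on
#'   minimal medium.
#' @param doublingTime culture doubling time in minutes (default 67 min,
#'   a typical M9-glucose doubling time).
#' @param duplication optional `c(start, end, multiplier)` in bp; the
#'   half-open interval `[start, end)` has its copy number multiplied by
#'   `multiplier`.  `start > end` wraps around the coordinate origin.
#'
#' @return A [ChromosomeSpec-class] object.
#' @examples
#' spec <- ChromosomeSpec(4.6e6, origins = 2.3e6)
#' expectedCopyNumber(spec, c(0, 2.3e6))
#' @export
ChromosomeSpec <- function(length, origins, forkSpeed = 30000,
                           doublingTime = 67, duplication = numeric(0)) {
    if (is.null(duplication)) duplication <- numeric(0)
    new("ChromosomeSpec",
        length = as.numeric(length),
        origins = as.numeric(sort(origins)),
        forkSpeed = as.numeric(forkSpeed),
        doublingTime = as.numeric(doublingTime),
        duplication = as.numeric(duplication))
}

setMethod("show", "ChromosomeSpec", function(object) {
    cat("ChromosomeSpec of", object@length, "bp with",
        length(object@origins), "origin(s)\n")
    cat("  origins:", paste(format(object@origins, big.mark = ","),
                            collapse = ", "), "\n")
    cat("  fork speed:", object@forkSpeed, "bp/min; doubling time:",
        object@doublingTime, "min (C/tau =",
        round(maxReplicationTime(object) / object@doublingTime, 3), ")\n")
    if (length(object@duplication) == 3L)
        cat("  duplication: [", object@duplication[1L], ",",
            object@duplication[2L], ") x", object@duplication[3L], "\n")
})

# ---------------------------------------------------------------------------
# WindowedCoverage / NormalizedProfile
# ---------------------------------------------------------------------------

#' Windowed genome coverage
#'
#' Mean per-base sequencing coverage in consecutive fixed-width windows
#' along a chromosome (0-based, half-open; the last window may be short).
#'
#' @slot genomeLength chromosome length in bp.
#' @slot window window width in bp.
#' @slot values mean per-base coverage per window, ordered by window start.
#' @seealso [normalizeCoverage()], [simulateCoverage()]
#' @export
setClass("WindowedCoverage",
    representation(genomeLength = "numeric", window = "numeric",
                   values = "numeric"))

#' Normalized copy-number profile
#'
#' Windowed coverage divided by the total coverage mapped to the genome, so
#' that the values sum to one and are directly comparable between samples.
#'
#' @slot genomeLength chromosome length in bp.
#' @slot window window width in bp.
#' @slot values normalized copy number per window (sums to 1).
#' @seealso [normalizeCoverage()], [loessSmooth()]
#' @export
setClass("NormalizedProfile",
    representation(genomeLength = "numeric", window = "numeric",
                   values = "numeric"))

.validTrack <- function(object) {
    msg <- character()
    nw <- ceiling(object@genomeLength / object@window)
    if (length(object@genomeLength) != 1L || object@genomeLength <= 0)
        msg <- c(msg, "'genomeLength' must be a single positive number")
    if (length(object@window) != 1L || object@window <= 0)
        msg <- c(msg, "'window' must be a single positive number")
    if (length(object@values) != nw)
        msg <- c(msg, sprintf("'values' must have ceiling(genomeLength/window) = %d elements", nw))
    if (any(!is.finite(object@values)) || any(object@values < 0))
        msg <- c(msg, "'values' must be finite and non-negative")
    if (length(msg)) msg else TRUE
}
setValidity("WindowedCoverage", .validTrack)
setValidity("NormalizedProfile", .validTrack)

#' @rdname WindowedCoverage-class
#' @param values mean per-base coverage per window.
#' @param window window width in bp.
#' @param genomeLength chromosome length in bp; defaults to
#'   `length(values) * window`.
#' @return `WindowedCoverage()` returns a [WindowedCoverage-class] object.
#' @export
WindowedCoverage <- function(values, window = 1000,
                             genomeLength = length(values) * window) {
    new("WindowedCoverage", genomeLength = as.numeric(genomeLength),
        window = as.numeric(window), values = as.numeric(values))
}

.showTrack <- function(object) {
    cat(class(object), "over", format(object@genomeLength, big.mark = ","),
        "bp in", length(object@values), "windows of", object@window, "bp\n")
    cat("  value range: [", format(min(object@values), digits = 4), ", ",
        format(max(object@values), digits = 4), "]\n", sep = "")
}
setMethod("show", "WindowedCoverage", .showTrack)
setMethod("show", "NormalizedProfile", .showTrack)

# ---------------------------------------------------------------------------
# LoessFit
# ---------------------------------------------------------------------------

#' Local-regression smooth of a copy-number profile
#'
#' Fitted values of a locally weighted polynomial regression (tricube
#' kernel) evaluated at every window midpoint of a [NormalizedProfile-class].
#'
#' @slot fitted smoothed values, one per window.
#' @slot span neighbourhood size as a fraction of the number of windows.
#' @slot degree local polynomial degree (1 or 2).
#' @slot circular whether the profile was wrapped before fitting.
#' @slot window window width in bp.
#' @slot genomeLength chromosome length in bp.
#' @seealso [loessSmooth()], [ptrLoess()], [findExtrema()]
#' @export
setClass("LoessFit",
    representation(fitted = "numeric", span = "numeric", degree = "integer",
                   circular = "logical", window = "numeric",
                   genomeLength = "numeric"))

setValidity("LoessFit", function(object) {
    msg <- character()
    if (any(!is.finite(object@fitted)))
        msg <- c(msg, "'fitted' values must be finite")
    if (object@span <= 0 || object@span > 1)
        msg <- c(msg, "'span' must be in (0, 1]")
    if (!object@degree %in% c(1L, 2L))
        msg <- c(msg, "'degree' must be 1 or 2")
    if (length(msg)) msg else TRUE
})

setMethod("show", "LoessFit", function(object) {
    cat("LoessFit over", length(object@fitted), "windows (span =",
        object@span, ", degree =", object@degree,
        if (object@circular) ", circular" else "", ")\n")
})

# ---------------------------------------------------------------------------
# GrowthCurve
# ---------------------------------------------------------------------------

#' OD600 growth curve
#'
#' A time series of optical-density measurements for one culture.
#'
#' @slot times measurement times in minutes, strictly increasing.
#' @slot od OD600 values, same length as `times`.
#' @seealso [growthRate()], [simulateGrowthCurve()]
#' @export
setClass("GrowthCurve",
    representation(times = "numeric", od = "numeric"))

setValidity("GrowthCurve", function(object) {
    msg <- character()
    if (length(object@times) != length(object@od))
        msg <- c(msg, "'times' and 'od' must have the same length")
    if (any(!is.finite(object@times)))
        msg <- c(msg, "'times' must be finite")
    if (length(object@times) > 1L && any(diff(object@times) <= 0))
        msg <- c(msg, "'times' must be strictly increasing")
    if (any(object@od < 0))
        msg <- c(msg, "'od' must be non-negative")
    if (length(msg)) msg else TRUE
})

#' @rdname GrowthCurve-class
#' @param times measurement times in minutes.
#' @param od OD600 values.
#' @return `GrowthCurve()` returns a [GrowthCurve-class] object.
#' @export
GrowthCurve <- function(times, od) {
    new("GrowthCurve", times = as.numeric(times), od = as.numeric(od))
}

setMethod("show", "GrowthCurve", function(object) {
    cat("GrowthCurve with", length(object@times), "points over",
        diff(range(object@times)), "min; OD range [",
        format(min(object@od), digits = 3), ",",
        format(max(object@od), digits = 3), "]\n")
})

# ---------------------------------------------------------------------------
# MdsEmbedding
# ---------------------------------------------------------------------------

#' Classical multidimensional-scaling embedding
#'
#' Sample coordinates from Torgerson double-centering of a Euclidean
#' distance matrix, together with the eigenvalues of the centred
#' inner-product matrix.
#'
#' @slot coordinates samples-by-dimensions coordinate matrix.
#' @slot eigenvalues all eigenvalues, non-increasing.
#' @slot warningFlag TRUE when fewer positive eigenvalues than requested
#'   dimensions were available and the embedding was truncated.
#' @seealso [classicalMds()], [centroidDissimilarity()]
#' @export
setClass("MdsEmbedding",
    representation(coordinates = "matrix", eigenvalues = "numeric",
                   warningFlag = "logical"))

setMethod("show", "MdsEmbedding", function(object) {
    cat("MdsEmbedding:", nrow(object@coordinates), "samples in",
        ncol(object@coordinates), "dimensions\n")
    ev <- object@eigenvalues[seq_len(min(5L, length(object@eigenvalues)))]
    cat("  leading eigenvalues:", paste(format(ev, digits = 4),
                                        collapse = ", "), "\n")
})
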