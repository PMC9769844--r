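# Accessor generics for the core data classes.

#' @export
setGeneric("genomeLength", function(x) standardGeneric("genomeLength"))
#' @export
setGeneric("windowSize", function(x) standardGeneric("windowSize"))
#' @export
setGeneric("trackValues", function(x) standardGeneric("trackValues"))
#' @export
setGeneric("windowStarts", function(x) standardGeneric("windowStarts"))
#' @export
setGeneric("windowMidpoints", function(x) standardGeneric("windowMidpoints"))
#' @export
setGeneric("fittedValues", function(x) standardGeneric("fittedValues"))
#' @export
setGeneric("mdsCoordinates", function(x) standardGeneric("mdsCoordinates"))
#' @export
setGeneric("mdsEigenvalues", function(x) standardGeneric("mdsEigenvalues"))

#' Accessors for windowed tracks and fits
#'
#' `genomeLength()`, `windowSize()`, `trackValues()`, `windowStarts()` and
#' `windowMidpoints()` expose the geometry and values of
#' [WindowedCoverage-class], [NormalizedProfile-class] and
#' [LoessFit-class] objects; `fittedValues()` returns the smoothed values
#' of a [LoessFit-class]; `mdsCoordinates()` and `mdsEigenvalues()` expose
#' an [MdsEmbedding-class].
#'
#' @param x a track, fit or embedding object.
#' @return numeric vectors (matrix for `mdsCoordinates`).
#' @name track-accessors
#' @aliases genomeLength windowSize trackValues windowStarts
#'   windowMidpoints fittedValues mdsCoordinates mdsEigenvalues
#' @examples
#' cov <- WindowedCoverage(c(4, 6, 10), window = 1000)
#' windowMidpoints(cov)
#' trackValues(normalizeCoverage(cov))
NULL

.starts <- function(x) seq(0, by = x@window,
                           length.out = ceiling(x@genomeLength / x@window))
.mids <- function(x) {
    st <- .starts(x)
    en <- pmin(st + x@window, x@genomeLength)
    (st + en) / 2
}

#' @rdname track-accessors
setMethod("genomeLength", "WindowedCoverage", function(x) x@genomeLength)
#' @rdname track-accessors
setMethod("genomeLength", "NormalizedProfile", function(x) x@genomeLength)
#' @rdname track-accessors
setMethod("genomeLength", "LoessFit", function(x) x@genomeLength)
#' @rdname track-accessors
setMethod("windowSize", "WindowedCoverage", function(x) x@window)
#' @rdname track-accessors
setMethod("windowSize", "NormalizedProfile", function(x) x@window)
#' @rdname track-accessors
setMethod("windowSize", "LoessFit", function(x) x@window)
#' @rdname track-accessors
setMethod("trackValues", "WindowedCoverage", function(x) x@values)
#' @rdname track-accessors
setMethod("trackValues", "NormalizedProfile", function(x) x@values)
#' @rdname track-accessors
setMethod("windowStarts", "WindowedCoverage", .starts)
#' @rdname track-accessors
setMethod("windowStarts", "NormalizedProfile", .starts)
#' @rdname track-accessors
setMethod("windowStarts", "LoessFit", .starts)
#' @rdname track-accessors
setMethod("windowMidpoints", "WindowedCoverage", .mids)
#' @rdname track-accessors
setMethod("windowMidpoints", "NormalizedProfile", .mids)
#' @rdname track-accessors
setMethod("windowMidpoints", "LoessFit", .mids)
#' @rdname track-accessors
setMethod("fittedValues", "LoessFit", function(x) x@fitted)
#' @rdname track-accessors
setMethod("mdsCoordinates", "MdsEmbedding", function(x) x@coordinates)
#' @rdname track-accessors
setMethod("mdsEigenvalues", "MdsEmbedding", function(x) x@eigenvalues)
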