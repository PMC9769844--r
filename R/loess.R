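# Local weighted polynomial regression (tricube kernel).
#
# Implemented directly rather than through stats::loess so that the
# neighbourhood rule (the ceiling(span * n) nearest windows), circular
# wrapping, and prediction at arbitrary points of an irregular training
# grid (needed when duplicated windows are masked before refitting) are
# all under explicit control.  At each evaluation point the fit solves a
# weighted least-squares polynomial of the requested degree with tricube
# weights on distance scaled by the distance to the q-th nearest
# neighbour.

# xt, yt: training points sorted by xt.  xout: evaluation points, sorted.
# Returns fitted values at xout.
.loessXY <- function(xt, yt, xout, q, degree) {
    n <- length(xt)
    q <- as.integer(min(max(q, degree + 2L), n))
    fitted <- numeric(length(xout))
    lo <- 1L
    for (k in seq_along(xout)) {
        x0 <- xout[k]
        # slide the q-window of nearest neighbours; width(lo) is the max
        # distance of the neighbourhood starting at lo, convex in lo
        hi <- lo + q - 1L
        while (hi < n &&
               max(abs(xt[lo + 1L] - x0), abs(xt[hi + 1L] - x0)) <=
               max(abs(xt[lo] - x0), abs(xt[hi] - x0))) {
            lo <- lo + 1L
            hi <- hi + 1L
        }
        idx <- lo:hi
        d <- abs(xt[idx] - x0)
        dmax <- max(d)
        w <- if (dmax <= 0) rep(1, q) else (1 - pmin(d / dmax, 1)^3)^3
        # guard against all-zero weights (can only happen for q = 1)
        if (all(w == 0)) w[which.min(d)] <- 1
        z <- if (dmax > 0) (xt[idx] - x0) / dmax else xt[idx] - x0
        X <- stats::poly(z, degree = degree, raw = TRUE, simple = TRUE)
        X <- cbind(1, X)
        sw <- sqrt(w)
        beta <- qr.coef(qr(X * sw), yt[idx] * sw)
        beta[is.na(beta)] <- 0
        fitted[k] <- beta[1L]
    }
    fitted
}

#' LOESS smoothing of a normalized copy-number profile
#'
#' Fits a locally weighted polynomial (tricube kernel, non-robust) at each
#' window midpoint, using the `ceiling(span * n)` nearest windows.  With
#' `circular = TRUE` the profile is padded by wrapping half a
#' neighbourhood of windows at each end before fitting, which removes the
#' one-sided-fit edge effect when the replication origin or terminus lies
#' near the coordinate boundary of a circular chromosome.
#'
#' As a rule of thumb the smoothing half-width (`span * L / 2`) should not
#' exceed half the smallest arc between adjacent copy-number extrema;
#' for multi-origin chromosomes this usually calls for a smaller span than
#' the single-origin default of 0.3.
#'
#' @param profile a [NormalizedProfile-class] (a [WindowedCoverage-class]
#'   is accepted and normalized on the fly).
#' @param span neighbourhood size as a fraction of the number of windows,
#'   in `(0, 1]` (default 0.3).
#' @param degree local polynomial degree, 1 or 2 (default 2).
#' @param circular wrap the profile before fitting (default `FALSE`).
#' @return a [LoessFit-class] with one fitted value per window.
#' @examples
#' spec <- ChromosomeSpec(1e6, origins = 5e5, doublingTime = 40,
#'                        forkSpeed = 12500)
#' fit <- loessSmooth(expectedProfile(spec, window = 5000))
#' ptrLoess(fit)
#' @export
loessSmooth <- function(profile, span = 0.3, degree = 2, circular = FALSE) {
    if (is(profile, "WindowedCoverage")) profile <- normalizeCoverage(profile)
    stopifnot(is(profile, "NormalizedProfile"))
    if (span <= 0 || span > 1) stop("'span' must be in (0, 1]")
    degree <- as.integer(degree)
    if (!degree %in% c(1L, 2L)) stop("'degree' must be 1 or 2")
    y <- profile@values
    n <- length(y)
    if (n < degree + 2L)
        stop("need at least degree + 2 windows to smooth")
    x <- windowMidpoints(profile)
    q <- as.integer(ceiling(span * n))
    if (circular) {
        pad <- min(as.integer(ceiling(q / 2)), n)
        L <- profile@genomeLength
        xt <- c(x[(n - pad + 1L):n] - L, x, x[1L:pad] + L)
        yt <- c(y[(n - pad + 1L):n], y, y[1L:pad])
    } else {
        xt <- x
        yt <- y
    }
    fitted <- .loessXY(xt, yt, x, q, degree)
    new("LoessFit", fitted = fitted, span = span, degree = degree,
        circular = circular, window = profile@window,
        genomeLength = profile@genomeLength)
}
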