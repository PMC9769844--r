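#' Exponential growth rate from an OD600 curve
#'
#' Slides a window of `windowPoints` consecutive measurements (all above
#' `odFloor`) along the curve, fits `ln(OD)` against time by ordinary
#' least squares in each window, and returns the largest slope among
#' windows whose fit reaches `r2Min`, converted to per hour.  This is the
#' classical maximum-specific-growth-rate estimator for plate-reader
#' curves: the window that captures unrestrained exponential growth has
#' both the best log-linearity and the steepest slope, while lag, floor
#' noise and saturation are rejected by the OD floor and the R-squared
#' gate.  When no window reaches `r2Min` the slope of the best-R-squared
#' window is returned with `warning_flag = TRUE`.
#'
#' @param curve a [GrowthCurve-class] (times in minutes).
#' @param windowPoints number of consecutive points per fit (default 5).
#' @param r2Min minimum R-squared for a window to qualify (default 0.99).
#' @param odFloor OD600 below or at which points are excluded as
#'   blank/noise (default 0.01).
#' @return a list with `rate` (per hour), `r_squared`, `window_start` and
#'   `window_end` (minutes), and `warning_flag`.
#' @examples
#' curve <- simulateGrowthCurve(0.02, mu = log(2), horizon = 300)
#' growthRate(curve)$rate   # ~ log(2) per hour
#' @export
growthRate <- function(curve, windowPoints = 5, r2Min = 0.99,
                       odFloor = 0.01) {
    stopifnot(is(curve, "GrowthCurve"))
    w <- as.integer(windowPoints)
    if (w < 3L) stop("'windowPoints' must be at least 3")
    usable <- curve@od > odFloor
    if (sum(usable) < w)
        stop("fewer than 'windowPoints' measurements above 'odFloor'")
    t <- curve@times
    y <- log(curve@od)
    n <- length(t)
    best <- list(slope = NA_real_, r2 = -Inf, i = NA_integer_)
    bestPass <- list(slope = -Inf, r2 = NA_real_, i = NA_integer_)
    anyPass <- FALSE
    for (i in seq_len(n - w + 1L)) {
        idx <- i:(i + w - 1L)
        if (!all(usable[idx])) next
        ti <- t[idx]; yi <- y[idx]
        sxx <- sum((ti - mean(ti))^2)
        sxy <- sum((ti - mean(ti)) * (yi - mean(yi)))
        syy <- sum((yi - mean(yi))^2)
        slope <- sxy / sxx
        r2 <- if (syy > 0) sxy^2 / (sxx * syy) else 1
        if (r2 > best$r2) best <- list(slope = slope, r2 = r2, i = i)
        if (r2 >= r2Min && slope > bestPass$slope) {
            anyPass <- TRUE
            bestPass <- list(slope = slope, r2 = r2, i = i)
        }
    }
    if (is.na(best$i))
        stop("no window of ", w, " consecutive points above 'odFloor'")
    res <- if (anyPass) bestPass else best
    list(rate = res$slope * 60, r_squared = res$r2,
         window_start = t[res$i], window_end = t[res$i + w - 1L],
         warning_flag = !anyPass)
}

#' Relative fitness
#'
#' The growth rate of a population divided by the growth rate of the
#' wild-type ancestor measured under the same conditions; the ancestor
#' itself maps to 1.
#'
#' @param mu growth rate(s), per hour.
#' @param muRef reference (wild-type ancestor) growth rate, per hour.
#' @return `mu / muRef`.
#' @examples
#' relativeFitness(0.58, 0.50)
#' @export
relativeFitness <- function(mu, muRef) {
    if (length(muRef) != 1L || !is.finite(muRef) || muRef <= 0)
        stop("'muRef' must be a single positive number")
    mu / muRef
}

#' Generations between two cell densities
#'
#' `log2(odFinal / odInitial)`: the number of doublings needed to grow
#' from the initial to the final density.
#'
#' @param odInitial,odFinal positive cell densities (e.g. OD600).
#' @return number of generations (vectorized).
#' @examples
#' generations(0.02, 0.4)   # log2(20)
#' @export
generations <- function(odInitial, odFinal) {
    if (any(odInitial <= 0) || any(odFinal <= 0))
        stop("densities must be positive")
    log2(odFinal / odInitial)
}

#' Cumulative generations over serial transfers
#'
#' Sums [generations()] over a sequence of culture cycles, each given by
#' its initial and final density.
#'
#' @param odInitial,odFinal vectors of per-cycle initial and final
#'   densities.
#' @return total number of generations.
#' @export
cumulativeGenerations <- function(odInitial, odFinal) {
    if (length(odInitial) != length(odFinal))
        stop("'odInitial' and 'odFinal' must have the same length")
    sum(generations(odInitial, odFinal))
}

#' Monotone fitness trajectory
#'
#' Smooths a fitness time series under the constraint that fitness never
#' decreases: the values are first projected onto the nearest
#' non-decreasing sequence (pool-adjacent-violators, via
#' [stats::isoreg()]), then interpolated with a shape-preserving monotone
#' cubic Hermite spline ([stats::splinefun()] with `method = "monoH.FC"`),
#' which reproduces the projected knot values exactly and is
#' non-decreasing everywhere between them.
#'
#' @param day measurement days, strictly increasing.
#' @param fitness relative fitness at each day.
#' @param grid days at which to evaluate the trajectory (default: 200
#'   points spanning the data).
#' @return a data.frame with columns `day` and `fitness`, non-decreasing
#'   in `fitness`.
#' @examples
#' monotoneFitnessTrajectory(0:3, c(1, 1.3, 1.1, 1.4), grid = 0:3)
#' @export
monotoneFitnessTrajectory <- function(day, fitness,
                                      grid = seq(min(day), max(day),
                                                 length.out = 200)) {
    if (length(day) != length(fitness))
        stop("'day' and 'fitness' must have the same length")
    if (length(day) < 3L) stop("need at least 3 points")
    if (anyDuplicated(day)) stop("duplicate days are not allowed")
    if (is.unsorted(day, strictly = TRUE))
        stop("'day' must be strictly increasing")
    proj <- stats::isoreg(day, fitness)$yf
    f <- stats::splinefun(day, proj, method = "monoH.FC")
    out <- f(grid)
    # guard against floating-point wiggle below resolution
    if (!is.unsorted(grid)) out <- cummax(out)
    data.frame(day = grid, fitness = out)
}
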