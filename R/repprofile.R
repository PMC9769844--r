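#' Normalize a windowed coverage track
#'
#' Divides the per-window mean coverage by the total coverage mapped to
#' the genome (the sum over windows), so the normalized copy numbers sum
#' to 1 and ratios between windows are preserved.  Any other constant
#' denominator would only rescale the profile uniformly; this choice makes
#' the unit-sum property a checkable invariant.
#'
#' @param cov a [WindowedCoverage-class].
#' @return a [NormalizedProfile-class].
#' @examples
#' normalizeCoverage(WindowedCoverage(c(30, 10), window = 1000))
#' @export
normalizeCoverage <- function(cov) {
    stopifnot(is(cov, "WindowedCoverage"))
    tot <- sum(cov@values)
    if (tot <= 0)
        stop("degenerate input: all-zero coverage cannot be normalized")
    new("NormalizedProfile", genomeLength = cov@genomeLength,
        window = cov@window, values = cov@values / tot)
}

#' Locate extrema of a smoothed profile
#'
#' Reports the global maximum and minimum of the LOESS fit (the copy
#' numbers of the replication origin and the termination site for a
#' single-origin chromosome) and, for each supplied genomic segment, the
#' position and value of the within-segment maximum (the copy numbers of
#' additional origins).  Ties break to the smallest genomic position.
#'
#' @param fit a [LoessFit-class].
#' @param segments optional list of `c(start, end)` half-open intervals in
#'   bp; windows belong to a segment when their midpoint lies inside it.
#' @return a list with components `global_max`, `global_min` (each
#'   `c(position, value)`, positions are window midpoints) and
#'   `segment_maxima`, a data.frame with one row per segment.
#' @examples
#' spec <- ChromosomeSpec(1e6, origins = 5e5, doublingTime = 40,
#'                        forkSpeed = 12500)
#' fit <- loessSmooth(expectedProfile(spec, window = 5000))
#' findExtrema(fit)$global_max
#' @export
findExtrema <- function(fit, segments = list()) {
    stopifnot(is(fit, "LoessFit"))
    mids <- windowMidpoints(fit)
    f <- fit@fitted
    imax <- which.max(f)
    imin <- which.min(f)
    seg <- NULL
    if (length(segments)) {
        seg <- do.call(rbind, lapply(segments, function(s) {
            if (length(s) != 2L || s[2L] <= s[1L])
                stop("each segment must be c(start, end) with end > start")
            inside <- which(mids >= s[1L] & mids < s[2L])
            if (!length(inside))
                stop("empty segment [", s[1L], ", ", s[2L], ")")
            i <- inside[which.max(f[inside])]
            data.frame(start = s[1L], end = s[2L],
                       position = mids[i], value = f[i])
        }))
    }
    list(global_max = c(position = mids[imax], value = f[imax]),
         global_min = c(position = mids[imin], value = f[imin]),
         segment_maxima = seg)
}

#' LOESS peak-to-trough ratio
#'
#' The ratio of the maximum to the minimum of the smoothed profile, read
#' as the copy-number ratio between the replication origin and the
#' termination site.  On a noiseless steady-state profile it approaches
#' the analytic `2^(C/tau)`.
#'
#' @param fit a [LoessFit-class] with positive fitted values.
#' @return a single ratio `>= 1` on well-behaved profiles.
#' @export
ptrLoess <- function(fit) {
    stopifnot(is(fit, "LoessFit"))
    mn <- min(fit@fitted)
    if (mn <= 0)
        stop("degenerate input: nonpositive LOESS minimum")
    max(fit@fitted) / mn
}

#' Multi-origin replication index
#'
#' Sums the smoothed copy numbers at the supplied peak loci and divides by
#' the smoothed copy number at the termination site.  For a chromosome
#' with k active origins the peak loci are the k coverage peaks; for a
#' single-origin relative used as a comparator, the homologous insertion
#' loci can be supplied as pseudo-peaks, so the index stays comparable
#' across strains.  With a flat profile the index equals the number of
#' peak loci (it is not anchored at 1).
#'
#' @param fit a [LoessFit-class].
#' @param peakLoci genomic positions (bp) of the peaks to sum.
#' @param troughLocus genomic position (bp) of the termination site;
#'   defaults to the position of the global LOESS minimum.
#' @return the index (a single positive number).
#' @export
multiOriIndex <- function(fit, peakLoci, troughLocus = NULL) {
    stopifnot(is(fit, "LoessFit"))
    nw <- length(fit@fitted)
    if (any(peakLoci < 0) || any(peakLoci >= fit@genomeLength))
        stop("peak loci must lie within the genome")
    if (is.null(troughLocus)) {
        troughLocus <- windowMidpoints(fit)[which.min(fit@fitted)]
    } else if (troughLocus < 0 || troughLocus >= fit@genomeLength) {
        stop("trough locus must lie within the genome")
    }
    peaks <- fit@fitted[windowIndex(peakLoci, fit@window, nw)]
    trough <- fit@fitted[windowIndex(troughLocus, fit@window, nw)]
    if (trough <= 0)
        stop("degenerate input: nonpositive copy number at the trough")
    sum(peaks) / trough
}

#' iRep-like replication index
#'
#' A simplified re-implementation of the index of replication: the
#' normalized copy numbers are log2-transformed and sorted, the extreme
#' `trimFraction` of windows is dropped at each end, and an ordinary
#' least-squares line of the sorted values against rank fraction (over
#' `[0, 1]`) is fitted.  The index is `2^slope`; for a symmetric
#' log-linear single-origin profile the sorted values are linear in rank,
#' so the slope recovers `log2` of the ori/ter ratio.
#'
#' Windows with zero coverage are excluded before transformation.
#'
#' @param profile a [NormalizedProfile-class] (or [WindowedCoverage-class]).
#' @param trimFraction fraction of windows trimmed at each end of the
#'   sorted values, in `[0, 0.25)` (default 0.05).
#' @return the index (a single positive number).
#' @export
irepLike <- function(profile, trimFraction = 0.05) {
    if (is(profile, "WindowedCoverage")) profile <- normalizeCoverage(profile)
    stopifnot(is(profile, "NormalizedProfile"))
    if (trimFraction < 0 || trimFraction >= 0.25)
        stop("'trimFraction' must be in [0, 0.25)")
    y <- profile@values[profile@values > 0]
    n <- length(y)
    if (n < 20L) stop("need at least 20 positive windows")
    y <- sort(log2(y))
    frac <- if (n == 1L) 0.5 else (seq_len(n) - 1) / (n - 1)
    k <- floor(trimFraction * n)
    keep <- if (k > 0) (k + 1L):(n - k) else seq_len(n)
    if (!length(keep)) stop("no windows left after trimming")
    slope <- stats::cov(frac[keep], y[keep]) / stats::var(frac[keep])
    2^slope
}

#' Median-filtered peak-to-trough ratio
#'
#' A simplified re-implementation of the coverage-based peak-to-trough
#' ratio: the normalized profile is median-filtered over `filterWindow`
#' bp, the filtered maximum and minimum are located (ties break to the
#' smallest position), and the ratio of the median raw copy number within
#' `flank` bp of the maximum to that within `flank` bp of the minimum is
#' returned.
#'
#' @param profile a [NormalizedProfile-class] (or [WindowedCoverage-class]).
#' @param filterWindow median-filter width in bp (default 10 kb).
#' @param flank half-width in bp of the region whose median is compared
#'   (default 10 kb).
#' @return the ratio (a single positive number).
#' @export
bptr <- function(profile, filterWindow = 10000, flank = 10000) {
    if (is(profile, "WindowedCoverage")) profile <- normalizeCoverage(profile)
    stopifnot(is(profile, "NormalizedProfile"))
    if (profile@genomeLength <= 4 * filterWindow)
        stop("genome must be longer than 4 * filterWindow")
    y <- profile@values
    k <- max(3L, as.integer(filterWindow / profile@window))
    if (k %% 2L == 0L) k <- k + 1L
    med <- stats::runmed(y, k = min(k, length(y) - (1 - length(y) %% 2L)),
                         endrule = "median")
    mids <- windowMidpoints(profile)
    pmax_ <- mids[which.max(med)]
    pmin_ <- mids[which.min(med)]
    num <- stats::median(y[abs(mids - pmax_) <= flank])
    den <- stats::median(y[abs(mids - pmin_) <= flank])
    if (den <= 0) stop("degenerate input: zero coverage at the trough")
    num / den
}

#' Detect segmental duplications from a copy-number profile
#'
#' Compares each window's normalized copy number with a LOESS baseline
#' and flags runs whose rolling-median ratio stays at or above
#' `ratioThreshold`.  To keep the duplicated segment itself from inflating
#' the baseline, the fit is computed twice: once on the full profile, and
#' once more after masking the windows whose ratio exceeds the
#' `maskQuantile` quantile; the second, mask-refitted baseline is used for
#' calling.
#'
#' @param profile a [NormalizedProfile-class] (or [WindowedCoverage-class]).
#' @param span,degree,circular LOESS parameters, see [loessSmooth()].
#' @param ratioThreshold minimum rolling-median ratio for a window to be
#'   flagged (default 1.7).
#' @param minLength minimum run length in bp (default 50 kb).
#' @param medianWindows width of the rolling median in windows (default
#'   21; even values are rounded up to the next odd number).
#' @param maskQuantile quantile of the first-pass ratio above which
#'   windows are masked before refitting (default 0.95).
#' @return a data.frame with columns `start`, `end`, `copy_ratio` and
#'   `n_windows`, one row per call (zero rows when nothing qualifies).
#' @examples
#' spec <- ChromosomeSpec(2e6, origins = 1e6,
#'                        duplication = c(2e5, 4e5, 2))
#' cov <- simulateCoverage(spec, nReads = 5e5, seed = 7)
#' detectDuplication(normalizeCoverage(cov))
#' @export
detectDuplication <- function(profile, span = 0.3, degree = 2,
                              circular = FALSE, ratioThreshold = 1.7,
                              minLength = 50000, medianWindows = 21,
                              maskQuantile = 0.95) {
    if (is(profile, "WindowedCoverage")) profile <- normalizeCoverage(profile)
    stopifnot(is(profile, "NormalizedProfile"))
    y <- profile@values
    n <- length(y)
    x <- windowMidpoints(profile)
    st <- windowStarts(profile)
    fit1 <- loessSmooth(profile, span = span, degree = degree,
                        circular = circular)
    r1 <- y / pmax(fit1@fitted, .Machine$double.eps)
    keep <- r1 <= stats::quantile(r1, maskQuantile)
    # refit once on the rank-trimmed profile so a true duplication does
    # not drag the baseline upward
    q <- as.integer(ceiling(span * n))
    fitted2 <- if (all(keep)) fit1@fitted
               else .loessXY(x[keep], y[keep], x, q, as.integer(degree))
    r <- y / pmax(fitted2, .Machine$double.eps)
    k <- as.integer(medianWindows)
    if (k %% 2L == 0L) k <- k + 1L
    k <- min(k, n - (1 - n %% 2L))
    rm_ <- stats::runmed(r, k = max(k, 3L), endrule = "median")
    flag <- rm_ >= ratioThreshold
    runs <- rle(flag)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    calls <- list()
    for (i in seq_along(runs$values)) {
        if (!runs$values[i]) next
        i1 <- starts[i]; i2 <- ends[i]
        lenBp <- (pmin(st[i2] + profile@window, profile@genomeLength)) - st[i1]
        if (lenBp < minLength) next
        calls[[length(calls) + 1L]] <- data.frame(
            start = st[i1],
            end = pmin(st[i2] + profile@window, profile@genomeLength),
            copy_ratio = mean(r[i1:i2]),
            n_windows = i2 - i1 + 1L)
    }
    if (length(calls)) do.call(rbind, calls)
    else data.frame(start = numeric(0), end = numeric(0),
                    copy_ratio = numeric(0), n_windows = integer(0))
}
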