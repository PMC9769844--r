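# Replication-profile indices: normalization, LOESS, extrema, PTR-type
# estimators and duplication detection.

test_that("normalization divides by total coverage and sums to one", {
    p <- normalizeCoverage(WindowedCoverage(c(10, 10, 10, 10)))
    expect_equal(trackValues(p), rep(0.25, 4))
    p2 <- normalizeCoverage(WindowedCoverage(c(30, 10)))
    expect_equal(trackValues(p2), c(0.75, 0.25))
    # scale invariance
    p3 <- normalizeCoverage(WindowedCoverage(7 * c(30, 10)))
    expect_identical(trackValues(p2), trackValues(p3))
    expect_error(normalizeCoverage(WindowedCoverage(c(0, 0, 0))),
                 "degenerate")
    # unit-sum invariant on simulated data
    spec <- singleOriginSpec(L = 1e6)
    prof <- normalizeCoverage(simulateCoverage(spec, 1e5, seed = 2))
    expect_equal(sum(trackValues(prof)), 1, tolerance = 1e-12)
})

test_that("LOESS reproduces constants and polynomials of its degree", {
    flat <- new("NormalizedProfile", genomeLength = 6e4, window = 1000,
                values = rep(1 / 60, 60))
    fit <- loessSmooth(flat, span = 0.3)
    expect_equal(fittedValues(fit), rep(1 / 60, 60), tolerance = 1e-12)

    lin <- (1:80) / sum(1:80)
    plin <- new("NormalizedProfile", genomeLength = 8e4, window = 1000,
                values = lin)
    for (deg in 1:2) {
        fitl <- loessSmooth(plin, span = 0.4, degree = deg)
        expect_equal(fittedValues(fitl), lin, tolerance = 1e-10)
    }
    expect_error(loessSmooth(plin, span = 0), "span")
    expect_error(loessSmooth(new("NormalizedProfile", genomeLength = 3e3,
                                 window = 1000, values = rep(1/3, 3))),
                 "windows")
})

test_that("LOESS matches the pointwise weighted-least-squares oracle", {
    set.seed(31)
    spec <- singleOriginSpec(ctau = 1, L = 2e5)
    y <- trackValues(expectedProfile(spec, window = 1000))
    y <- y * exp(rnorm(length(y), sd = 0.05))
    prof <- new("NormalizedProfile", genomeLength = 2e5, window = 1000,
                values = y / sum(y))
    fit <- loessSmooth(prof, span = 0.3, degree = 2)
    x <- windowMidpoints(prof)
    v <- trackValues(prof)
    probe <- c(1, 7, 50, 100, 151, 200)
    for (i in probe)
        expect_equal(fittedValues(fit)[i],
                     loessOracleAt(x, v, i, span = 0.3, degree = 2),
                     tolerance = 1e-10)
})

test_that("circular LOESS is equivariant under rotation of the profile", {
    # wrapping makes the fit blind to where the coordinate origin sits:
    # rotating the profile rotates the fitted values identically
    spec <- ChromosomeSpec(1e6, origins = 0, forkSpeed = 10000,
                           doublingTime = 50)
    y <- trackValues(expectedProfile(spec, window = 1000))
    k <- 137L
    rot <- c(y[-seq_len(k)], y[seq_len(k)])
    profA <- new("NormalizedProfile", genomeLength = 1e6, window = 1000,
                 values = y)
    profB <- new("NormalizedProfile", genomeLength = 1e6, window = 1000,
                 values = rot)
    fa <- fittedValues(loessSmooth(profA, span = 0.3, circular = TRUE))
    fb <- fittedValues(loessSmooth(profB, span = 0.3, circular = TRUE))
    expect_equal(c(fa[-seq_len(k)], fa[seq_len(k)]), fb,
                 tolerance = 1e-10)
})

test_that("extrema report global and per-segment maxima with stable ties", {
    flat <- new("LoessFit", fitted = rep(0.02, 50), span = 0.5,
                degree = 2L, circular = FALSE, window = 1000,
                genomeLength = 5e4)
    ex <- findExtrema(flat)
    expect_equal(ex$global_max[["position"]], 500)  # first window midpoint
    expect_equal(ex$global_min[["position"]], 500)
    expect_equal(ex$global_max[["value"]], ex$global_min[["value"]])

    # simulated single-origin profile: extrema near origin and antipode
    spec <- ChromosomeSpec(4.6e6, origins = 3.9e6, forkSpeed = 30000,
                           doublingTime = 67)
    cov <- simulateCoverage(spec, nReads = 1e6, seed = 32)
    fit <- loessSmooth(normalizeCoverage(cov), span = 0.3, circular = TRUE)
    ex2 <- findExtrema(fit)
    expect_lt(abs(ex2$global_max[["position"]] - 3.9e6), 5e4)
    antipode <- 3.9e6 - 2.3e6
    expect_lt(abs(ex2$global_min[["position"]] - antipode), 5e4)

    expect_error(findExtrema(fit, segments = list(c(2e6, 2e6))), "segment")
})

test_that("segment maxima recover additional origins on a 3-origin genome", {
    spec <- threeOriginSpec()
    cov <- simulateCoverage(spec, nReads = 1e6, seed = 33)
    # resolution rule: smoothing half-width below half the smallest
    # inter-origin arc calls for span <= 0.19 here
    fit <- loessSmooth(normalizeCoverage(cov), span = 0.15, circular = TRUE)
    ex <- findExtrema(fit, segments = list(c(0, 1e6), c(1e6, 2e6)))
    expect_lt(abs(ex$segment_maxima$position[1] - 365000), 5e4)
    expect_lt(abs(ex$segment_maxima$position[2] - 1240000), 5e4)
})

test_that("LOESS peak-to-trough ratio tracks the analytic 2^(C/tau)", {
    flat <- loessSmooth(new("NormalizedProfile", genomeLength = 1e5,
                            window = 1000, values = rep(1e-2, 100)),
                        span = 0.3)
    expect_equal(ptrLoess(flat), 1)

    fit <- loessSmooth(expectedProfile(singleOriginSpec(ctau = 1)),
                       span = 0.3)
    expect_equal(ptrLoess(fit), 2, tolerance = 0.05)

    # slower growth (larger tau) strictly decreases the ratio
    ratios <- sapply(c(0.5, 0.75, 1, 1.25), function(ct)
        ptrLoess(loessSmooth(expectedProfile(singleOriginSpec(
            ctau = ct, L = 1e6)), span = 0.3)))
    expect_true(all(diff(ratios) > 0))
})

test_that("multi-origin index sums peak copy numbers over the trough", {
    flat <- loessSmooth(new("NormalizedProfile", genomeLength = 1e5,
                            window = 1000, values = rep(1e-2, 100)),
                        span = 0.3)
    expect_equal(multiOriIndex(flat, peakLoci = c(1e4, 5e4, 9e4)), 3)

    # one peak locus at the global max collapses to ptrLoess
    spec <- singleOriginSpec(ctau = 1)
    fit <- loessSmooth(expectedProfile(spec), span = 0.3)
    ex <- findExtrema(fit)
    expect_equal(multiOriIndex(fit, peakLoci = ex$global_max[["position"]]),
                 ptrLoess(fit), tolerance = 1e-12)

    # noiseless 3-origin profile vs the closed form
    spec3 <- threeOriginSpec()
    fit3 <- loessSmooth(expectedProfile(spec3), span = 0.15,
                        circular = TRUE)
    tmax <- maxReplicationTime(spec3)
    closed <- sum(2^((tmax - replicationTime(spec3, spec3@origins)) / 67))
    idx <- multiOriIndex(fit3, peakLoci = spec3@origins)
    expect_equal(idx, closed, tolerance = 0.05)
    expect_error(multiOriIndex(fit3, peakLoci = 5e6), "within the genome")
})

test_that("iRep-like index recovers the sorted log-coverage slope", {
    flat <- new("NormalizedProfile", genomeLength = 1e5, window = 1000,
                values = rep(1e-2, 100))
    expect_equal(irepLike(flat), 1)

    prof <- expectedProfile(singleOriginSpec(ctau = 1))
    expect_equal(irepLike(prof), 2, tolerance = 0.1)

    # strictly increasing in 1/tau
    vals <- sapply(c(0.25, 0.5, 1, 1.5), function(ct)
        irepLike(expectedProfile(singleOriginSpec(ctau = ct, L = 1e6))))
    expect_true(all(diff(vals) > 0))
    expect_error(irepLike(flat, trimFraction = 0.3), "trimFraction")
})

test_that("median-filtered PTR matches the closed form and the LOESS ratio", {
    flat <- new("NormalizedProfile", genomeLength = 1e5, window = 1000,
                values = rep(1e-2, 100))
    expect_equal(bptr(flat), 1)

    prof <- expectedProfile(singleOriginSpec(ctau = 1))
    expect_equal(bptr(prof), 2, tolerance = 0.1)

    # cross-estimator agreement on noisy single-origin simulations
    spec <- singleOriginSpec(ctau = 1, L = 2.3e6)
    for (s in 1:3) {
        prof <- normalizeCoverage(simulateCoverage(spec, 1e6, seed = s))
        lr <- ptrLoess(loessSmooth(prof, span = 0.3))
        expect_lt(abs(log2(bptr(prof)) - log2(lr)), 0.15)
    }
})

test_that("duplication detection flags planted segments and nothing else", {
    L <- 4.6e6
    specDup <- ChromosomeSpec(L, origins = L / 2, forkSpeed = 30000,
                              doublingTime = 67,
                              duplication = c(1e6, 1.2e6, 2))
    cov <- simulateCoverage(specDup, nReads = 1e6, seed = 41)
    calls <- detectDuplication(normalizeCoverage(cov))
    expect_equal(nrow(calls), 1L)
    expect_lt(abs(calls$start - 1e6), 1e4)
    expect_lt(abs(calls$end - 1.2e6), 1e4)
    expect_gt(calls$copy_ratio, 1.8)
    expect_lt(calls$copy_ratio, 2.2)

    # null: no calls
    specNull <- ChromosomeSpec(L, origins = L / 2, forkSpeed = 30000,
                               doublingTime = 67)
    covN <- simulateCoverage(specNull, nReads = 1e6, seed = 42)
    expect_equal(nrow(detectDuplication(normalizeCoverage(covN))), 0L)

    # globally doubled coverage is absorbed by normalization
    cov2 <- WindowedCoverage(2 * trackValues(covN), window = 1000,
                             genomeLength = L)
    expect_equal(nrow(detectDuplication(normalizeCoverage(cov2))), 0L)
})
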