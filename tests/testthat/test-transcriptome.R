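# Normalization, DE testing, overlaps, MDS and the dissimilarity
# regression.

test_that("median-of-ratios size factors recover exact library scalars", {
    m <- cbind(a = c(10, 20, 30, 5), b = 2 * c(10, 20, 30, 5),
               c = 0.5 * c(10, 20, 30, 5))
    sf <- medianRatioSizeFactors(m)
    expect_equal(unname(sf["b"] / sf["a"]), 2)
    expect_equal(unname(sf["c"] / sf["a"]), 0.5)
    # identical samples get identical factors
    m2 <- cbind(x = c(3, 9, 1), y = c(3, 9, 1))
    expect_equal(diff(unname(medianRatioSizeFactors(m2))), 0)
    expect_error(medianRatioSizeFactors(cbind(c(0, 1), c(1, 0))),
                 "degenerate")
})

test_that("size factors agree with the DESeq2 reference implementation", {
    skip_if_not_installed("DESeq2")
    des <- ExpressionDesign(nGenes = 400, dispersion = 0.02, seed = 61)
    m <- SummarizedExperiment::assay(simulateCounts(des))
    ours <- medianRatioSizeFactors(m)
    ref <- DESeq2::estimateSizeFactorsForMatrix(m)
    # same estimator up to a common rescaling
    expect_equal(ours / ours[1L], ref / ref[1L], tolerance = 1e-6)
})

test_that("size factors recover planted library scalars on NB data", {
    des <- ExpressionDesign(nGenes = 2000, dispersion = 0.01,
                            effectScale = 0, shiftedFraction = 0,
                            seed = 62)
    se <- simulateCounts(des)
    sf <- medianRatioSizeFactors(se)
    truth <- SummarizedExperiment::colData(se)$size_factor_true
    expect_lt(max(abs((sf / sf[1L]) / (truth / truth[1L]) - 1)), 0.05)
})

test_that("rlog-like transform is a shifted log2 of normalized counts", {
    m <- matrix(c(0, 3, 7, 15), ncol = 1,
                dimnames = list(NULL, "s1"))
    y <- rlogLike(m, sizeFactors = 1)
    expect_equal(as.numeric(y), log2(c(1, 4, 8, 16)))
    # monotone in counts at fixed size factor
    expect_true(all(diff(as.numeric(y)) > 0))
    expect_error(rlogLike(m, sizeFactors = -1), "positive")
})

test_that("identical groups produce zero fold changes and no DEGs", {
    m <- matrix(rpois(400, 50), ncol = 4)
    m <- cbind(m, m)   # group B duplicates group A sample-for-sample
    colnames(m) <- paste0("s", 1:8)
    meta <- data.frame(population = rep(c("A", "B"), each = 4))
    res <- deTest(m, "A", "B", meta = meta)
    expect_true(all(res$log2_fold_change[res$tested] == 0))
    expect_false(any(res$is_deg))
    expect_error(deTest(m[, 1:3], "A", "B",
                        meta = meta[1:3, , drop = FALSE]),
                 "at least 2")
})

test_that("DE q-values are BH-monotone and respect both thresholds", {
    set.seed(63)
    m <- matrix(rnbinom(2000 * 6, mu = 200, size = 50), ncol = 6)
    m[1:50, 4:6] <- matrix(rnbinom(50 * 3, mu = 900, size = 50), ncol = 3)
    colnames(m) <- paste0("s", 1:6)
    meta <- data.frame(population = rep(c("A", "B"), each = 3))
    res <- deTest(m, "A", "B", meta = meta)
    ord <- order(res$p_value[res$tested])
    q <- res$q_value[res$tested][ord]
    expect_true(all(diff(q) >= -1e-12))
    expect_equal(res$q_value[res$tested],
                 p.adjust(res$p_value[res$tested], "BH"))
    flagged <- which(res$is_deg)
    fc <- 2^res$log2_fold_change[flagged]
    expect_true(all(res$q_value[flagged] < 0.05))
    expect_true(all(fc > 1.5 | fc < 1 / 1.5))
})

test_that("all-zero genes are excluded from testing but reported", {
    m <- matrix(rpois(300, 30), ncol = 6)
    m[5, ] <- 0
    colnames(m) <- paste0("s", 1:6)
    meta <- data.frame(population = rep(c("A", "B"), each = 3))
    res <- deTest(m, "A", "B", meta = meta)
    expect_false(res$tested[5])
    expect_true(is.na(res$p_value[5]))
    expect_false(res$is_deg[5])
    expect_equal(sum(res$tested), 49L)
})

test_that("DEG overlap counts exclusive intersections exhaustively", {
    ov <- degOverlap(list(p1 = c("a", "b", "c"), p2 = c("b", "c", "d"),
                          p3 = "c"))
    expect_equal(ov$common, "c")
    expect_equal(ov$common_fraction_pct, 25)
    expect_equal(ov$union_size, 4L)
    # disjoint sets share nothing
    expect_equal(degOverlap(list(x = "a", y = "b"))$common_fraction_pct, 0)

    # brute-force enumeration oracle: exclusive counts partition the union
    set.seed(64)
    sets <- lapply(1:4, function(i) sample(letters, sample(5:15, 1)))
    names(sets) <- paste0("s", 1:4)
    ov2 <- degOverlap(sets)
    expect_equal(sum(ov2$exclusive$count), ov2$union_size)
    u <- unique(unlist(sets))
    oracleCommon <- u[vapply(u, function(g)
        all(vapply(sets, function(s) g %in% s, logical(1))), logical(1))]
    expect_setequal(ov2$common, oracleCommon)
})

test_that("classical MDS reproduces Euclidean configurations exactly", {
    set.seed(65)
    pts <- matrix(rnorm(14 * 3), ncol = 3)   # 14 samples in 3-D
    emb <- classicalMds(pts, m = 3)
    expect_lt(max(abs(as.matrix(dist(mdsCoordinates(emb))) -
                      as.matrix(dist(pts)))), 1e-8)
    expect_false(emb@warningFlag)

    # two samples at distance d embed at +/- d/2
    two <- classicalMds(stats::dist(matrix(c(0, 4), ncol = 1)), m = 1)
    expect_equal(sort(as.numeric(mdsCoordinates(two))), c(-2, 2))

    # equilateral triangle, side 1
    D <- stats::as.dist(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3))
    tri <- classicalMds(D, m = 2)
    expect_equal(as.numeric(dist(mdsCoordinates(tri))), rep(1, 3),
                 tolerance = 1e-10)
})

test_that("classical MDS agrees with cmdscale and flags rank deficits", {
    set.seed(66)
    pts <- matrix(rnorm(10 * 4), ncol = 4)
    ours <- classicalMds(pts, m = 3)
    ref <- stats::cmdscale(dist(pts), k = 3)
    expect_equal(as.matrix(dist(mdsCoordinates(ours))),
                 as.matrix(dist(ref)), tolerance = 1e-8,
                 ignore_attr = TRUE)

    # points on a line have one positive eigenvalue; asking for 3 warns
    line <- matrix(1:5, ncol = 1)
    embL <- classicalMds(line, m = 3)
    expect_true(embL@warningFlag)
    expect_equal(ncol(mdsCoordinates(embL)), 1L)
})

test_that("centroid dissimilarity measures distance to the lineage ancestor", {
    coords <- rbind(c(0, 0, 0), c(0, 0, 0),       # ancestor replicates
                    c(3, 4, 0), c(3, 4, 0))       # population replicates
    emb <- new("MdsEmbedding", coordinates = coords,
               eigenvalues = rep(1, 3), warningFlag = FALSE)
    meta <- data.frame(
        population = c("anc", "anc", "evo", "evo"), lineage = "WT",
        relative_fitness = c(1, 1, 1.3, 1.3),
        is_ancestor = c(TRUE, TRUE, FALSE, FALSE))
    d <- centroidDissimilarity(emb, meta)
    expect_equal(d$dissimilarity[d$population == "evo"], 5)
    expect_equal(d$dissimilarity[d$population == "anc"], 0)

    # invariance under rigid rotation and translation
    set.seed(67)
    q <- qr.Q(qr(matrix(rnorm(9), 3)))
    coords2 <- coords %*% q + matrix(rnorm(3), nrow(coords), 3,
                                     byrow = TRUE)
    emb2 <- new("MdsEmbedding", coordinates = coords2,
                eigenvalues = rep(1, 3), warningFlag = FALSE)
    expect_equal(centroidDissimilarity(emb2, meta)$dissimilarity,
                 d$dissimilarity, tolerance = 1e-10)

    expect_error(centroidDissimilarity(emb, transform(meta,
        is_ancestor = FALSE)), "ancestor")
})

test_that("fitness regression matches the normal-equations oracle", {
    set.seed(68)
    pts <- data.frame(relative_fitness = runif(8, 1, 1.5),
                      dissimilarity = runif(8, 0, 5),
                      is_ancestor = FALSE)
    res <- fitnessRegression(pts)
    X <- cbind(1, pts$relative_fitness)
    beta <- solve(t(X) %*% X, t(X) %*% pts$dissimilarity)
    expect_equal(res$intercept, beta[1], tolerance = 1e-10)
    expect_equal(res$slope, beta[2], tolerance = 1e-10)
    expect_gte(res$r_squared, 0)
    expect_lte(res$r_squared, 1)

    # perfectly collinear points
    col <- data.frame(relative_fitness = c(1, 1.2, 1.4),
                      dissimilarity = c(0, 2, 4), is_ancestor = FALSE)
    expect_equal(suppressWarnings(fitnessRegression(col))$r_squared, 1,
                 tolerance = 1e-12)
    expect_error(fitnessRegression(data.frame(
        relative_fitness = rep(1.2, 4), dissimilarity = 1:4,
        is_ancestor = FALSE)), "variance")
})
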