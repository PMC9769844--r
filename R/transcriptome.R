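.countsMatrix <- function(counts) {
    if (is(counts, "SummarizedExperiment"))
        counts <- SummarizedExperiment::assay(counts, "counts")
    counts <- as.matrix(counts)
    if (any(counts < 0)) stop("counts must be non-negative")
    counts
}

.sampleMeta <- function(x, meta = NULL) {
    if (is.null(meta) && is(x, "SummarizedExperiment"))
        meta <- as.data.frame(SummarizedExperiment::colData(x))
    if (is.null(meta)) stop("sample metadata is required")
    req <- c("population", "lineage", "relative_fitness", "is_ancestor")
    miss <- setdiff(req, names(meta))
    if (length(miss))
        stop("sample metadata lacks column(s): ", paste(miss, collapse = ", "))
    meta
}

#' Median-of-ratios library size factors
#'
#' The classical median-of-ratios normalization: a pseudo-reference is
#' built as the per-gene geometric mean across samples (over genes with
#' all-positive counts), and each sample's size factor is the median of
#' its ratios to that reference.  Factors are reported as-is, without
#' rescaling to a unit mean.
#'
#' @param counts a gene-by-sample count matrix or a
#'   `SummarizedExperiment` with a `"counts"` assay.
#' @return a numeric vector of positive size factors, one per sample.
#' @examples
#' m <- cbind(a = c(10, 20, 30), b = c(20, 40, 60))
#' medianRatioSizeFactors(m)   # b is exactly twice a
#' @export
medianRatioSizeFactors <- function(counts) {
    m <- .countsMatrix(counts)
    pos <- rowSums(m > 0) == ncol(m)
    if (!any(pos))
        stop("degenerate input: no gene is positive in all samples")
    lg <- log(m[pos, , drop = FALSE])
    ref <- rowMeans(lg)
    sf <- apply(exp(lg - ref), 2L, stats::median)
    names(sf) <- colnames(m)
    sf
}

#' Regularized-log-like transform
#'
#' `log2(count / sizeFactor + pseudocount)` per gene and sample: a light
#' stand-in for a shrinkage-based regularized log transform whose only
#' contract here is to provide variance-damped values on which Euclidean
#' distances feed multidimensional scaling.  Genes absent from a strain
#' (e.g. deleted regions) should be carried as zero counts, which map to
#' `log2(pseudocount)`.
#'
#' @param counts a count matrix or `SummarizedExperiment`.
#' @param sizeFactors per-sample positive size factors; computed with
#'   [medianRatioSizeFactors()] when `NULL`.
#' @param pseudocount added inside the log (default 1).
#' @return a gene-by-sample numeric matrix.
#' @export
rlogLike <- function(counts, sizeFactors = NULL, pseudocount = 1) {
    m <- .countsMatrix(counts)
    if (is.null(sizeFactors)) sizeFactors <- medianRatioSizeFactors(m)
    if (any(sizeFactors <= 0)) stop("size factors must be positive")
    if (length(sizeFactors) != ncol(m))
        stop("need one size factor per sample")
    log2(sweep(m, 2L, sizeFactors, "/") + pseudocount)
}

#' Lightweight negative-binomial differential-expression test
#'
#' A Wald test on the log2 fold change of normalized means between two
#' groups of samples.  Per gene, the group means of normalized counts get
#' a pseudocount of 0.5; the dispersion is a method-of-moments estimate
#' pooled over both groups with a floor of 0.01; the standard error of
#' the log2 fold change follows from the delta method under
#' negative-binomial variance (`var = mu + alpha * mu^2`); p-values are
#' two-sided normal and q-values are Benjamini-Hochberg.  A gene is
#' flagged as differentially expressed when `q < qThreshold` and the
#' normalized-mean fold change exceeds `fcThreshold` in either direction.
#'
#' Genes with zero counts in every sample of both groups are excluded
#' from testing (`tested = FALSE`, all statistics `NA`).
#'
#' @param counts a count matrix or `SummarizedExperiment`.
#' @param meta sample metadata with a `population` column (taken from
#'   `colData` when `counts` is a `SummarizedExperiment`).
#' @param groupA,groupB population labels to compare (fold changes are
#'   B over A).
#' @param qThreshold,fcThreshold DEG thresholds (defaults 0.05 and 1.5).
#' @param dispersionFloor lower bound on the dispersion estimate.
#' @return a data.frame with one row per gene: `gene`, `base_mean_a`,
#'   `base_mean_b`, `log2_fold_change`, `p_value`, `q_value`, `is_deg`,
#'   `direction` (`"up"`, `"down"` or `"none"`), `tested`.
#' @export
deTest <- function(counts, groupA, groupB, meta = NULL,
                   qThreshold = 0.05, fcThreshold = 1.5,
                   dispersionFloor = 0.01) {
    m <- .countsMatrix(counts)
    if (is.null(meta)) {
        if (is(counts, "SummarizedExperiment"))
            meta <- as.data.frame(SummarizedExperiment::colData(counts))
        else stop("'meta' is required when 'counts' is a matrix")
    }
    if (!"population" %in% names(meta))
        stop("'meta' needs a 'population' column")
    ia <- which(meta$population == groupA)
    ib <- which(meta$population == groupB)
    if (length(ia) < 2L || length(ib) < 2L)
        stop("each group needs at least 2 samples")
    sf <- medianRatioSizeFactors(m)
    nm <- sweep(m, 2L, sf, "/")
    a <- nm[, ia, drop = FALSE]
    b <- nm[, ib, drop = FALSE]
    na <- length(ia); nb <- length(ib)
    tested <- rowSums(m[, c(ia, ib), drop = FALSE]) > 0
    mA <- rowMeans(a) + 0.5
    mB <- rowMeans(b) + 0.5
    lfc <- log2(mB / mA)
    vA <- apply(a, 1L, stats::var)
    vB <- apply(b, 1L, stats::var)
    vPool <- ((na - 1) * vA + (nb - 1) * vB) / (na + nb - 2)
    mPool <- (rowMeans(a) * na + rowMeans(b) * nb) / (na + nb) + 0.5
    alpha <- pmax((vPool - mPool) / mPool^2, dispersionFloor)
    # variance of the log2 of a group mean under NB sampling
    varLog2 <- function(mu, n) (mu + alpha * mu^2) / (n * mu^2) / log(2)^2
    se <- sqrt(varLog2(mA, na) + varLog2(mB, nb))
    z <- lfc / se
    p <- 2 * stats::pnorm(-abs(z))
    p[!tested] <- NA_real_
    q <- rep(NA_real_, length(p))
    q[tested] <- stats::p.adjust(p[tested], method = "BH")
    fc <- mB / mA
    isDeg <- tested & !is.na(q) & q < qThreshold &
        (fc > fcThreshold | fc < 1 / fcThreshold)
    direction <- ifelse(isDeg & lfc > 0, "up",
                        ifelse(isDeg & lfc < 0, "down", "none"))
    out <- data.frame(
        gene = if (!is.null(rownames(m))) rownames(m)
               else sprintf("gene%05d", seq_len(nrow(m))),
        base_mean_a = mA - 0.5, base_mean_b = mB - 0.5,
        log2_fold_change = ifelse(tested, lfc, NA_real_),
        p_value = p, q_value = q, is_deg = isDeg, direction = direction,
        tested = tested, row.names = NULL)
    out
}

#' Overlaps between per-population DEG sets
#'
#' Computes all exclusive (UpSet-style) intersection counts for a
#' collection of gene sets, plus the fraction of the union shared by
#' every set.  Typically called once for upregulated and once for
#' downregulated genes.
#'
#' @param sets named list of character vectors over the same gene
#'   universe.
#' @return a list with `exclusive`, a data.frame of exclusive
#'   intersection counts (one row per non-empty combination, `members`
#'   separated by `"+"`), `common` (genes present in every set),
#'   `common_fraction_pct` (`100 * |intersection| / |union|`), and
#'   `union_size`.
#' @examples
#' degOverlap(list(a = c("x", "y", "z"), b = c("y", "z", "w"), c = "z"))
#' @export
degOverlap <- function(sets) {
    stopifnot(is.list(sets), length(sets) >= 1L)
    if (is.null(names(sets)) || any(names(sets) == ""))
        stop("'sets' must be a named list")
    sets <- lapply(sets, unique)
    universe <- unique(unlist(sets, use.names = FALSE))
    k <- length(sets)
    if (!length(universe)) {
        return(list(exclusive = data.frame(members = character(0),
                                           count = integer(0)),
                    common = character(0), common_fraction_pct = 0,
                    union_size = 0L))
    }
    membership <- vapply(sets, function(s) universe %in% s,
                         logical(length(universe)))
    membership <- matrix(membership, nrow = length(universe))
    key <- apply(membership, 1L, function(r)
        paste(names(sets)[r], collapse = "+"))
    tab <- table(key)
    excl <- data.frame(members = names(tab), count = as.integer(tab),
                       row.names = NULL)
    common <- universe[rowSums(membership) == k]
    list(exclusive = excl[order(-excl$count), , drop = FALSE],
         common = common,
         common_fraction_pct = 100 * length(common) / length(universe),
         union_size = length(universe))
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Embeds samples so that Euclidean distances between embedded points
#' approximate the Euclidean distances between the rows of `y`: the
#' squared-distance matrix is double-centred
#' (`B = -1/2 * J * D^2 * J`), eigendecomposed, and the coordinates are
#' the leading eigenvectors scaled by the square roots of their (positive)
#' eigenvalues.  When the input distances are Euclidean and generated by
#' points in at most `m` dimensions, the embedding reproduces them
#' exactly.  When fewer than `m` positive eigenvalues exist, a
#' lower-dimensional embedding is returned with `warningFlag = TRUE`.
#'
#' @param y a samples-by-features numeric matrix (e.g. the transpose of
#'   an [rlogLike()] matrix), or a `dist` object of precomputed
#'   distances.
#' @param m number of embedding dimensions (default 3).
#' @return an [MdsEmbedding-class].
#' @examples
#' pts <- matrix(rnorm(30), nrow = 10)
#' emb <- classicalMds(pts, m = 3)
#' max(abs(dist(mdsCoordinates(emb)) - dist(pts)))   # ~ 0
#' @export
classicalMds <- function(y, m = 3) {
    D <- if (inherits(y, "dist")) as.matrix(y) else as.matrix(stats::dist(y))
    n <- nrow(D)
    if (n < m + 1L) stop("need at least m + 1 samples")
    D2 <- D^2
    B <- -0.5 * (D2 - rowMeans(D2) -
                 rep(colMeans(D2), each = n) + mean(D2))
    eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
    pos <- which(eig$values > max(eig$values[1L], 0) * 1e-12)
    keep <- pos[seq_len(min(m, length(pos)))]
    flag <- length(keep) < m
    coords <- eig$vectors[, keep, drop = FALSE] %*%
        diag(sqrt(eig$values[keep]), nrow = length(keep))
    rownames(coords) <- rownames(D)
    new("MdsEmbedding", coordinates = coords, eigenvalues = eig$values,
        warningFlag = flag)
}

#' Transcriptome dissimilarity as centroid distance to the ancestor
#'
#' For each population, averages its replicates' MDS coordinates into a
#' centroid and reports the Euclidean distance between that centroid and
#' the centroid of the ancestral population of the same lineage.  An
#' ancestor's own dissimilarity is 0 by construction.
#'
#' @param embedding an [MdsEmbedding-class] whose rows correspond to the
#'   rows of `meta` (typically 3-dimensional).
#' @param meta per-sample metadata with columns `population`, `lineage`,
#'   `relative_fitness` and `is_ancestor` (a `colData`-style data.frame).
#' @return a data.frame with one row per population: `population`,
#'   `lineage`, `relative_fitness`, `is_ancestor`, `dissimilarity`.
#' @export
centroidDissimilarity <- function(embedding, meta) {
    stopifnot(is(embedding, "MdsEmbedding"))
    coords <- embedding@coordinates
    meta <- .sampleMeta(NULL, as.data.frame(meta))
    if (nrow(meta) != nrow(coords))
        stop("'meta' must have one row per embedded sample")
    pops <- unique(meta$population)
    cents <- lapply(pops, function(p)
        colMeans(coords[meta$population == p, , drop = FALSE]))
    names(cents) <- pops
    popMeta <- meta[!duplicated(meta$population),
                    c("population", "lineage", "relative_fitness",
                      "is_ancestor")]
    anc <- popMeta$population[popMeta$is_ancestor]
    ancLineage <- popMeta$lineage[popMeta$is_ancestor]
    out <- popMeta
    out$dissimilarity <- vapply(seq_len(nrow(popMeta)), function(i) {
        li <- popMeta$lineage[i]
        j <- which(ancLineage == li)
        if (length(j) != 1L)
            stop("lineage '", li, "' must have exactly one ancestor")
        sqrt(sum((cents[[popMeta$population[i]]] - cents[[anc[j]]])^2))
    }, numeric(1))
    rownames(out) <- NULL
    out
}

#' Regression of transcriptome dissimilarity on relative fitness
#'
#' Ordinary least squares with dissimilarity as the response and relative
#' fitness as the predictor, summarising whether the distance a
#' population's transcriptome has travelled from its ancestor scales with
#' its fitness gain.
#'
#' @param points a data.frame from [centroidDissimilarity()] (columns
#'   `relative_fitness`, `dissimilarity`, and `is_ancestor` unless
#'   `includeAncestors = TRUE`).
#' @param includeAncestors keep the ancestors' zero-dissimilarity points
#'   in the regression (default `FALSE`, matching a design where each
#'   lineage is anchored at its own ancestor).
#' @return a list with `slope`, `intercept`, `r_squared`, `p_value`
#'   (F-test of the slope), `n`, and the fitted `model` (an `lm`).
#' @export
fitnessRegression <- function(points, includeAncestors = FALSE) {
    stopifnot(is.data.frame(points))
    if (!includeAncestors && "is_ancestor" %in% names(points))
        points <- points[!points$is_ancestor, , drop = FALSE]
    if (nrow(points) < 3L) stop("need at least 3 points")
    if (stats::var(points$relative_fitness) == 0)
        stop("zero variance in relative fitness")
    fit <- stats::lm(dissimilarity ~ relative_fitness, data = points)
    sm <- summary(fit)
    fstat <- sm$fstatistic
    list(slope = unname(stats::coef(fit)[2L]),
         intercept = unname(stats::coef(fit)[1L]),
         r_squared = sm$r.squared,
         p_value = unname(stats::pf(fstat[1L], fstat[2L], fstat[3L],
                                    lower.tail = FALSE)),
         n = nrow(points), model = fit)
}
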