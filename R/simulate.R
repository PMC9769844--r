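#' Simulate a windowed coverage track
#'
#' Draws sequencing reads from the steady-state copy-number landscape of a
#' [ChromosomeSpec-class] and bins them into fixed-width windows.  Window
#' probabilities are proportional to the expected copy number at the
#' window midpoint times the window width (the midpoint approximation is
#' exact to first order because windows are tiny relative to the
#' chromosome).  In `"poisson"` mode the window counts are a single
#' multinomial draw, so they sum to `nReads` exactly; in
#' `"negative_binomial"` mode each window count is drawn independently
#' from a negative binomial with the same mean and the given dispersion
#' (gamma-Poisson overdispersion), so the total varies.
#'
#' Counts are converted to mean per-base coverage as
#' `count * readLength / windowWidth`.
#'
#' @param spec a [ChromosomeSpec-class].
#' @param nReads total number of reads to place.
#' @param window window width in bp (default 1000).
#' @param noise `"poisson"` or `"negative_binomial"`.
#' @param dispersion negative-binomial dispersion (variance =
#'   `mu + dispersion * mu^2`); 0 falls back to Poisson draws.
#' @param readLength read length in bp used for the coverage conversion
#'   (default 100).
#' @param seed RNG seed; identical seeds give identical tracks.
#' @return a [WindowedCoverage-class].
#' @examples
#' spec <- ChromosomeSpec(1e6, origins = 5e5)
#' cov <- simulateCoverage(spec, nReads = 1e5, seed = 1)
#' cov
#' @export
simulateCoverage <- function(spec, nReads, window = 1000,
                             noise = c("poisson", "negative_binomial"),
                             dispersion = 0, readLength = 100, seed = NULL) {
    stopifnot(is(spec, "ChromosomeSpec"))
    noise <- match.arg(noise)
    if (!is.numeric(nReads) || length(nReads) != 1L || nReads <= 0)
        stop("'nReads' must be a single positive number")
    if (dispersion < 0) stop("'dispersion' must be >= 0")
    nw <- ceiling(spec@length / window)
    st <- seq(0, by = window, length.out = nw)
    widths <- pmin(st + window, spec@length) - st
    mids <- st + widths / 2
    p <- expectedCopyNumber(spec, mids) * widths
    p <- p / sum(p)
    counts <- withSeed(seed, {
        if (noise == "poisson") {
            as.numeric(stats::rmultinom(1L, size = nReads, prob = p))
        } else if (dispersion == 0) {
            stats::rpois(nw, lambda = nReads * p)
        } else {
            stats::rnbinom(nw, mu = nReads * p, size = 1 / dispersion)
        }
    })
    new("WindowedCoverage", genomeLength = spec@length,
        window = as.numeric(window),
        values = counts * readLength / widths)
}

#' Simulate an OD600 growth curve
#'
#' Exponential growth that saturates at a carrying capacity:
#' `OD(t) = min(od0 * exp(mu * t), carryingCapacity)`, sampled on a regular
#' grid and optionally perturbed by multiplicative log-normal noise with
#' coefficient of variation `noiseCv`.
#'
#' @param od0 initial OD600.
#' @param mu growth rate per hour.
#' @param carryingCapacity saturation OD600.
#' @param cadence sampling interval in minutes (default 30, the usual
#'   plate-reader setting).
#' @param horizon last sampling time in minutes; samples are taken at
#'   `0, cadence, 2 * cadence, ... <= horizon`.
#' @param noiseCv coefficient of variation of the multiplicative
#'   log-normal measurement noise (0 = noiseless).
#' @param seed RNG seed.
#' @return a [GrowthCurve-class].
#' @examples
#' simulateGrowthCurve(0.02, mu = log(2), horizon = 240)
#' @export
simulateGrowthCurve <- function(od0, mu, carryingCapacity = 1.0,
                                cadence = 30, horizon = 720,
                                noiseCv = 0, seed = NULL) {
    if (od0 <= 0 || od0 >= carryingCapacity)
        stop("'od0' must satisfy 0 < od0 < carryingCapacity")
    if (cadence <= 0) stop("'cadence' must be positive")
    if (noiseCv < 0) stop("'noiseCv' must be >= 0")
    times <- seq(0, horizon, by = cadence)
    od <- pmin(od0 * exp(mu * times / 60), carryingCapacity)
    if (noiseCv > 0) {
        sdlog <- sqrt(log(1 + noiseCv^2))
        od <- withSeed(seed, {
            od * stats::rlnorm(length(od), meanlog = -sdlog^2 / 2,
                               sdlog = sdlog)
        })
    }
    GrowthCurve(times, od)
}

#' Expression design for count simulation
#'
#' Describes a gene-by-sample negative-binomial count simulation in which
#' a fixed random subset of genes carries expression shifts whose
#' magnitude scales with a population's fitness gain.  Gene `g` in sample
#' `j` of population `p` has mean
#' `mu_gj = s_j * q_g * 2^(kappa * (W_p - 1) * delta_g)` for planted genes
#' (`delta_g ~ N(0, 1)`, shared across populations) and
#' `mu_gj = s_j * q_g` otherwise, with library-size factors `s_j` drawn
#' log-uniform on `[0.5, 2]` and counts drawn negative-binomially with
#' dispersion `alpha`.  Because every population moves along the same
#' direction in log-expression space with length proportional to
#' `W_p - 1`, centroid dissimilarity in that space is linear in fitness
#' gain by construction.
#'
#' The default populations mirror a single-lineage evolution experiment:
#' an ancestor at relative fitness 1 and five evolved populations at
#' 1.10, 1.16, 1.25, 1.35 and 1.45, two replicates each.
#'
#' @param nGenes number of genes.
#' @param populations data.frame with columns `label`,
#'   `relative_fitness`, `n_replicates` and optionally `lineage` and
#'   `is_ancestor` (default: the population(s) with relative fitness 1).
#' @param baselineMeanlog,baselineSdlog log-normal parameters of the
#'   per-gene baseline means `q_g` (defaults give a median of 150 counts).
#' @param dispersion negative-binomial dispersion `alpha` (0 = Poisson).
#' @param shiftedFraction fraction `f` of genes carrying a planted shift.
#' @param effectScale scale `kappa` of the planted shifts in log2 units
#'   per unit fitness gain.
#' @param seed RNG seed.
#' @return a list of class `ExpressionDesign`.
#' @seealso [simulateCounts()]
#' @export
ExpressionDesign <- function(nGenes = 2000,
                             populations = NULL,
                             baselineMeanlog = log(150),
                             baselineSdlog = 1.2,
                             dispersion = 0.01,
                             shiftedFraction = 0.15,
                             effectScale = 1.5,
                             seed = NULL) {
    if (is.null(populations)) {
        populations <- data.frame(
            label = c("anc", "P1", "P2", "P3", "P4", "P5"),
            relative_fitness = c(1.00, 1.10, 1.16, 1.25, 1.35, 1.45),
            n_replicates = 2L)
    }
    req <- c("label", "relative_fitness", "n_replicates")
    if (!all(req %in% names(populations)))
        stop("'populations' needs columns ", paste(req, collapse = ", "))
    if (!"lineage" %in% names(populations)) populations$lineage <- "WT"
    if (!"is_ancestor" %in% names(populations))
        populations$is_ancestor <- populations$relative_fitness == 1
    if (any(populations$relative_fitness < 1))
        stop("relative fitness must be >= 1 (ancestor = 1 by convention)")
    if (anyDuplicated(populations$label))
        stop("population labels must be unique")
    if (dispersion < 0) stop("'dispersion' must be >= 0")
    if (shiftedFraction < 0 || shiftedFraction > 1)
        stop("'shiftedFraction' must be in [0, 1]")
    if (effectScale > 0 && shiftedFraction * nGenes < 1)
        stop("shiftedFraction * nGenes must be >= 1 when effectScale > 0")
    structure(list(nGenes = as.integer(nGenes), populations = populations,
                   baselineMeanlog = baselineMeanlog,
                   baselineSdlog = baselineSdlog, dispersion = dispersion,
                   shiftedFraction = shiftedFraction,
                   effectScale = effectScale, seed = seed),
              class = "ExpressionDesign")
}

#' Simulate a count matrix with fitness-scaled expression shifts
#'
#' Draws the gene-by-sample count matrix described by an
#' [ExpressionDesign()].  The returned
#' [SummarizedExperiment::SummarizedExperiment] carries the counts in
#' assay `"counts"`, sample metadata (population, replicate, lineage,
#' relative fitness, ancestor flag, and the true library-size factor) in
#' `colData`, and the simulation ground truth (baseline mean, planted
#' flag, effect size) in `rowData`.
#'
#' @param design an [ExpressionDesign()].
#' @param seed RNG seed; overrides the seed stored in the design.
#' @return a `SummarizedExperiment`.
#' @examples
#' se <- simulateCounts(ExpressionDesign(nGenes = 100, seed = 1))
#' SummarizedExperiment::colData(se)
#' @export
simulateCounts <- function(design, seed = design$seed) {
    stopifnot(inherits(design, "ExpressionDesign"))
    pops <- design$populations
    nGenes <- design$nGenes
    withSeed(seed, {
        q <- stats::rlnorm(nGenes, design$baselineMeanlog,
                           design$baselineSdlog)
        nShift <- ceiling(design$shiftedFraction * nGenes)
        shifted <- rep(FALSE, nGenes)
        delta <- rep(0, nGenes)
        if (design$effectScale > 0 && nShift >= 1) {
            idx <- sample.int(nGenes, nShift)
            shifted[idx] <- TRUE
            delta[idx] <- stats::rnorm(nShift)
        }
        nSamples <- sum(pops$n_replicates)
        counts <- matrix(0, nrow = nGenes, ncol = nSamples)
        meta <- vector("list", nSamples)
        j <- 0L
        for (p in seq_len(nrow(pops))) {
            W <- pops$relative_fitness[p]
            for (r in seq_len(pops$n_replicates[p])) {
                j <- j + 1L
                s <- exp(stats::runif(1, log(0.5), log(2)))
                mu <- s * q * 2^(design$effectScale * (W - 1) * delta)
                counts[, j] <- if (design$dispersion == 0)
                    stats::rpois(nGenes, mu)
                else
                    stats::rnbinom(nGenes, mu = mu,
                                   size = 1 / design$dispersion)
                meta[[j]] <- data.frame(
                    sample_id = paste0(pops$label[p], "_r", r),
                    population = pops$label[p], replicate = r,
                    lineage = pops$lineage[p],
                    relative_fitness = W,
                    is_ancestor = pops$is_ancestor[p],
                    size_factor_true = s)
            }
        }
        meta <- do.call(rbind, meta)
        gene_ids <- sprintf("gene%05d", seq_len(nGenes))
        dimnames(counts) <- list(gene_ids, meta$sample_id)
        SummarizedExperiment::SummarizedExperiment(
            assays = list(counts = counts),
            rowData = S4Vectors::DataFrame(
                baseline_mean = q, shifted = shifted, delta = delta,
                row.names = gene_ids),
            colData = S4Vectors::DataFrame(meta, row.names = meta$sample_id))
    })
}
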