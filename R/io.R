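# Readers and writers for the plain-text formats used by the pipeline.

#' Read and write windowed coverage
#'
#' `readCoverageTSV()`/`writeCoverageTSV()` handle a two-column
#' tab-separated layout (`window_start`, `mean_coverage`);
#' `readCoverageBedGraph()`/`writeCoverageBedGraph()` handle bedGraph
#' (chrom, 0-based half-open start/end, value) through `rtracklayer`.
#' Windows must be consecutive and equally spaced (the last may be
#' short).
#'
#' @param path file path.
#' @param cov a [WindowedCoverage-class].
#' @param genomeLength chromosome length in bp; defaults to the end of
#'   the last window.
#' @param chrom chromosome name used when writing bedGraph.
#' @return the readers return a [WindowedCoverage-class]; the writers
#'   return `path` invisibly.
#' @name coverage-io
NULL

#' @rdname coverage-io
#' @export
readCoverageTSV <- function(path, genomeLength = NULL) {
    d <- utils::read.delim(path)
    if (!all(c("window_start", "mean_coverage") %in% names(d)))
        stop("expected columns 'window_start' and 'mean_coverage'")
    d <- d[order(d$window_start), , drop = FALSE]
    window <- if (nrow(d) > 1L) d$window_start[2L] - d$window_start[1L]
              else stop("need at least two windows")
    if (any(abs(diff(d$window_start) - window) > 1e-6))
        stop("windows must be consecutive and equally spaced")
    if (is.null(genomeLength))
        genomeLength <- d$window_start[nrow(d)] + window
    WindowedCoverage(d$mean_coverage, window = window,
                     genomeLength = genomeLength)
}

#' @rdname coverage-io
#' @export
writeCoverageTSV <- function(cov, path) {
    stopifnot(is(cov, "WindowedCoverage"))
    utils::write.table(
        data.frame(window_start = windowStarts(cov),
                   mean_coverage = cov@values),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname coverage-io
#' @export
readCoverageBedGraph <- function(path, genomeLength = NULL) {
    gr <- rtracklayer::import(path, format = "bedGraph")
    gr <- GenomicRanges::sort(gr)
    st <- GenomicRanges::start(gr) - 1L   # back to 0-based
    en <- GenomicRanges::end(gr)
    if (length(gr) < 2L) stop("need at least two windows")
    window <- en[1L] - st[1L]
    if (any(st[-1L] != en[-length(en)]))
        stop("bedGraph windows must be consecutive")
    if (is.null(genomeLength)) genomeLength <- en[length(en)]
    WindowedCoverage(gr$score, window = window, genomeLength = genomeLength)
}

#' @rdname coverage-io
#' @export
writeCoverageBedGraph <- function(cov, path, chrom = "chr") {
    stopifnot(is(cov, "WindowedCoverage"))
    st <- windowStarts(cov)
    en <- pmin(st + cov@window, cov@genomeLength)
    gr <- GenomicRanges::GRanges(
        seqnames = chrom,
        ranges = IRanges::IRanges(start = st + 1, end = en),
        score = cov@values)
    rtracklayer::export(gr, path, format = "bedGraph")
    invisible(path)
}

#' Read and write growth curves
#'
#' Tab-separated layout with columns `time_min` and `od600`.
#'
#' @param path file path.
#' @param curve a [GrowthCurve-class].
#' @return `readGrowthCurveTSV()` returns a [GrowthCurve-class];
#'   `writeGrowthCurveTSV()` returns `path` invisibly.
#' @name growth-io
NULL

#' @rdname growth-io
#' @export
readGrowthCurveTSV <- function(path) {
    d <- utils::read.delim(path)
    if (!all(c("time_min", "od600") %in% names(d)))
        stop("expected columns 'time_min' and 'od600'")
    GrowthCurve(d$time_min, d$od600)
}

#' @rdname growth-io
#' @export
writeGrowthCurveTSV <- function(curve, path) {
    stopifnot(is(curve, "GrowthCurve"))
    utils::write.table(data.frame(time_min = curve@times,
                                  od600 = curve@od),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read and write count matrices with sample metadata
#'
#' Counts are stored as TSV with genes in rows (first column `gene_id`)
#' and one column per sample; metadata as TSV with columns `sample_id`,
#' `population`, `replicate`, `lineage`, `relative_fitness`,
#' `is_ancestor`.  `readCountsTSV()` reassembles a `SummarizedExperiment`
#' when a metadata path is supplied.
#'
#' @param path,metaPath file paths.
#' @param se a `SummarizedExperiment` with a `"counts"` assay.
#' @return `readCountsTSV()` returns a `SummarizedExperiment` (or a bare
#'   matrix when `metaPath` is `NULL`); the writers return their first
#'   path invisibly.
#' @name counts-io
NULL

#' @rdname counts-io
#' @export
readCountsTSV <- function(path, metaPath = NULL) {
    d <- utils::read.delim(path, check.names = FALSE)
    if (names(d)[1L] != "gene_id") stop("first column must be 'gene_id'")
    m <- as.matrix(d[, -1L, drop = FALSE])
    rownames(m) <- d$gene_id
    if (is.null(metaPath)) return(m)
    meta <- utils::read.delim(metaPath)
    if (!"sample_id" %in% names(meta))
        stop("metadata needs a 'sample_id' column")
    if (!setequal(meta$sample_id, colnames(m)))
        stop("metadata samples do not match count matrix columns")
    meta <- meta[match(colnames(m), meta$sample_id), , drop = FALSE]
    SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = m),
        colData = S4Vectors::DataFrame(meta, row.names = meta$sample_id))
}

#' @rdname counts-io
#' @export
writeCountsTSV <- function(se, path, metaPath = NULL) {
    m <- .countsMatrix(se)
    utils::write.table(data.frame(gene_id = rownames(m), m,
                                  check.names = FALSE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(metaPath) && is(se, "SummarizedExperiment")) {
        meta <- as.data.frame(SummarizedExperiment::colData(se))
        utils::write.table(meta, metaPath, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    invisible(path)
}
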