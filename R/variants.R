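# Populational variant tables: parsing, allele-frequency filters,
# codon-level effect classification, per-lineage summaries.

.codonPattern <- "\\(([ACGT]{3})\u2192([ACGT]{3})\\)"

#' Read a populational variant table
#'
#' Reads a tab-separated variant table in the layout produced by
#' population-mode resequencing pipelines: columns `lineage`, `gene`,
#' `annotation`, `mutation`, `allele_frequency`, `description`.  A codon
#' change is extracted from annotations of the form `"R69H (CGC>CAC)"`
#' (with a UTF-8 right arrow between the codons); rows without such a
#' pattern carry `NA` codons.  The mutation class is `"SNP"` for
#' single-base substitutions (arrow-separated single-base mutation strings)
#' and `"DIP"` (deletion/insertion/other polymorphism) otherwise.
#'
#' @param path path to a UTF-8 TSV file with the columns above.
#' @return a data.frame of variant records with additional columns
#'   `mutation_class`, `ref_codon`, `alt_codon`.
#' @examples
#' tab <- readVariantTable(system.file("extdata", "table1_variants.tsv",
#'                                     package = "oriscope"))
#' nrow(tab)
#' @export
readVariantTable <- function(path) {
    d <- utils::read.delim(path, stringsAsFactors = FALSE,
                           fileEncoding = "UTF-8", check.names = FALSE)
    req <- c("lineage", "gene", "annotation", "mutation",
             "allele_frequency", "description")
    miss <- setdiff(req, names(d))
    if (length(miss))
        stop("variant table lacks column(s): ", paste(miss, collapse = ", "))
    d$allele_frequency <- as.numeric(d$allele_frequency)
    bad <- which(!is.finite(d$allele_frequency) |
                 d$allele_frequency <= 0 | d$allele_frequency > 100)
    if (length(bad))
        stop("allele frequency outside (0, 100] in row ", bad[1L])
    snp <- grepl("^[ACGT]\u2192[ACGT]$", d$mutation)
    d$mutation_class <- ifelse(snp, "SNP", "DIP")
    m <- regmatches(d$annotation, regexec(.codonPattern, d$annotation))
    d$ref_codon <- vapply(m, function(x)
        if (length(x) == 3L) x[2L] else NA_character_, character(1))
    d$alt_codon <- vapply(m, function(x)
        if (length(x) == 3L) x[3L] else NA_character_, character(1))
    d
}

#' Write a variant table
#'
#' Writes the core columns of a variant record data.frame as UTF-8 TSV so
#' that [readVariantTable()] round-trips losslessly (derived columns are
#' re-computed on read).
#'
#' @param records a data.frame as returned by [readVariantTable()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeVariantTable <- function(records, path) {
    cols <- c("lineage", "gene", "annotation", "mutation",
              "allele_frequency", "description")
    miss <- setdiff(cols, names(records))
    if (length(miss))
        stop("records lack column(s): ", paste(miss, collapse = ", "))
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    utils::write.table(records[, cols], con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Filter variants by allele frequency
#'
#' Published thresholds mix "over 10%" (strict) with "greater than or
#' equal to 50%" semantics, so the comparison mode is explicit:
#' `mode = "gte"` keeps records with `allele_frequency >= minAF` (the
#' default), `mode = "gt"` keeps strictly greater.  The filter is
#' idempotent and monotone in `minAF`.
#'
#' @param records a variant record data.frame.
#' @param minAF threshold in percent, in `[0, 100]`.
#' @param mode `"gte"` or `"gt"`.
#' @return the filtered data.frame.
#' @export
filterByAF <- function(records, minAF, mode = c("gte", "gt")) {
    mode <- match.arg(mode)
    if (minAF < 0 || minAF > 100) stop("'minAF' must be in [0, 100]")
    keep <- if (mode == "gte") records$allele_frequency >= minAF
            else records$allele_frequency > minAF
    records[keep, , drop = FALSE]
}

#' Classify the protein-level effect of a codon change
#'
#' Translates both codons with the standard genetic code: identical amino
#' acids give `"synonymous"`; a non-stop codon changing to a stop gives
#' `"nonsense"`; any other amino-acid change is `"missense"`.
#'
#' @param refCodon,altCodon length-3 strings over `A`, `C`, `G`, `T`
#'   (vectorized).
#' @return a character vector of `"synonymous"`, `"missense"`,
#'   `"nonsense"`, or `"not_applicable"` for `NA` codon pairs.
#' @examples
#' classifyEffect("CGC", "CAC")   # Arg -> His, missense
#' classifyEffect("TCG", "TAG")   # Ser -> stop, nonsense
#' @export
classifyEffect <- function(refCodon, altCodon) {
    if (length(refCodon) != length(altCodon))
        stop("'refCodon' and 'altCodon' must have the same length")
    out <- rep("not_applicable", length(refCodon))
    have <- !is.na(refCodon) & !is.na(altCodon)
    if (!any(have)) return(out)
    ref <- toupper(refCodon[have])
    alt <- toupper(altCodon[have])
    gc <- Biostrings::GENETIC_CODE
    if (any(!ref %in% names(gc)) || any(!alt %in% names(gc)))
        stop("invalid codon(s): codons must be length-3 over A/C/G/T")
    aaRef <- unname(gc[ref])
    aaAlt <- unname(gc[alt])
    eff <- ifelse(aaRef == aaAlt, "synonymous",
                  ifelse(aaAlt == "*" & aaRef != "*", "nonsense",
                         "missense"))
    out[have] <- eff
    out
}

#' Fraction of fixed mutations
#'
#' The share of records whose allele frequency equals 100% (within
#' floating-point tolerance), overall and per lineage.
#'
#' @param records a non-empty variant record data.frame.
#' @param tol tolerance on the comparison with 100 (default 1e-9).
#' @return a list with `overall` (a fraction in `[0, 1]`) and
#'   `by_lineage` (a named numeric vector).
#' @export
fixedFraction <- function(records, tol = 1e-9) {
    if (!nrow(records)) stop("empty record list")
    fixed <- abs(records$allele_frequency - 100) <= tol
    list(overall = mean(fixed),
         by_lineage = vapply(split(fixed, records$lineage), mean,
                             numeric(1)))
}

#' Per-lineage mutation summary
#'
#' Counts SNPs, DIPs, missense/nonsense/synonymous coding changes and
#' fixed mutations for each lineage.  Counts are exhaustive and
#' non-overlapping within their category; `n` totals the records.
#'
#' @param records a variant record data.frame (possibly empty).
#' @param lineages optional lineage labels to report (adds all-zero rows
#'   for lineages without records).
#' @return a data.frame with one row per lineage and columns `lineage`,
#'   `n`, `snp`, `dip`, `missense`, `nonsense`, `synonymous`, `fixed`.
#' @export
summarizeByLineage <- function(records, lineages = NULL) {
    if (is.null(lineages)) lineages <- unique(records$lineage)
    eff <- classifyEffect(records$ref_codon, records$alt_codon)
    fixed <- abs(records$allele_frequency - 100) <= 1e-9
    rows <- lapply(lineages, function(l) {
        i <- records$lineage == l
        data.frame(lineage = l, n = sum(i),
                   snp = sum(records$mutation_class[i] == "SNP"),
                   dip = sum(records$mutation_class[i] == "DIP"),
                   missense = sum(eff[i] == "missense"),
                   nonsense = sum(eff[i] == "nonsense"),
                   synonymous = sum(eff[i] == "synonymous"),
                   fixed = sum(fixed[i]))
    })
    do.call(rbind, rows)
}
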