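#' Construct a PoolCallSet
#'
#' Builds the central container for a pooled-sequencing SNV call set: one row
#' per biallelic SNV, one column per pool, integer assays of REF- and
#' ALT-supporting read counts, per-variant QUAL and database-membership flag,
#' and the number of diploid individuals per pool.
#'
#' @param chrom Character vector of chromosome names.
#' @param pos Integer vector of 1-based positions.
#' @param ref,alt Single-base REF and ALT alleles (characters in A/C/G/T).
#' @param qual Non-negative numeric caller quality scores (QUAL).
#' @param inDb Logical: is the variant reported in any public database
#'   (1000Genomes, dbSNP, ExAC, ESP)?
#' @param refReads,altReads Integer matrices (variants x pools) of read
#'   counts supporting REF and ALT in each pool.
#' @param poolSize Number of diploid individuals per pool.
#' @param poolNames Optional column (pool) names.
#' @return A [PoolCallSet].
#' @examples
#' cs <- poolCallSet(
#'     chrom = c("1", "1"), pos = c(101L, 202L),
#'     ref = c("A", "G"), alt = c("T", "C"),
#'     qual = c(120, 35), inDb = c(TRUE, FALSE),
#'     refReads = matrix(c(340, 310, 355, 298), nrow = 2),
#'     altReads = matrix(c(12, 5, 9, 4), nrow = 2),
#'     poolSize = 12)
#' cohortAF(cs)
#' @export
poolCallSet <- function(chrom, pos, ref, alt, qual, inDb,
                        refReads, altReads, poolSize,
                        poolNames = NULL) {
    refReads <- as.matrix(refReads)
    altReads <- as.matrix(altReads)
    storage.mode(refReads) <- "integer"
    storage.mode(altReads) <- "integer"
    nv <- length(chrom)
    if (!all(dim(refReads) == dim(altReads)) || nrow(refReads) != nv)
        stop("count matrices must be variants x pools and equal-sized")
    if (is.null(poolNames))
        poolNames <- sprintf("pool%02d", seq_len(ncol(refReads)))
    dimnames(refReads) <- dimnames(altReads) <- NULL
    rr <- GenomicRanges::GRanges(
        seqnames = as.character(chrom),
        ranges = IRanges::IRanges(start = as.integer(pos), width = 1L))
    S4Vectors::mcols(rr) <- S4Vectors::DataFrame(
        ref = as.character(ref), alt = as.character(alt),
        qual = as.numeric(qual), inDb = as.logical(inDb))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(ref = refReads, alt = altReads),
        rowRanges = rr,
        colData = S4Vectors::DataFrame(pool = poolNames,
                                       row.names = poolNames),
        metadata = list(poolSize = as.integer(poolSize)))
    methods::validObject(obj <- methods::new("PoolCallSet", se))
    obj
}

#' Accessors for PoolCallSet objects
#'
#' `refReads()`/`altReads()` return the variants x pools read-count matrices;
#' `qualScores()` the per-variant QUAL vector; `inDb()` the logical
#' database-membership flags; `poolSize()` the number of diploid individuals
#' per pool; `numPools()` the number of pools; `variantKeys()` the canonical
#' `"chrom:pos:ref:alt"` key per variant.
#'
#' @param x A [PoolCallSet].
#' @name poolCallSet
#' @aliases refReads altReads qualScores inDb poolSize numPools variantKeys
NULL

#' @rdname poolCallSet
#' @export
setMethod("refReads", "PoolCallSet", function(x)
    SummarizedExperiment::assay(x, "ref"))

#' @rdname poolCallSet
#' @export
setMethod("altReads", "PoolCallSet", function(x)
    SummarizedExperiment::assay(x, "alt"))

#' @rdname poolCallSet
#' @export
setMethod("qualScores", "PoolCallSet", function(x)
    SummarizedExperiment::rowData(x)$qual)

#' @rdname poolCallSet
#' @export
setMethod("inDb", "PoolCallSet", function(x)
    SummarizedExperiment::rowData(x)$inDb)

#' @rdname poolCallSet
#' @export
setMethod("poolSize", "PoolCallSet", function(x)
    S4Vectors::metadata(x)$poolSize)

#' @rdname poolCallSet
#' @export
setMethod("numPools", "PoolCallSet", function(x) ncol(x))

#' @rdname poolCallSet
#' @export
setMethod("variantKeys", "PoolCallSet", function(x) {
    rd <- SummarizedExperiment::rowData(x)
    makeKeys(as.character(GenomicRanges::seqnames(x)),
             GenomicRanges::start(x), rd$ref, rd$alt)
})

setMethod("show", "PoolCallSet", function(object) {
    cat("PoolCallSet with", nrow(object), "SNVs across",
        ncol(object), "pools\n")
    cat("  pool size:", poolSize(object), "diploid individuals",
        sprintf("(AF lattice step 1/%d)\n", 2L * poolSize(object)))
    if (nrow(object) > 0L) {
        cat(sprintf("  in.db: %d | novel: %d\n",
                    sum(inDb(object)), sum(!inDb(object))))
        q <- qualScores(object)
        cat(sprintf("  QUAL range: [%.4g, %.4g]\n", min(q), max(q)))
    }
    invisible(NULL)
})
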