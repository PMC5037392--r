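#' PoolCallSet: a pooled-sequencing variant call set
#'
#' `PoolCallSet` extends
#' [SummarizedExperiment::RangedSummarizedExperiment] to hold a biallelic SNV
#' call set for a cohort of DNA pools. Rows are variants, columns are pools.
#' Two integer assays, `"ref"` and `"alt"`, carry the per-pool read counts
#' supporting the reference and alternative allele. Per-variant metadata
#' (`rowData`) carries the REF/ALT bases, the caller quality score `qual`,
#' and the database-membership flag `inDb` (present in any public variant
#' database such as 1000Genomes, dbSNP, ExAC or ESP). The number of diploid
#' individuals per pool is stored in `metadata(x)$poolSize`.
#'
#' Validity requires: non-negative integer counts in both assays; single-base
#' REF and ALT with REF != ALT; `qual >= 0`; a logical `inDb`; a unique
#' (chrom, pos, ref, alt) key per row; and `poolSize >= 1`.
#'
#' @seealso [poolCallSet()] the constructor, [readCallSet()], [writeCallSet()]
#' @aliases PoolCallSet-class
#' @exportClass PoolCallSet
setClass("PoolCallSet", contains = "RangedSummarizedExperiment")

.validPoolCallSet <- function(object) {
    msg <- character()
    if (!all(c("ref", "alt") %in% SummarizedExperiment::assayNames(object)))
        return("assays 'ref' and 'alt' are required")
    ref <- SummarizedExperiment::assay(object, "ref")
    alt <- SummarizedExperiment::assay(object, "alt")
    if (!is.numeric(ref) || !is.numeric(alt))
        msg <- c(msg, "read-count assays must be numeric")
    else if (any(ref < 0, na.rm = TRUE) || any(alt < 0, na.rm = TRUE))
        msg <- c(msg, "read counts must be non-negative")
    rd <- SummarizedExperiment::rowData(object)
    need <- c("ref", "alt", "qual", "inDb")
    if (!all(need %in% colnames(rd)))
        return(paste("rowData must contain columns:",
                     paste(need, collapse = ", ")))
    if (nrow(object) > 0L) {
        if (!all(rd$ref %in% c("A", "C", "G", "T")) ||
            !all(rd$alt %in% c("A", "C", "G", "T")))
            msg <- c(msg, "REF and ALT must be single bases in {A,C,G,T}")
        if (any(rd$ref == rd$alt))
            msg <- c(msg, "REF and ALT alleles must differ")
        if (!is.numeric(rd$qual) || any(rd$qual < 0))
            msg <- c(msg, "qual must be numeric and >= 0")
        if (!is.logical(rd$inDb))
            msg <- c(msg, "inDb must be logical")
        if (anyDuplicated(variantKeys(object)))
            msg <- c(msg, "duplicated (chrom, pos, ref, alt) variant keys")
    }
    ps <- S4Vectors::metadata(object)$poolSize
    if (is.null(ps) || length(ps) != 1L || is.na(ps) || ps < 1)
        msg <- c(msg, "metadata(x)$poolSize must be a single value >= 1")
    if (length(msg)) msg else TRUE
}
setValidity("PoolCallSet", .validPoolCallSet)

#' Outcome of applying one filter to a PoolCallSet
#'
#' Produced by [applyQf()] and [applyMpf()]. Holds the surviving call set,
#' the keys of fully-removed variants, the total number of (variant, pool)
#' cells whose ALT count was reset to zero (MPF only; always 0 for QF), and
#' the input key universe so that two outcomes can be checked for
#' compatibility before intersection.
#'
#' @slot surviving A [PoolCallSet] of variants passing the filter (MPF:
#'   with per-pool ALT counts after resetting).
#' @slot removedKeys Character vector of fully-removed variant keys.
#' @slot poolResets Integer, number of (variant, pool) ALT cells zeroed.
#' @slot inputKeys Character vector, keys of the input call set.
#' @slot filter `"qf"` or `"mpf"`.
#' @slot threshold The threshold applied (QUAL units for QF, percent for MPF).
#' @aliases FilterOutcome-class
#' @exportClass FilterOutcome
setClass("FilterOutcome",
    representation(surviving = "PoolCallSet", removedKeys = "character",
                   poolResets = "integer", inputKeys = "character",
                   filter = "character", threshold = "numeric"))

setValidity("FilterOutcome", function(object) {
    surv <- variantKeys(object@surviving)
    if (length(intersect(surv, object@removedKeys)))
        return("surviving and removed keys overlap")
    if (!setequal(union(surv, object@removedKeys), object@inputKeys))
        return("surviving + removed keys do not partition the input keys")
    TRUE
})

#' Result of a threshold scan minimising the KS D statistic
#'
#' Produced by [scanThresholds()]. For each candidate threshold the filter
#' was applied, the surviving variants' QUAL scores were stratified into the
#' database-annotated ("in.db") and novel classes, and the two-sample
#' Kolmogorov-Smirnov D statistic between the two QUAL samples was computed.
#' `bestThreshold` is the smallest grid value attaining the minimum defined
#' D (the least aggressive optimal filter). Grid points at which either
#' class became empty carry `NA` and are excluded from the argmin.
#'
#' @slot filter `"qf"` or `"mpf"`.
#' @slot subset Which variants entered the scan: "all", "rare" or "common".
#' @slot grid Numeric vector of candidate thresholds (strictly increasing).
#' @slot dstat D statistic per threshold (`NA` where degenerate).
#' @slot removedInDb,removedNovel Counts of fully-removed variants per class
#'   at each threshold.
#' @slot bestThreshold,bestDstat The argmin threshold and minimum D.
#' @aliases ScanResult-class
#' @exportClass ScanResult
setClass("ScanResult",
    representation(filter = "character", subset = "character",
                   grid = "numeric", dstat = "numeric",
                   removedInDb = "integer", removedNovel = "integer",
                   bestThreshold = "numeric", bestDstat = "numeric"))

#' Benchmark of a call set against an individual-sequencing truth set
#'
#' @slot nCalled Number of pool-seq variants considered.
#' @slot nTp Number of those confirmed by the truth set (true positives).
#' @slot tpRetainedPercent 100 * TP / baseline TP (100 when no baseline).
#' @slot fprPercent 100 * (nCalled - nTp) / nCalled.
#' @aliases TruthComparison-class
#' @exportClass TruthComparison
setClass("TruthComparison",
    representation(nCalled = "integer", nTp = "integer",
                   tpRetainedPercent = "numeric", fprPercent = "numeric"))

#' Allele-frequency concordance summary
#'
#' @slot rSquared Squared Pearson correlation of the paired AFs.
#' @slot deltaStats Named numeric: min, q1, median, mean, q3, max of
#'   (pool AF - reference AF).
#' @slot nPairs Number of AF pairs compared.
#' @aliases ConcordanceSummary-class
#' @exportClass ConcordanceSummary
setClass("ConcordanceSummary",
    representation(rSquared = "numeric", deltaStats = "numeric",
                   nPairs = "integer"))

#' Configuration of the synthetic pooled-sequencing cohort generator
#'
#' See [simConfig()] for field semantics and defaults.
#'
#' @aliases SimConfig-class
#' @exportClass SimConfig
setClass("SimConfig",
    representation(seed = "integer", numPools = "integer",
                   poolSize = "integer", numTrueVariants = "integer",
                   numErrorSites = "integer", rareWeight = "numeric",
                   rareMinAf = "numeric", rareMaxAf = "numeric",
                   commonShape1 = "numeric", commonShape2 = "numeric",
                   meanDepth = "numeric", depthDispersion = "numeric",
                   errorRate = "numeric", errorAltFraction = "numeric",
                   minAltReads = "integer", qualMin = "numeric",
                   trueQualMeanlog = "numeric", trueQualSdlog = "numeric",
                   errQualMeanlog = "numeric", errQualSdlog = "numeric",
                   annotIntercept = "numeric", annotSlope = "numeric",
                   errAnnotProb = "numeric", regionSize = "integer"))

setValidity("SimConfig", function(object) {
    msg <- character()
    chk <- function(cond, text) if (!cond) msg <<- c(msg, text)
    chk(object@numPools >= 1L, "numPools must be >= 1")
    chk(object@poolSize >= 1L, "poolSize must be >= 1")
    chk(object@numTrueVariants >= 0L, "numTrueVariants must be >= 0")
    chk(object@numErrorSites >= 0L, "numErrorSites must be >= 0")
    chk(object@rareWeight >= 0 && object@rareWeight <= 1,
        "rareWeight must be in [0,1]")
    chk(object@errorRate >= 0 && object@errorRate < 0.1,
        "errorRate must be in [0, 0.1)")
    chk(object@errorAltFraction > 0 && object@errorAltFraction <= 1,
        "errorAltFraction must be in (0,1]")
    chk(object@errAnnotProb >= 0 && object@errAnnotProb <= 1,
        "errAnnotProb must be in [0,1]")
    chk(object@meanDepth >= 0, "meanDepth must be >= 0")
    chk(object@depthDispersion > 0, "depthDispersion must be > 0")
    chk(object@minAltReads >= 0L, "minAltReads must be >= 0")
    chk(object@rareMinAf > 0 && object@rareMaxAf <= 1 &&
        object@rareMinAf < object@rareMaxAf,
        "rare AF range must satisfy 0 < min < max <= 1")
    chk(object@regionSize >= object@numTrueVariants + object@numErrorSites,
        "regionSize too small for the requested number of sites")
    if (length(msg)) msg else TRUE
})
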