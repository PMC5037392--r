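#' Benchmark called variants against an individual-sequencing truth set
#'
#' Treats the variants called from individual sequencing of a pool's
#' subjects as true. A called variant present in the truth set is a true
#' positive (TP); the false-positive rate is
#' `FPR = 100 * (called - TP) / called`. When a baseline TP count is given
#' (the TP of the unfiltered call set), the TP retention
#' `100 * TP / baselineTp` is reported; otherwise retention is 100.
#' Percentages are rounded half-up to two decimals.
#'
#' @param calledKeys Nonempty character vector of called variant keys
#'   (`"chrom:pos:ref:alt"`).
#' @param truth Character vector of truth keys (see [readTruthSet()]).
#' @param baselineTp Optional TP count of the unfiltered call set.
#' @return A [TruthComparison].
#' @examples
#' ## a filtered set of 3896 calls of which 3636 are confirmed, against an
#' ## unfiltered baseline of 3772 confirmed calls:
#' keys <- sprintf("1:%d:A:T", 1:3896)
#' truth <- c(keys[1:3636], sprintf("2:%d:A:T", 1:500))
#' compareToTruth(keys, truth, baselineTp = 3772)
#' @export
compareToTruth <- function(calledKeys, truth, baselineTp = NULL) {
    if (!length(calledKeys))
        stop("called set is empty")
    nCalled <- length(calledKeys)
    nTp <- sum(calledKeys %in% truth)
    if (!is.null(baselineTp) && baselineTp <= 0)
        stop("baselineTp must be a positive count")
    retained <- if (is.null(baselineTp)) 100
                else roundHalfUp(100 * nTp / baselineTp, 2L)
    methods::new("TruthComparison",
        nCalled = as.integer(nCalled), nTp = as.integer(nTp),
        tpRetainedPercent = as.numeric(retained),
        fprPercent = roundHalfUp(100 * (nCalled - nTp) / nCalled, 2L))
}

setMethod("show", "TruthComparison", function(object) {
    cat(sprintf(
        "TruthComparison: called %d | TP %d | retained %.2f%% | FPR %.2f%%\n",
        object@nCalled, object@nTp, object@tpRetainedPercent,
        object@fprPercent))
    invisible(NULL)
})

#' @rdname TruthComparison-class
#' @param x A [TruthComparison].
#' @param row.names,optional,... As in [base::as.data.frame()].
#' @method as.data.frame TruthComparison
#' @export
as.data.frame.TruthComparison <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
    data.frame(n_called = x@nCalled, n_tp = x@nTp,
               tp_retained_percent = x@tpRetainedPercent,
               fpr_percent = x@fprPercent)
}

#' Truth benchmark stratified by rare/common allele frequency
#'
#' Splits the call set into common and rare strata by cohort allele
#' frequency and runs [compareToTruth()] for the whole set and per stratum.
#' When benchmarking a filtered call set, pass `af` (the unfiltered cohort
#' AFs, named by variant key) so a variant cannot change stratum because
#' filtering altered its AF, and `baseline` (the comparison of the
#' unfiltered set) so TP retention is reported per stratum.
#'
#' @param cs A [PoolCallSet].
#' @param truth Character vector of truth keys.
#' @param rarityCutoff Rarity cutoff (strict `<`), default 0.01.
#' @param baseline Optional result of a previous call on the unfiltered
#'   call set (a list of [TruthComparison]); its per-stratum TP counts
#'   become the retention baselines.
#' @param af Optional named numeric of cohort AFs to stratify by (defaults
#'   to `cohortAF(cs)`).
#' @return Named list of [TruthComparison] for `"all"`, `"common"` and
#'   `"rare"`; an empty stratum is dropped with a warning.
#' @export
stratifiedTruthComparison <- function(cs, truth, rarityCutoff = 0.01,
                                      baseline = NULL, af = NULL) {
    keys <- variantKeys(cs)
    if (is.null(af)) {
        af <- cohortAF(cs)
        names(af) <- keys
    }
    if (!all(keys %in% names(af)))
        stop("'af' must cover every variant in the call set")
    rarity <- classifyRarity(af[keys], rarityCutoff)
    strata <- list(all = keys,
                   common = keys[rarity == "common"],
                   rare = keys[rarity == "rare"])
    out <- list()
    for (nm in names(strata)) {
        if (!length(strata[[nm]])) {
            warning("empty '", nm, "' stratum dropped")
            next
        }
        base <- if (!is.null(baseline) && !is.null(baseline[[nm]]))
            baseline[[nm]]@nTp else NULL
        out[[nm]] <- compareToTruth(strata[[nm]], truth, baselineTp = base)
    }
    out
}

#' Allele-frequency concordance against a reference AF table
#'
#' Summarises the agreement between pooled-sequencing allele frequencies
#' and reference frequencies (public-database AFs, or AFs from individual
#' genotyping): the coefficient of determination (the squared Pearson
#' correlation of the pairs) and the minimum, quartiles, median, mean and
#' maximum of the differences (pool AF - reference AF).
#'
#' @param poolAF,refAF Paired numeric vectors of allele frequencies in
#'   `[0, 1]`, at least 3 pairs, each with nonzero variance.
#' @return A [ConcordanceSummary].
#' @examples
#' af <- runif(50)
#' afConcordance(af, af)   # perfect agreement: R^2 = 1, all deltas 0
#' @export
afConcordance <- function(poolAF, refAF) {
    if (length(poolAF) != length(refAF))
        stop("poolAF and refAF must be paired")
    ok <- !(is.na(poolAF) | is.na(refAF))
    poolAF <- poolAF[ok]; refAF <- refAF[ok]
    if (length(poolAF) < 3L)
        stop("need at least 3 AF pairs")
    if (any(poolAF < 0 | poolAF > 1 | refAF < 0 | refAF > 1))
        stop("allele frequencies must lie in [0, 1]")
    if (stats::sd(poolAF) == 0 || stats::sd(refAF) == 0)
        stop("zero variance in one coordinate: correlation undefined")
    r2 <- stats::cor(poolAF, refAF)^2
    delta <- poolAF - refAF
    qs <- stats::quantile(delta, c(0.25, 0.5, 0.75), names = FALSE)
    methods::new("ConcordanceSummary",
        rSquared = r2,
        deltaStats = c(min = min(delta), q1 = qs[1L], median = qs[2L],
                       mean = mean(delta), q3 = qs[3L], max = max(delta)),
        nPairs = length(delta))
}

setMethod("show", "ConcordanceSummary", function(object) {
    cat(sprintf("ConcordanceSummary over %d AF pairs: R^2 = %.3f\n",
                object@nPairs, object@rSquared))
    d <- object@deltaStats
    cat(sprintf(
        "  delta (pool - ref): min %.3f | Q1 %.3f | median %.3f | mean %.3f | Q3 %.3f | max %.3f\n",
        d["min"], d["q1"], d["median"], d["mean"], d["q3"], d["max"]))
    invisible(NULL)
})
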