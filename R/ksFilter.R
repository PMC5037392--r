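#' Two-sample Kolmogorov-Smirnov D statistic
#'
#' The D statistic is the supremum over x of the absolute difference of the
#' two empirical cumulative distribution functions, `sup |F_a(x) - F_b(x)|`,
#' evaluated exactly as the maximum over the pooled sample points; ties are
#' handled exactly. `0 <= D <= 1`; lower values indicate more similar
#' distributions. No p-value enters threshold selection, which uses D only.
#'
#' @param a,b Nonempty numeric samples (multisets; ties allowed).
#' @return The D statistic.
#' @examples
#' ksD(1:10, 1:10)          # identical samples: 0
#' ksD(c(1, 2, 3), c(10, 11, 12))  # disjoint supports: 1
#' ksD(c(1, 2), c(1.5, 3))  # 0.5
#' @export
ksD <- function(a, b) {
    a <- as.numeric(a); b <- as.numeric(b)
    if (!length(a) || !length(b))
        stop("both samples must be nonempty")
    if (anyNA(a) || anyNA(b))
        stop("samples must not contain NA")
    pts <- sort(unique(c(a, b)))
    fa <- findInterval(pts, sort(a)) / length(a)
    fb <- findInterval(pts, sort(b)) / length(b)
    max(abs(fa - fb))
}

#' Apply the Quality Filter (QF)
#'
#' The QF removes a variant from all pools when its caller quality score is
#' not strictly greater than the threshold (`QUAL > t` survives, mirroring
#' an ad-hoc "QUAL > 100" style cut). Counts of surviving variants are
#' untouched.
#'
#' @param cs A [PoolCallSet].
#' @param qualThreshold Threshold in QUAL units, `>= 0`.
#' @return A [FilterOutcome].
#' @seealso [applyMpf()], [scanThresholds()], [intersectFilters()]
#' @export
applyQf <- function(cs, qualThreshold) {
    stopifnot(length(qualThreshold) == 1L, qualThreshold >= 0)
    keep <- qualScores(cs) > qualThreshold
    keys <- variantKeys(cs)
    methods::new("FilterOutcome",
        surviving = cs[keep, ],
        removedKeys = keys[!keep],
        poolResets = 0L,
        inputKeys = keys,
        filter = "qf",
        threshold = as.numeric(qualThreshold))
}

#' Apply the Minimum-Percentage-of-reads Filter (MPF)
#'
#' The MPF acts per (variant, pool) cell: ALT read counts strictly below
#' `thPercent` percent of the pool's depth are reset to 0 (see
#' [applyMpfToCounts()]). A variant whose ALT count is zero in every pool
#' afterwards is removed entirely; surviving variants keep their original
#' QUAL and the adjusted counts.
#'
#' @param cs A [PoolCallSet].
#' @param thPercent Threshold in percent, `0 <= thPercent <= 100`.
#' @return A [FilterOutcome]; `poolResets(x)` counts the zeroed cells.
#' @export
applyMpf <- function(cs, thPercent) {
    stopifnot(length(thPercent) == 1L, thPercent >= 0, thPercent <= 100)
    ref <- refReads(cs)
    alt <- altReads(cs)
    reset <- altBelowPercent(ref, alt, thPercent) & alt > 0L
    alt[reset] <- 0L
    keep <- rowSums(alt) > 0L
    keys <- variantKeys(cs)
    surv <- cs[keep, ]
    SummarizedExperiment::assay(surv, "alt") <- alt[keep, , drop = FALSE]
    methods::new("FilterOutcome",
        surviving = surv,
        removedKeys = keys[!keep],
        poolResets = sum(reset),
        inputKeys = keys,
        filter = "mpf",
        threshold = as.numeric(thPercent))
}

#' @rdname FilterOutcome-accessors
#' @title Accessors for FilterOutcome objects
#' @param x A [FilterOutcome].
#' @aliases surviving removedKeys poolResets
#' @export
setMethod("surviving", "FilterOutcome", function(x) x@surviving)

#' @rdname FilterOutcome-accessors
#' @export
setMethod("removedKeys", "FilterOutcome", function(x) x@removedKeys)

#' @rdname FilterOutcome-accessors
#' @export
setMethod("poolResets", "FilterOutcome", function(x) x@poolResets)

setMethod("show", "FilterOutcome", function(object) {
    cat(sprintf("FilterOutcome [%s at %s]: %d of %d variants survive",
                toupper(object@filter), format(object@threshold),
                nrow(object@surviving), length(object@inputKeys)))
    if (object@filter == "mpf")
        cat(sprintf(" (%d pool cells reset)", object@poolResets))
    cat("\n")
    invisible(NULL)
})

#' Default threshold grids for the QF and MPF scans
#'
#' QF: QUAL 20 to 200 in steps of 1 (181 points). MPF: 0% to 5% in steps of
#' 0.1% (51 points). Grid values are generated as integers scaled by the
#' step so no floating-point accumulation drift occurs.
#'
#' @param filter `"qf"` or `"mpf"`.
#' @return Strictly increasing numeric vector.
#' @export
defaultGrid <- function(filter = c("qf", "mpf")) {
    filter <- match.arg(filter)
    if (filter == "qf") as.numeric(20:200) else (0:50) / 10
}

#' Scan filter thresholds minimising the KS D statistic
#'
#' For each candidate threshold the filter (QF or MPF) is applied, the
#' surviving variants' QUAL scores are stratified into database-annotated
#' ("in.db") and novel classes, and the two-sample KS D statistic between
#' the two QUAL samples is computed. The objectively selected cut-off is
#' the threshold minimising D: removing spurious calls (concentrated in the
#' novel, low-quality corner) makes the two distributions maximally
#' similar, while over-filtering buys no further similarity and needlessly
#' discards annotated variants. Ties are broken towards the smallest
#' threshold (the least aggressive filter); grid points at which either
#' class empties get `NA` and are excluded from the argmin with a warning.
#'
#' @param cs A [PoolCallSet] containing both classes.
#' @param filter `"qf"` or `"mpf"`.
#' @param grid Strictly increasing candidate thresholds; defaults to
#'   [defaultGrid()] for the chosen filter.
#' @param subset Restrict the scan to `"all"` (default), `"rare"` or
#'   `"common"` variants (by unfiltered cohort AF).
#' @param rarityCutoff Cutoff for the restriction, default 0.01.
#' @return A [ScanResult].
#' @examples
#' set.seed(7)
#' sim <- simulateCohort(simConfig(seed = 7, numPools = 10,
#'     numTrueVariants = 150, numErrorSites = 400))
#' scanThresholds(sim$callSet, "qf", grid = as.numeric(20:60))
#' @export
scanThresholds <- function(cs, filter = c("qf", "mpf"), grid = NULL,
                           subset = c("all", "rare", "common"),
                           rarityCutoff = 0.01) {
    filter <- match.arg(filter)
    subset <- match.arg(subset)
    if (is.null(grid)) grid <- defaultGrid(filter)
    grid <- as.numeric(grid)
    if (!length(grid) || is.unsorted(grid, strictly = TRUE))
        stop("grid must be nonempty and strictly increasing")

    if (subset != "all") {
        af <- cohortAF(cs)
        cs <- cs[classifyRarity(af, rarityCutoff) == subset, ]
    }
    quals <- qualScores(cs)
    flag <- inDb(cs)
    nInDb <- sum(flag); nNovel <- sum(!flag)
    if (nInDb == 0L || nNovel == 0L)
        stop("both the in.db and the novel class must be nonempty")

    ng <- length(grid)
    dstat <- rep(NA_real_, ng)
    remInDb <- remNovel <- integer(ng)
    if (filter == "qf") {
        for (i in seq_len(ng)) {
            keep <- quals > grid[i]
            a <- quals[keep & flag]
            b <- quals[keep & !flag]
            remInDb[i] <- nInDb - length(a)
            remNovel[i] <- nNovel - length(b)
            if (length(a) && length(b)) dstat[i] <- ksD(a, b)
        }
    } else {
        ref <- refReads(cs)
        alt <- altReads(cs)
        depth <- ref + alt
        scaledAlt <- alt * 1e8
        for (i in seq_len(ng)) {
            num <- round(grid[i] * 1e6)
            altKept <- !(depth > 0 & scaledAlt < num * depth) & alt > 0L
            keep <- rowSums(altKept) > 0L
            a <- quals[keep & flag]
            b <- quals[keep & !flag]
            remInDb[i] <- nInDb - length(a)
            remNovel[i] <- nNovel - length(b)
            if (length(a) && length(b)) dstat[i] <- ksD(a, b)
        }
    }
    if (all(is.na(dstat)))
        stop("all grid points are degenerate (a class emptied everywhere)")
    if (anyNA(dstat))
        warning(sum(is.na(dstat)), " grid point(s) degenerate (a class ",
                "emptied); excluded from the argmin")
    best <- which.min(dstat)   # first index attaining the minimum
    methods::new("ScanResult", filter = filter, subset = subset,
                 grid = grid, dstat = dstat,
                 removedInDb = remInDb, removedNovel = remNovel,
                 bestThreshold = grid[best], bestDstat = dstat[best])
}

#' @rdname ScanResult-accessors
#' @title Accessors for ScanResult objects
#' @param x A [ScanResult].
#' @aliases bestThreshold bestDstat
#' @export
setMethod("bestThreshold", "ScanResult", function(x) x@bestThreshold)

#' @rdname ScanResult-accessors
#' @export
setMethod("bestDstat", "ScanResult", function(x) x@bestDstat)

#' @rdname ScanResult-accessors
#' @param row.names,optional,... As in [base::as.data.frame()].
#' @method as.data.frame ScanResult
#' @export
as.data.frame.ScanResult <- function(x, row.names = NULL,
                                     optional = FALSE, ...) {
    data.frame(threshold = x@grid, dstat = x@dstat,
               n_in_db_removed = x@removedInDb,
               n_novel_removed = x@removedNovel)
}

setMethod("show", "ScanResult", function(object) {
    cat(sprintf(
        "ScanResult [%s, subset=%s]: %d thresholds in [%s, %s]\n",
        toupper(object@filter), object@subset, length(object@grid),
        format(min(object@grid)), format(max(object@grid))))
    cat(sprintf("  best threshold: %s (Dstat_min = %.4f)\n",
                format(object@bestThreshold), object@bestDstat))
    invisible(NULL)
})

#' Intersect the survivors of the two filters
#'
#' The QF and MPF act at different levels (whole-variant versus per-pool)
#' but do a similar job; a robust call set keeps the variants present in
#' both survivor sets. The result carries the MPF-adjusted per-pool counts
#' and the original QUAL scores.
#'
#' @param qfOut A [FilterOutcome] from [applyQf()].
#' @param mpfOut A [FilterOutcome] from [applyMpf()], derived from the same
#'   input call set.
#' @return A [PoolCallSet] of variants surviving both filters.
#' @export
intersectFilters <- function(qfOut, mpfOut) {
    stopifnot(methods::is(qfOut, "FilterOutcome"),
              methods::is(mpfOut, "FilterOutcome"))
    if (qfOut@filter == "mpf" && mpfOut@filter == "qf") {
        tmp <- qfOut; qfOut <- mpfOut; mpfOut <- tmp
    }
    if (!setequal(qfOut@inputKeys, mpfOut@inputKeys))
        stop("the two outcomes come from different input call sets")
    qfKeys <- variantKeys(surviving(qfOut))
    mpf <- surviving(mpfOut)
    mpf[variantKeys(mpf) %in% qfKeys, ]
}
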