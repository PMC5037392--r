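#' Stratify quality scores by database membership
#'
#' Splits a call set's QUAL values into the two samples that feed the
#' Kolmogorov-Smirnov comparison: variants annotated in at least one public
#' database ("in.db") versus variants absent from all of them ("novel").
#' Optionally the call set is first restricted to rare or common variants
#' by cohort allele frequency. Because presence in a public database and
#' the caller's quality score are independent parameters, the two QUAL
#' distributions are expected to be similar for a clean call set; spurious
#' calls concentrate in the novel class and pull the distributions apart.
#'
#' @param cs A [PoolCallSet].
#' @param subset `"all"` (default), `"rare"` or `"common"`; restriction by
#'   [classifyRarity()] on the cohort AF.
#' @param rarityCutoff Rarity cutoff for the restriction (default 0.01).
#' @param af Optional precomputed cohort AF vector aligned with `cs` (used
#'   so a filtered call set can be stratified by its unfiltered AFs).
#' @return A list with numeric components `inDb` and `novel` (class
#'   `"StratifiedQuals"`). An empty class is an error ("degenerate
#'   stratification"): the KS statistic is undefined.
#' @examples
#' cs <- poolCallSet(rep("1", 5), 1:5 * 100L, rep("A", 5), rep("T", 5),
#'                   qual = c(50, 60, 70, 20, 30),
#'                   inDb = c(TRUE, TRUE, TRUE, FALSE, FALSE),
#'                   refReads = matrix(300, 5, 2),
#'                   altReads = matrix(30, 5, 2), poolSize = 12)
#' stratifyQuals(cs)
#' @export
stratifyQuals <- function(cs, subset = c("all", "rare", "common"),
                          rarityCutoff = 0.01, af = NULL) {
    subset <- match.arg(subset)
    keep <- rep(TRUE, nrow(cs))
    if (subset != "all") {
        if (is.null(af)) af <- cohortAF(cs)
        keep <- classifyRarity(af, rarityCutoff) == subset
    }
    quals <- qualScores(cs)[keep]
    flag <- inDb(cs)[keep]
    out <- structure(list(inDb = quals[flag], novel = quals[!flag]),
                     class = "StratifiedQuals")
    if (!length(out$inDb) || !length(out$novel))
        stop("degenerate stratification: the '",
             if (length(out$inDb)) "novel" else "in.db",
             "' class is empty (KS statistic undefined)")
    out
}

#' @export
print.StratifiedQuals <- function(x, ...) {
    cat("StratifiedQuals: in.db n =", length(x$inDb),
        "| novel n =", length(x$novel), "\n")
    invisible(x)
}

#' Percentage of variants removed by a filter
#'
#' `100 * (before - after) / before`, reported to two decimals (half-up),
#' the convention used when quoting class losses such as "7.69% of the
#' annotated variants removed".
#'
#' @param before Count before filtering (> 0).
#' @param after Count after filtering, `0 <= after <= before`.
#' @return Percentage removed, rounded to 2 decimals.
#' @examples
#' removalPercent(6359, 6359 - 489)    # 7.69
#' @export
removalPercent <- function(before, after) {
    if (any(before <= 0))
        stop("'before' must be positive")
    if (any(after < 0 | after > before))
        stop("'after' must satisfy 0 <= after <= before")
    roundHalfUp(100 * (before - after) / before, 2L)
}
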