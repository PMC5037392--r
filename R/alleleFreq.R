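#' Allele frequencies from pooled read counts
#'
#' The allele frequency of a variant inside one pool is the fraction of
#' reads supporting the alternative allele, `alt / (ref + alt)`; it is
#' undefined (`NA`) for a pool with zero depth. The cohort allele frequency
#' (poolAF) is the unweighted arithmetic mean of the per-pool AFs.
#'
#' @param x A [PoolCallSet], or a numeric vector/matrix of REF read counts
#'   (in which case `alt` must be supplied with matching shape).
#' @param alt ALT read counts (only for the numeric method).
#' @param zeroDepth How a zero-depth pool enters the cohort mean:
#'   `"exclude"` (default; the pool is dropped from the mean) or `"zero"`
#'   (counted as AF 0).
#' @param ... Passed between methods.
#' @return `perPoolAF`: numeric of the same shape as the counts, `NA` at
#'   zero depth. `cohortAF`: numeric vector, one value in `[0, 1]` per
#'   variant; a variant with no covered pool is an error.
#' @examples
#' perPoolAF(96, 4)               # 0.04
#' cs <- poolCallSet("1", 101L, "A", "T", 50, FALSE,
#'                   refReads = matrix(c(100, 50), 1),
#'                   altReads = matrix(c(0, 50), 1), poolSize = 12)
#' cohortAF(cs)                   # mean of 0 and 0.5 = 0.25
#' @name alleleFrequencies
NULL

.perPoolAF <- function(ref, alt) {
    if (any(dim(ref) %||% length(ref) != (dim(alt) %||% length(alt))))
        stop("ref and alt counts must have the same shape")
    depth <- ref + alt
    out <- alt / depth
    out[depth == 0] <- NA_real_
    out
}

#' @rdname alleleFrequencies
#' @export
setMethod("perPoolAF", "numeric", function(x, alt, ...) {
    if (missing(alt)) stop("supply matching 'alt' counts")
    .perPoolAF(x, alt)
})

#' @rdname alleleFrequencies
#' @export
setMethod("perPoolAF", "matrix", function(x, alt, ...) {
    if (missing(alt)) stop("supply matching 'alt' counts")
    .perPoolAF(x, alt)
})

#' @rdname alleleFrequencies
#' @export
setMethod("perPoolAF", "PoolCallSet", function(x, ...) {
    ref <- refReads(x)
    alt <- altReads(x)
    depth <- ref + alt
    out <- alt / depth
    out[depth == 0] <- NA_real_
    out
})

#' @rdname alleleFrequencies
#' @export
setMethod("cohortAF", "PoolCallSet", function(x,
        zeroDepth = c("exclude", "zero"), ...) {
    zeroDepth <- match.arg(zeroDepth)
    af <- perPoolAF(x)
    if (zeroDepth == "zero") af[is.na(af)] <- 0
    covered <- rowSums(!is.na(af))
    if (any(covered == 0L))
        stop("no coverage in any pool for variant(s): ",
             paste(utils::head(variantKeys(x)[covered == 0L], 3L),
                   collapse = ", "))
    rowMeans(af, na.rm = TRUE)
})

#' Reset sub-threshold ALT read counts (MPF recalculation rule)
#'
#' Implements the Minimum-Percentage-of-reads Filter at the level of one
#' (variant, pool) count cell: if the pool's ALT reads make up strictly less
#' than `thPercent` percent of its depth, the ALT count is reset to 0 (the
#' reads are assumed to be sequencing errors); otherwise the counts are
#' unchanged. The comparison `100 * alt / depth < thPercent` is performed in
#' exact integer arithmetic so grid thresholds such as 2.6 behave exactly at
#' lattice boundaries.
#'
#' @param ref,alt Non-negative integer vectors or matrices of read counts.
#' @param thPercent Threshold in percent, in `[0, 100]`.
#' @return A list with components `ref` and `alt` after resetting.
#' @examples
#' applyMpfToCounts(395, 5, 2.6)$alt    # 1.25% < 2.6% -> 0
#' applyMpfToCounts(388, 12, 2.6)$alt   # 3.0% >= 2.6% -> unchanged (12)
#' @export
applyMpfToCounts <- function(ref, alt, thPercent) {
    stopifnot(thPercent >= 0, thPercent <= 100)
    reset <- altBelowPercent(ref, alt, thPercent)
    alt[reset] <- 0L
    list(ref = ref, alt = alt)
}

#' Attainable allele frequencies in a pool of diploid individuals
#'
#' A pool of `n` diploids carries `2n` autosomal chromosomes, so the ideal
#' per-pool allele frequencies form the lattice `{0, 1, ..., 2n} / (2n)`.
#' The smallest nonzero value, `1/(2n)`, is the lower detection limit for a
#' variant allele in a single pool (about 0.04 for `n = 12`).
#'
#' @param n Pool size (diploid individuals), `n >= 1`.
#' @return Strictly increasing numeric vector of length `2n + 1`.
#' @examples
#' afLattice(1)    # 0, 0.5, 1 : absent, heterozygous, homozygous
#' afLattice(12)[2] # 1/24, the single-pool detection limit
#' @export
afLattice <- function(n) {
    if (length(n) != 1L || is.na(n) || n < 1 || n != floor(n))
        stop("pool size n must be a single integer >= 1")
    (0:(2L * as.integer(n))) / (2 * n)
}

#' Classify variants as rare or common by allele frequency
#'
#' A variant is rare when its cohort allele frequency is strictly below the
#' cutoff (default 0.01).
#'
#' @param af Numeric vector of allele frequencies in `[0, 1]`.
#' @param cutoff Rarity cutoff (strict `<`), default 0.01.
#' @return Character vector, `"rare"` or `"common"`.
#' @examples
#' classifyRarity(c(0.009, 0.01))  # "rare", "common"
#' @export
classifyRarity <- function(af, cutoff = 0.01) {
    stopifnot(all(af >= 0 & af <= 1, na.rm = TRUE))
    ifelse(af < cutoff, "rare", "common")
}
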