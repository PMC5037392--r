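#' Configure the synthetic pooled-sequencing cohort generator
#'
#' The generator emulates the statistical structure a Pool-seq filtering
#' guideline relies on: true variants segregating in pools of diploid
#' individuals, error-born spurious sites concentrated at low allele
#' frequency and low quality, and partial database annotation. Defaults
#' describe a cohort of 83 pools of 12 diploids sequenced to a mean depth
#' of 352x with a per-base error rate of 0.005, a true-AF mixture skewed so
#' that about 80\% of true variants are rare (cohort AF < 0.01), and an
#' error:true site ratio chosen so roughly half of the emitted variants are
#' spurious before filtering.
#'
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @param numPools Number of pools (default 83).
#' @param poolSize Diploid individuals per pool (default 12).
#' @param numTrueVariants Number of segregating sites drawn from the true-AF
#'   mixture (default 3000).
#' @param numErrorSites Number of pure-error sites offered to the caller
#'   floor (default 12000; only those reaching `minAltReads` somewhere are
#'   emitted).
#' @param rareWeight Mixture weight of the rare component (default 0.8).
#' @param rareMinAf,rareMaxAf Support of the rare component; the population
#'   AF is drawn log-uniformly on this interval (defaults 5e-4 and 0.01).
#' @param commonShape1,commonShape2 Beta shape parameters of the common
#'   component, rescaled to (`rareMaxAf`, 1) (defaults 0.6, 1.8).
#' @param meanDepth,depthDispersion Negative-binomial per-pool depth model:
#'   mean and size (defaults 352 and 10); `depthDispersion = Inf` fixes
#'   every pool's depth at `round(meanDepth)`.
#' @param errorRate Per-base sequencing error rate epsilon (default 0.005).
#' @param errorAltFraction Fraction rho of errors producing the called ALT
#'   base (default 1/3: an error is any of the three non-REF bases).
#' @param minAltReads Caller emission floor: a site is emitted only if some
#'   pool has at least this many ALT reads (default 4).
#' @param qualMin Minimum emitted QUAL (default 20).
#' @param trueQualMeanlog,trueQualSdlog Log-normal QUAL model for true
#'   variants (defaults `log(1200)` and 1.0).
#' @param errQualMeanlog,errQualSdlog Log-normal QUAL model for error
#'   variants (defaults `log(40)` and 0.4). The QUAL model is a stand-in
#'   distribution, not a reimplementation of any caller's scoring.
#' @param annotIntercept,annotSlope Logistic model of the probability that
#'   a true variant is database-annotated,
#'   `plogis(annotIntercept + annotSlope * log10(AF))` (defaults 1.8, 1.1:
#'   increasing with AF, about 30\% for rare variants).
#' @param errAnnotProb Probability an error variant is annotated (default 0).
#' @param regionSize Size of the simulated target region in bp
#'   (default 1.9e6); positions are drawn without replacement.
#' @return A validated [SimConfig].
#' @seealso [simulateCohort()], [expectedSpuriousRate()]
#' @export
simConfig <- function(seed = 1L,
                      numPools = 83L,
                      poolSize = 12L,
                      numTrueVariants = 3000L,
                      numErrorSites = 12000L,
                      rareWeight = 0.8,
                      rareMinAf = 5e-4,
                      rareMaxAf = 0.01,
                      commonShape1 = 0.6,
                      commonShape2 = 1.8,
                      meanDepth = 352,
                      depthDispersion = 10,
                      errorRate = 0.005,
                      errorAltFraction = 1 / 3,
                      minAltReads = 4L,
                      qualMin = 20,
                      trueQualMeanlog = log(1200),
                      trueQualSdlog = 1.0,
                      errQualMeanlog = log(40),
                      errQualSdlog = 0.4,
                      annotIntercept = 1.8,
                      annotSlope = 1.1,
                      errAnnotProb = 0,
                      regionSize = 1900000L) {
    methods::new("SimConfig",
        seed = as.integer(seed), numPools = as.integer(numPools),
        poolSize = as.integer(poolSize),
        numTrueVariants = as.integer(numTrueVariants),
        numErrorSites = as.integer(numErrorSites),
        rareWeight = rareWeight, rareMinAf = rareMinAf,
        rareMaxAf = rareMaxAf, commonShape1 = commonShape1,
        commonShape2 = commonShape2, meanDepth = meanDepth,
        depthDispersion = depthDispersion, errorRate = errorRate,
        errorAltFraction = errorAltFraction,
        minAltReads = as.integer(minAltReads), qualMin = qualMin,
        trueQualMeanlog = trueQualMeanlog, trueQualSdlog = trueQualSdlog,
        errQualMeanlog = errQualMeanlog, errQualSdlog = errQualSdlog,
        annotIntercept = annotIntercept, annotSlope = annotSlope,
        errAnnotProb = errAnnotProb, regionSize = as.integer(regionSize))
}

setMethod("show", "SimConfig", function(object) {
    cat(sprintf(
        "SimConfig: %d pools x %d diploids | %d true + %d error sites\n",
        object@numPools, object@poolSize, object@numTrueVariants,
        object@numErrorSites))
    cat(sprintf(
        "  depth ~ NB(mu=%.0f, size=%.1f) | error rate %.4g | seed %d\n",
        object@meanDepth, object@depthDispersion, object@errorRate,
        object@seed))
    invisible(NULL)
})

#' Simulate a pooled-sequencing cohort with ground truth
#'
#' For each true site a population AF `p` is drawn from the rare/common
#' mixture; each pool receives `k ~ Binomial(2n, p)` allele copies and a
#' negative-binomial depth `d`; the pool's ALT read count is
#' `Binomial(d, f(1-eps) + (1-f) eps rho)` with `f = k/(2n)`, so a carrier
#' pool's reads are perturbed and a non-carrier pool sees only errors.
#' Pure-error sites have `k = 0` in every pool. Sites whose ALT count stays
#' below `minAltReads` in every pool are suppressed (the caller's emission
#' floor). QUAL is drawn from the class-specific log-normal model and
#' database membership from the AF-dependent annotation model. A drawn
#' "true" site that received zero allele copies in the whole cohort is
#' bookkept as not true: only sequencing errors can put it in the output.
#'
#' @param cfg A [SimConfig].
#' @return A list: `callSet` (a [PoolCallSet] of the emitted variants),
#'   `truth` (data.frame with key, chrom, pos, ref, alt, isTrue, trueAF,
#'   inDb for each emitted variant; `trueAF` is total allele copies over
#'   `2n * numPools`) and `copies` (matrix of per-pool true allele copies
#'   for the emitted variants).
#' @examples
#' sim <- simulateCohort(simConfig(seed = 42, numPools = 8,
#'     numTrueVariants = 100, numErrorSites = 300))
#' sim$callSet
#' table(sim$truth$isTrue)
#' @export
simulateCohort <- function(cfg) {
    methods::validObject(cfg)
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        oldSeed <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", oldSeed, envir = globalenv()))
    }
    set.seed(cfg@seed)

    nP <- cfg@numPools
    n2 <- 2L * cfg@poolSize
    nT <- cfg@numTrueVariants
    nE <- cfg@numErrorSites
    nS <- nT + nE
    if (nS == 0L) stop("no sites requested")

    pos <- sort(sample.int(cfg@regionSize, nS))
    bases <- c("A", "C", "G", "T")
    refB <- sample(bases, nS, replace = TRUE)
    altB <- vapply(refB, function(r) sample(setdiff(bases, r), 1L), "")
    isTrueSite <- sample(rep(c(TRUE, FALSE), c(nT, nE)))

    ## population AF of the drawn true sites (rare/common mixture)
    p <- numeric(nS)
    if (nT > 0L) {
        rare <- stats::runif(nT) < cfg@rareWeight
        pr <- exp(stats::runif(nT, log(cfg@rareMinAf),
                               log(cfg@rareMaxAf)))
        pc <- cfg@rareMaxAf +
            (1 - cfg@rareMaxAf) * stats::rbeta(nT, cfg@commonShape1,
                                               cfg@commonShape2)
        p[isTrueSite] <- ifelse(rare, pr, pc)
    }

    copies <- matrix(0L, nrow = nS, ncol = nP)
    copies[isTrueSite, ] <- stats::rbinom(nT * nP, n2,
                                          rep(p[isTrueSite], nP))
    depth <- if (is.finite(cfg@depthDispersion))
        matrix(stats::rnbinom(nS * nP, mu = cfg@meanDepth,
                              size = cfg@depthDispersion), nrow = nS)
    else matrix(round(cfg@meanDepth), nrow = nS, ncol = nP)
    f <- copies / n2
    er <- cfg@errorRate * cfg@errorAltFraction
    pAlt <- f * (1 - cfg@errorRate) + (1 - f) * er
    alt <- matrix(stats::rbinom(nS * nP, as.vector(depth),
                                as.vector(pAlt)), nrow = nS)
    ref <- depth - alt

    trueAF <- rowSums(copies) / (n2 * nP)
    isTrue <- trueAF > 0
    qual <- pmax(cfg@qualMin, ifelse(isTrue,
        stats::rlnorm(nS, cfg@trueQualMeanlog, cfg@trueQualSdlog),
        stats::rlnorm(nS, cfg@errQualMeanlog, cfg@errQualSdlog)))
    pAnnot <- ifelse(isTrue,
        stats::plogis(cfg@annotIntercept +
                      cfg@annotSlope * log10(pmax(trueAF, 1e-12))),
        cfg@errAnnotProb)
    inDbFlag <- stats::runif(nS) < pAnnot

    emit <- rowSums(alt >= cfg@minAltReads) > 0L
    if (!any(emit))
        stop("no site reached the emission floor; increase depth, error ",
             "rate or the number of sites")

    cs <- poolCallSet(chrom = rep("1", sum(emit)), pos = pos[emit],
                      ref = refB[emit], alt = altB[emit],
                      qual = qual[emit], inDb = inDbFlag[emit],
                      refReads = ref[emit, , drop = FALSE],
                      altReads = alt[emit, , drop = FALSE],
                      poolSize = cfg@poolSize)
    truth <- data.frame(
        key = makeKeys("1", pos[emit], refB[emit], altB[emit]),
        chrom = "1", pos = pos[emit], ref = refB[emit], alt = altB[emit],
        isTrue = isTrue[emit], trueAF = trueAF[emit],
        inDb = inDbFlag[emit], stringsAsFactors = FALSE)
    list(callSet = cs, truth = truth,
         copies = copies[emit, , drop = FALSE])
}

#' Analytic emission rate of pure-error sites
#'
#' Probability that a site carrying no variant allele reaches the caller's
#' emission floor (`minAltReads` ALT reads, default 4) through sequencing
#' errors alone. At fixed depth `d` the per-pool probability is
#' `1 - BinomCDF(minAltReads - 1; d, eps * rho)`; the depth model is
#' averaged by enumeration over the negative-binomial mass. By default the
#' site-level rate across the cohort's independent pools is returned,
#' `1 - (1 - perPoolRate)^numPools`; with `perPool = TRUE` the per-pool
#' rate itself.
#'
#' @param cfg A [SimConfig].
#' @param perPool Return the single-pool rate instead of the site-level
#'   cohort rate.
#' @return A probability.
#' @examples
#' cfg <- simConfig()
#' expectedSpuriousRate(cfg)                # site level, default cohort
#' expectedSpuriousRate(cfg, perPool = TRUE)
#' @export
expectedSpuriousRate <- function(cfg, perPool = FALSE) {
    methods::validObject(cfg)
    er <- cfg@errorRate * cfg@errorAltFraction
    if (er == 0) return(0)
    if (is.finite(cfg@depthDispersion)) {
        dmax <- stats::qnbinom(1 - 1e-12, mu = cfg@meanDepth,
                               size = cfg@depthDispersion)
        d <- 0:dmax
        w <- stats::dnbinom(d, mu = cfg@meanDepth,
                            size = cfg@depthDispersion)
        w <- w / sum(w)
    } else {                    # fixed per-pool depth
        d <- round(cfg@meanDepth)
        w <- 1
    }
    poolMiss <- sum(w * stats::pbinom(cfg@minAltReads - 1L, d, er))
    if (perPool) 1 - poolMiss else 1 - poolMiss^cfg@numPools
}
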