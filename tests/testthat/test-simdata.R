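test_that("the generator is deterministic given a seed", {
    cfg <- smallSimConfig(seed = 77)
    s1 <- simulateCohort(cfg)
    s2 <- simulateCohort(cfg)
    expect_identical(s1$truth, s2$truth)
    expect_identical(refReads(s1$callSet), refReads(s2$callSet))
    expect_identical(altReads(s1$callSet), altReads(s2$callSet))
    p1 <- withr::local_tempfile(fileext = ".vcf")
    p2 <- withr::local_tempfile(fileext = ".vcf")
    writeCallSet(s1$callSet, p1)
    writeCallSet(s2$callSet, p2)
    expect_identical(readLines(p1), readLines(p2))
    ## a different seed gives a different cohort
    s3 <- simulateCohort(smallSimConfig(seed = 78))
    expect_false(identical(refReads(s1$callSet), refReads(s3$callSet)))
    ## and the caller's RNG stream is left untouched
    set.seed(1); before <- runif(1)
    set.seed(1); invisible(simulateCohort(cfg)); after <- runif(1)
    expect_identical(before, after)
})

test_that("invalid configurations are rejected with named fields", {
    expect_error(simConfig(errorRate = 0.5), "errorRate")
    expect_error(simConfig(numPools = 0), "numPools")
    expect_error(simConfig(rareWeight = 1.5), "rareWeight")
    expect_error(simConfig(depthDispersion = 0), "depthDispersion")
})

test_that("without sequencing errors every emitted variant is true", {
    sim <- simulateCohort(smallSimConfig(seed = 41, errorRate = 0,
                                         numErrorSites = 0))
    expect_true(all(sim$truth$isTrue))
    ## FPR against the generator's truth is exactly 0
    cmp <- compareToTruth(variantKeys(sim$callSet),
                          sim$truth$key[sim$truth$isTrue])
    expect_identical(cmp@fprPercent, 0)
    ## per-pool AF deviates from k/(2n) only by binomial read sampling
    f <- sim$copies / (2 * poolSize(sim$callSet))
    af <- perPoolAF(sim$callSet)
    depth <- refReads(sim$callSet) + altReads(sim$callSet)
    ok <- !is.na(af) & depth > 50
    se <- sqrt(pmax(f * (1 - f), 1e-6) / pmax(depth, 1))
    expect_gt(mean((abs(af - f) <= 5 * se)[ok]), 0.98)
})

test_that("per-pool allele copies follow Binomial(2n, p)", {
    ## pin the population AF at p ~ 0.25 by a degenerate rare interval;
    ## the mean over 200 seeded replicates of the per-pool copies must sit
    ## within 3 standard errors of 2 * 12 * 0.25 = 6
    copies <- unlist(lapply(seq_len(200), function(s) {
        sim <- simulateCohort(simConfig(seed = 3000L + s, numPools = 4L,
            numTrueVariants = 5L, numErrorSites = 0L, errorRate = 0,
            rareWeight = 1, rareMinAf = 0.25 - 1e-9,
            rareMaxAf = 0.25 + 1e-9))
        sim$copies
    }))
    mu <- 24 * 0.25
    se <- sqrt(24 * 0.25 * 0.75) / sqrt(length(copies))
    expect_gt(length(copies), 3500)
    expect_lt(abs(mean(copies) - mu), 3 * se)
})

test_that("analytic spurious-site rate matches Monte-Carlo emission", {
    cfg <- simConfig(seed = 55, numPools = 12L, numTrueVariants = 0L,
                     numErrorSites = 600L)
    rate <- expectedSpuriousRate(cfg)
    sim <- simulateCohort(cfg)
    nEmit <- nrow(sim$callSet)
    se <- sqrt(rate * (1 - rate) * 600)
    expect_lt(abs(nEmit - 600 * rate), 3 * se + 1e-9)

    ## the zero-error limit
    expect_identical(expectedSpuriousRate(simConfig(errorRate = 0)), 0)

    ## fixed depth: matches a brute-force binomial tail sum exactly
    cfgF <- simConfig(meanDepth = 400, depthDispersion = Inf,
                      errorRate = 0.003, errorAltFraction = 1 / 3)
    per <- 0.003 / 3
    brute <- 1 - sum(stats::dbinom(0:3, 400, per))
    expect_equal(expectedSpuriousRate(cfgF, perPool = TRUE), brute,
                 tolerance = 1e-12)
})

test_that("the rare/common mixture lands near its design fractions", {
    sim <- simulateCohort(simConfig(seed = 10, numPools = 40,
                                    numTrueVariants = 1500,
                                    numErrorSites = 0))
    rareFrac <- mean(sim$truth$trueAF[sim$truth$isTrue] < 0.01)
    expect_gt(rareFrac, 0.65)
    expect_lt(rareFrac, 0.9)
    ## annotation is increasing in AF: annotated true variants have a
    ## higher median AF than unannotated ones
    tr <- sim$truth[sim$truth$isTrue, ]
    expect_gt(median(tr$trueAF[tr$inDb]), median(tr$trueAF[!tr$inDb]))
})
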