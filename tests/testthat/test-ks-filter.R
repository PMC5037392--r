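test_that("the KS D statistic is exact on worked examples", {
    expect_equal(ksD(c(3, 1, 4, 1, 5), c(3, 1, 4, 1, 5)), 0)
    expect_equal(ksD(c(1, 2, 3), c(10, 11, 12)), 1)
    ## enumerate ECDF differences at pooled points {1, 1.5, 2, 3}:
    ## |.5-0|, |.5-.5|, |1-.5|, |1-1| -> max 0.5
    expect_equal(ksD(c(1, 2), c(1.5, 3)), 0.5)
    expect_error(ksD(numeric(0), 1), "nonempty")
})

test_that("ksD is symmetric and invariant under monotone transforms", {
    withr::with_seed(31, {
        for (i in 1:25) {
            a <- sample(round(rlnorm(sample(3:80, 1), 4, 1)))
            b <- sample(round(rlnorm(sample(3:80, 1), 4.5, 1)))
            d <- ksD(a, b)
            expect_identical(d, ksD(b, a))
            expect_equal(ksD(log1p(a), log1p(b)), d)
            expect_equal(ksD(-b, -a), d)
        }
    })
})

test_that("ksD matches the reference implementation on tied samples", {
    withr::with_seed(42, {
        for (i in 1:200) {
            a <- round(rlnorm(sample(2:150, 1), 4, 1.5))
            b <- round(rlnorm(sample(2:150, 1), 4.3, 1))
            expect_equal(ksD(a, b), refKsD(a, b), tolerance = 1e-12)
        }
    })
})

test_that("the QF keeps variants with QUAL strictly above the threshold", {
    cs <- tinyCallSet(nv = 3L, qual = c(50, 74, 100))
    out <- applyQf(cs, 74)
    expect_equal(qualScores(surviving(out)), 100)
    expect_setequal(removedKeys(out), variantKeys(cs)[1:2])
    ## below-minimum threshold is the identity
    out0 <- applyQf(cs, 10)
    expect_length(removedKeys(out0), 0L)
    expect_identical(variantKeys(surviving(out0)), variantKeys(cs))
})

test_that("QF survivors are monotone in the threshold and QF is idempotent", {
    sim <- simulateCohort(smallSimConfig(seed = 23))
    cs <- sim$callSet
    prev <- NULL
    for (t in c(20, 50, 74, 120, 200)) {
        surv <- variantKeys(surviving(applyQf(cs, t)))
        if (!is.null(prev)) expect_true(all(surv %in% prev))
        prev <- surv
    }
    once <- surviving(applyQf(cs, 74))
    twice <- surviving(applyQf(once, 74))
    expect_identical(variantKeys(twice), variantKeys(once))
})

test_that("the MPF resets cells, removes all-zero variants, keeps QUAL", {
    cs <- poolCallSet(c("1", "1"), c(100L, 200L), c("A", "G"),
                      c("T", "C"), qual = c(80, 90),
                      inDb = c(TRUE, FALSE),
                      refReads = matrix(c(990, 990, 985, 970), 2),
                      altReads = matrix(c(10, 15, 15, 30), 2),
                      poolSize = 12)
    ## variant 1: alt% = {1.0, 1.5} -> both cells reset -> fully removed
    ## variant 2: alt% = {1.5, 3.0} -> pool-1 reset only -> survives
    out <- applyMpf(cs, 2.6)
    expect_equal(removedKeys(out), "1:100:A:T")
    surv <- surviving(out)
    expect_equal(unname(altReads(surv)[1, ]), c(0L, 30L))
    expect_equal(unname(refReads(surv)[1, ]), c(990L, 970L))  # depth kept
    expect_equal(qualScores(surv), 90)
    expect_equal(poolResets(out), 3L)
    ## th = 0 is the identity
    out0 <- applyMpf(cs, 0)
    expect_length(removedKeys(out0), 0L)
    expect_equal(poolResets(out0), 0L)
    expect_identical(altReads(surviving(out0)), altReads(cs))
    ## idempotence at a fixed threshold
    once <- surviving(applyMpf(cs, 2.6))
    again <- applyMpf(once, 2.6)
    expect_length(removedKeys(again), 0L)
    expect_identical(altReads(surviving(again)), altReads(once))
})

test_that("scan grids default to 181 QF and 51 MPF evaluations", {
    expect_length(defaultGrid("qf"), 181L)
    expect_equal(defaultGrid("qf")[c(1, 181)], c(20, 200))
    expect_length(defaultGrid("mpf"), 51L)
    expect_equal(defaultGrid("mpf")[c(1, 51)], c(0, 5))
    expect_identical(defaultGrid("mpf"), (0:50) / 10)
})

test_that("scan Dstat equals the from-scratch composition at every point", {
    sim <- simulateCohort(smallSimConfig(seed = 7))
    cs <- sim$callSet
    qfGrid <- as.numeric(seq(20, 200, by = 20))
    sc <- scanThresholds(cs, "qf", grid = qfGrid)
    for (i in seq_along(qfGrid)) {
        out <- applyQf(cs, qfGrid[i])
        sq <- stratifyQuals(surviving(out))
        expect_equal(sc@dstat[i], ksD(sq$inDb, sq$novel))
        expect_equal(sc@removedInDb[i],
                     sum(inDb(cs)) - length(sq$inDb))
        expect_equal(sc@removedNovel[i],
                     sum(!inDb(cs)) - length(sq$novel))
    }
    mpfGrid <- (0:10) / 2
    sm <- scanThresholds(cs, "mpf", grid = mpfGrid)
    for (i in seq_along(mpfGrid)) {
        out <- applyMpf(cs, mpfGrid[i])
        sq <- stratifyQuals(surviving(out))
        expect_equal(sm@dstat[i], ksD(sq$inDb, sq$novel))
    }
    ## applying the filter once at the best threshold reproduces bestDstat
    outBest <- applyQf(cs, bestThreshold(sc))
    sqBest <- stratifyQuals(surviving(outBest))
    expect_equal(ksD(sqBest$inDb, sqBest$novel), bestDstat(sc))
})

test_that("scan tie-break picks the smallest argmin threshold", {
    ## identical QUAL distributions in both classes and no removals in
    ## range: every Dstat is equal, so the first grid point must win
    qual <- rep(c(500, 600, 700, 800), times = 2)
    cs <- tinyCallSet(nv = 8L, qual = qual,
                      inDb = rep(c(TRUE, FALSE), each = 4L))
    sc <- scanThresholds(cs, "qf", grid = as.numeric(20:40))
    expect_equal(sc@dstat, rep(0, 21))
    expect_equal(bestThreshold(sc), 20)
})

test_that("degenerate grid points get NA and are excluded from the argmin", {
    cs <- tinyCallSet(nv = 6L, qual = c(30, 40, 50, 300, 400, 500),
                      inDb = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
    expect_warning(
        sc <- scanThresholds(cs, "qf", grid = as.numeric(c(25, 60, 100))),
        "degenerate")
    expect_true(is.na(sc@dstat[2]) || is.na(sc@dstat[3]))
    expect_false(is.na(bestDstat(sc)))
})

test_that("intersection keeps MPF counts, original QUAL, and obeys algebra", {
    sim <- simulateCohort(smallSimConfig(seed = 3))
    cs <- sim$callSet
    qf <- applyQf(cs, 74)
    mpf <- applyMpf(cs, 2.6)
    both <- intersectFilters(qf, mpf)
    keys <- variantKeys(both)
    expect_true(all(keys %in% variantKeys(surviving(qf))))
    expect_true(all(keys %in% variantKeys(surviving(mpf))))
    expect_lte(nrow(both), min(nrow(surviving(qf)), nrow(surviving(mpf))))
    ## MPF-adjusted counts and original QUAL carried through
    mpfSurv <- surviving(mpf)
    idx <- match(keys, variantKeys(mpfSurv))
    expect_identical(altReads(both), altReads(mpfSurv)[idx, , drop = FALSE])
    expect_identical(qualScores(both),
                     qualScores(cs)[match(keys, variantKeys(cs))])
    ## counts conserved for each filter
    expect_equal(nrow(surviving(qf)) + length(removedKeys(qf)), nrow(cs))
    expect_equal(nrow(surviving(mpf)) + length(removedKeys(mpf)), nrow(cs))
    ## argument order does not matter
    expect_identical(variantKeys(intersectFilters(mpf, qf)), keys)
    ## mismatched universes are an error
    expect_error(intersectFilters(qf, applyMpf(cs[-1, ], 2.6)),
                 "different input")
})

test_that("an empty survivor set intersects to an empty call set", {
    cs <- tinyCallSet(nv = 4L, qual = c(30, 40, 50, 60))
    qf <- applyQf(cs, 1000)       # removes everything
    mpf <- applyMpf(cs, 0)
    expect_equal(nrow(intersectFilters(qf, mpf)), 0L)
})

test_that("filtering a spurious-heavy cohort lowers the KS distance", {
    ## seeded simulation where error variants have systematically lower
    ## QUAL: the scan-selected QF must bring the in.db and novel QUAL
    ## distributions closer than they were unfiltered
    sim <- simulateCohort(smallSimConfig(seed = 12))
    cs <- sim$callSet
    sq0 <- stratifyQuals(cs)
    d0 <- ksD(sq0$inDb, sq0$novel)
    sc <- scanThresholds(cs, "qf")
    expect_lt(bestDstat(sc), d0)
})
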