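# Shared fixtures: small call sets built in code.

# A deterministic hand-sized call set: nv variants, np pools.
tinyCallSet <- function(nv = 6L, np = 3L, poolSize = 12L,
                        qual = NULL, inDb = NULL, seed = 11L) {
    withr::with_seed(seed, {
        if (is.null(qual)) qual <- round(runif(nv, 20, 500), 2)
        if (is.null(inDb)) inDb <- rep_len(c(TRUE, FALSE), nv)
        ref <- matrix(rpois(nv * np, 300), nv)
        alt <- matrix(rpois(nv * np, 15), nv)
        poolCallSet(chrom = rep("1", nv), pos = seq_len(nv) * 100L,
                    ref = rep_len(c("A", "C", "G", "T"), nv),
                    alt = rep_len(c("T", "G", "A", "C"), nv),
                    qual = qual, inDb = inDb,
                    refReads = ref, altReads = alt, poolSize = poolSize)
    })
}

# A small but structured simulated cohort, cheap enough for many tests.
smallSimConfig <- function(seed = 5L, ...) {
    args <- utils::modifyList(
        list(seed = seed, numPools = 12L, numTrueVariants = 250L,
             numErrorSites = 900L),
        list(...))
    do.call(simConfig, args)
}

# JSON generator config on disk for CLI tests; returns the path.
writeCfg <- function(fields) {
    path <- tempfile(fileext = ".json")
    jsonlite::write_json(fields, path, auto_unbox = TRUE)
    path
}

# Independent reference for the two-sample KS D statistic.
refKsD <- function(a, b) {
    unname(suppressWarnings(stats::ks.test(a, b))$statistic)
}
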