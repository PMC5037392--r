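test_that("PoolCallSet validity enforces the domain invariants", {
    cs <- tinyCallSet()
    expect_s4_class(cs, "PoolCallSet")
    expect_error(
        poolCallSet("1", 1L, "A", "A", 10, FALSE,
                    matrix(1), matrix(1), 12),
        "differ")
    expect_error(
        poolCallSet("1", 1L, "A", "AT", 10, FALSE,
                    matrix(1), matrix(1), 12),
        "single bases")
    expect_error(
        poolCallSet("1", 1L, "A", "T", -5, FALSE,
                    matrix(1), matrix(1), 12),
        "qual")
    expect_error(
        poolCallSet(c("1", "1"), c(1L, 1L), c("A", "A"), c("T", "T"),
                    c(10, 20), c(FALSE, TRUE),
                    matrix(1, 2, 1), matrix(1, 2, 1), 12),
        "duplicated")
})

test_that("a CRISP-style VCF with per-pool allelic depths maps directly", {
    path <- withr::local_tempfile(fileext = ".vcf")
    writeLines(c(
        "##fileformat=VCFv4.2",
        "##poolSize=12",
        paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
               "Description=\"Allelic depths\">"),
        "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tp1\tp2",
        "1\t100\trs1\tA\tT\t74\t.\t.\tAD\t96,4\t300,12",
        "1\t200\t.\tG\tC\t120.5\t.\t.\tAD\t250,0\t180,20",
        "2\t300\t.\tT\tG\t20\t.\t.\tAD\t0,50\t10,10"), path)
    cs <- readCallSet(path)
    expect_equal(nrow(cs), 3L)
    expect_equal(ncol(cs), 2L)
    expect_equal(poolSize(cs), 12L)
    expect_equal(qualScores(cs), c(74, 120.5, 20))
    expect_equal(inDb(cs), c(TRUE, FALSE, FALSE))
    expect_equal(unname(refReads(cs)[1, ]), c(96L, 300L))
    expect_equal(unname(altReads(cs)[, 2]), c(12L, 20L, 10L))
    expect_equal(variantKeys(cs), c("1:100:A:T", "1:200:G:C", "2:300:T:G"))
})

test_that("non-SNV records are excluded and counted; strict mode errors", {
    path <- withr::local_tempfile(fileext = ".vcf")
    writeLines(c(
        "##fileformat=VCFv4.2",
        "##poolSize=12",
        paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
               "Description=\"Allelic depths\">"),
        "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tp1",
        "1\t100\t.\tA\tAT\t50\t.\t.\tAD\t96,4",
        "1\t200\t.\tG\tC\t60\t.\t.\tAD\t250,9"), path)
    expect_message(cs <- readCallSet(path), "1 non-SNV")
    expect_equal(nrow(cs), 1L)
    expect_equal(unname(S4Vectors::metadata(cs)$skipped["nonSnv"]), 1L)
    expect_error(readCallSet(path, strict = TRUE), "non-SNV")
})

test_that("multiallelic records are rejected by default, split on request", {
    path <- withr::local_tempfile(fileext = ".vcf")
    writeLines(c(
        "##fileformat=VCFv4.2",
        "##poolSize=12",
        paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
               "Description=\"Allelic depths\">"),
        "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tp1",
        "1\t100\t.\tA\tT,G\t50\t.\t.\tAD\t90,4,6",
        "1\t200\t.\tG\tC\t60\t.\t.\tAD\t250,9"), path)
    cs <- readCallSet(path)
    expect_equal(nrow(cs), 1L)
    expect_equal(unname(S4Vectors::metadata(cs)$skipped["multiallelic"]), 1L)
    cs2 <- readCallSet(path, multiallelic = "split")
    expect_equal(nrow(cs2), 3L)
    expect_setequal(variantKeys(cs2),
                    c("1:100:A:T", "1:100:A:G", "1:200:G:C"))
    expect_equal(unname(altReads(cs2)[variantKeys(cs2) == "1:100:A:G", 1]),
                 6L)
})

test_that("write + read round-trips a call set field-exactly", {
    sim <- simulateCohort(smallSimConfig(seed = 21))
    cs <- sim$callSet
    path <- withr::local_tempfile(fileext = ".vcf")
    writeCallSet(cs, path)
    cs2 <- readCallSet(path)
    expect_identical(variantKeys(cs2), variantKeys(cs))
    expect_identical(refReads(cs2), refReads(cs))
    expect_identical(altReads(cs2), altReads(cs))
    expect_identical(inDb(cs2), inDb(cs))
    expect_equal(poolSize(cs2), poolSize(cs))
    expect_lt(max(abs(qualScores(cs2) - qualScores(cs)) /
                  pmax(qualScores(cs), 1)), 1e-9)
    ## empty and single-variant sets stay valid VCFs
    writeCallSet(cs[0, ], path)
    expect_equal(nrow(readCallSet(path)), 0L)
    dataLines <- grep("^[^#]", readLines(path))
    expect_length(dataLines, 0L)
    writeCallSet(cs[1, ], path)
    expect_length(grep("^[^#]", readLines(path)), 1L)
})

test_that("truth tables deduplicate, round-trip and report bad lines", {
    path <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("1\t100\tA\tT", "1\t100\tA\tT", "2\t50\tG\tC"), path)
    expect_setequal(readTruthSet(path), c("1:100:A:T", "2:50:G:C"))

    writeLines(character(), path)
    expect_length(readTruthSet(path), 0L)

    writeLines(c("1\t100\tA\tT", "garbage line"), path)
    expect_error(readTruthSet(path), "line 2")

    sim <- simulateCohort(smallSimConfig(seed = 33))
    keys <- sim$truth$key[sim$truth$isTrue]
    writeTruthSet(keys, path)
    expect_setequal(readTruthSet(path), keys)
})

test_that("membership tables override the ID rule", {
    sim <- simulateCohort(smallSimConfig(seed = 8))
    cs <- sim$callSet
    vcfPath <- withr::local_tempfile(fileext = ".vcf")
    memPath <- withr::local_tempfile(fileext = ".tsv")
    writeCallSet(cs, vcfPath)
    keys <- variantKeys(cs)
    writeTruthSet(keys[c(1, 3)], memPath)
    cs2 <- readCallSet(vcfPath, membership = memPath)
    expect_equal(which(inDb(cs2)), c(1L, 3L))
})
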