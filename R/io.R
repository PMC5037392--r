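#' Read a pooled variant call set from a VCF file
#'
#' Reads a multi-pool VCF (as produced by a pooled caller such as CRISP,
#' one sample column per pool) into a [PoolCallSet]. Per-pool REF/ALT read
#' counts are taken from an allelic-depth-style FORMAT field (default `AD`,
#' `Number=R`: REF depth followed by ALT depth). Only biallelic SNV records
#' are retained; INDELs and other non-SNV records are skipped with a counted
#' message (or rejected in strict mode). Database membership is assigned
#' either by the default ID rule (`ID` present and not `"."`) or from an
#' explicit membership table.
#'
#' @param file Path to a VCF 4.x file.
#' @param membership `NULL` for the ID rule; otherwise a character vector of
#'   `"chrom:pos:ref:alt"` keys, or the path to a tab-separated membership
#'   table with columns chrom, pos, ref, alt (see [readTruthSet()]).
#' @param countField FORMAT field holding per-pool allelic depths
#'   (default `"AD"`); the field must contain one REF and one ALT count.
#' @param poolSize Individuals per pool; if `NULL`, taken from a
#'   `##poolSize=` header line (written by [writeCallSet()]).
#' @param multiallelic `"reject"` (default: records skipped and counted) or
#'   `"split"` (expanded into biallelic records with per-allele counts).
#' @param strict Logical; if `TRUE` any skipped record is an error instead.
#' @param verbose Message the number of skipped records.
#' @return A [PoolCallSet]. `metadata(x)$skipped` records how many non-SNV
#'   and multiallelic records were excluded.
#' @seealso [writeCallSet()], [readTruthSet()]
#' @export
readCallSet <- function(file, membership = NULL, countField = "AD",
                        poolSize = NULL,
                        multiallelic = c("reject", "split"),
                        strict = FALSE, verbose = TRUE) {
    multiallelic <- match.arg(multiallelic)
    if (!file.exists(file))
        stop("VCF file not found: ", file)
    vcf <- VariantAnnotation::readVcf(file, genome = "unknown")
    hdr <- VariantAnnotation::header(vcf)
    if (is.null(poolSize)) {
        mlist <- VariantAnnotation::meta(hdr)
        for (nmEl in names(mlist)) {
            df <- mlist[[nmEl]]
            if ("poolSize" %in% rownames(df))
                poolSize <- suppressWarnings(as.integer(df["poolSize", 1L]))
        }
    }
    if (is.null(poolSize) || is.na(poolSize))
        stop("poolSize not supplied and no ##poolSize header line found")

    nAlt <- S4Vectors::elementNROWS(VariantAnnotation::alt(vcf))
    nMulti <- sum(nAlt > 1L)
    if (nMulti > 0L) {
        if (multiallelic == "reject") {
            if (strict)
                stop(nMulti, " multiallelic record(s) present; use ",
                     "multiallelic = 'split' or remove them")
            vcf <- vcf[nAlt == 1L]
        } else {
            vcf <- VariantAnnotation::expand(vcf)
        }
    }

    rr <- SummarizedExperiment::rowRanges(vcf)
    altv <- VariantAnnotation::alt(vcf)
    if (!methods::is(altv, "DNAStringSet"))
        altv <- unlist(altv)
    refv <- as.character(VariantAnnotation::ref(vcf))
    altc <- as.character(altv)
    bases <- c("A", "C", "G", "T")
    isSnv <- nchar(refv) == 1L & nchar(altc) == 1L &
        refv %in% bases & altc %in% bases & refv != altc
    nNonSnv <- sum(!isSnv)
    if (nNonSnv > 0L) {
        if (strict)
            stop(nNonSnv, " non-SNV record(s), e.g. ",
                 names(rr)[which(!isSnv)[1L]])
        if (verbose)
            message(nNonSnv, " non-SNV record(s) skipped")
    }

    g <- VariantAnnotation::geno(vcf)
    if (!countField %in% names(g))
        stop("per-pool count field '", countField,
             "' is missing from the VCF FORMAT fields")
    ad <- g[[countField]]
    if (is.list(ad)) {
        getEl <- function(i) {
            v <- vapply(ad, function(z) {
                if (length(z) < 2L) NA_integer_ else as.integer(z[i])
            }, integer(1L))
            matrix(v, nrow = nrow(ad), ncol = ncol(ad))
        }
        refm <- getEl(1L); altm <- getEl(2L)
    } else if (length(dim(ad)) == 3L) {
        refm <- ad[, , 1L, drop = TRUE]
        altm <- ad[, , 2L, drop = TRUE]
        if (is.null(dim(refm))) {   # single record or single sample
            refm <- matrix(refm, nrow = nrow(ad), ncol = ncol(ad))
            altm <- matrix(altm, nrow = nrow(ad), ncol = ncol(ad))
        }
    } else stop("cannot interpret '", countField, "' as REF/ALT depth pairs")
    storage.mode(refm) <- "integer"
    storage.mode(altm) <- "integer"

    chrom <- as.character(GenomicRanges::seqnames(rr))
    pos <- GenomicRanges::start(rr)
    if (anyNA(refm[isSnv, , drop = FALSE]) ||
        anyNA(altm[isSnv, , drop = FALSE])) {
        badRow <- which(isSnv & (rowSums(is.na(refm)) + rowSums(is.na(altm)) > 0))[1L]
        stop("missing per-pool counts in record ",
             makeKeys(chrom[badRow], pos[badRow], refv[badRow], altc[badRow]))
    }

    nm <- names(rr)
    constructed <- paste0(chrom, ":", pos, "_", refv, "/", altc)
    idFlag <- !(is.na(nm) | nm == "." | nm == "" | nm == constructed)

    keep <- which(isSnv)
    keys <- makeKeys(chrom[keep], pos[keep], refv[keep], altc[keep])
    if (anyDuplicated(keys))
        stop("duplicate variant key(s) in VCF: ",
             keys[duplicated(keys)][1L])

    if (is.null(membership)) {
        flag <- idFlag[keep]
    } else {
        if (length(membership) == 1L && file.exists(membership))
            membership <- readTruthSet(membership)
        flag <- keys %in% membership
    }

    pools <- colnames(vcf) %||% sprintf("pool%02d", seq_len(ncol(refm)))
    cs <- poolCallSet(chrom = chrom[keep], pos = pos[keep],
                      ref = refv[keep], alt = altc[keep],
                      qual = VariantAnnotation::fixed(vcf)$QUAL[keep],
                      inDb = flag,
                      refReads = refm[keep, , drop = FALSE],
                      altReads = altm[keep, , drop = FALSE],
                      poolSize = poolSize, poolNames = pools)
    S4Vectors::metadata(cs)$skipped <-
        c(nonSnv = nNonSnv,
          multiallelic = if (multiallelic == "reject") nMulti else 0L)
    cs
}

#' Write a PoolCallSet to a VCF file
#'
#' Emits a VCF 4.2 file with one sample column per pool carrying REF/ALT
#' allelic depths in the `AD` FORMAT field, the caller quality in `QUAL`,
#' and the pool size in a `##poolSize=` header line. Database-annotated
#' variants receive a synthetic ID (`db_<chrom>_<pos>_<ref>_<alt>`), novel
#' variants `"."`, so that membership round-trips through the default ID
#' rule of [readCallSet()].
#'
#' @param cs A [PoolCallSet].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
writeCallSet <- function(cs, file) {
    rd <- SummarizedExperiment::rowData(cs)
    chrom <- as.character(GenomicRanges::seqnames(cs))
    pos <- GenomicRanges::start(cs)
    hdr <- c("##fileformat=VCFv4.2",
             paste0("##poolSize=", poolSize(cs)),
             paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
                    "Description=\"Allelic depths (REF,ALT reads) ",
                    "per pool\">"),
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", colnames(cs)), collapse = "\t"))
    con <- file(file, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(hdr, con)
    if (nrow(cs) > 0L) {
        id <- ifelse(rd$inDb,
                     paste("db", chrom, pos, rd$ref, rd$alt, sep = "_"),
                     ".")
        refm <- refReads(cs); altm <- altReads(cs)
        adCols <- matrix(paste0(refm, ",", altm), nrow = nrow(cs))
        lines <- paste(chrom, pos, id, rd$ref, rd$alt,
                       sprintf("%.12g", rd$qual), ".", ".", "AD",
                       apply(adCols, 1L, paste, collapse = "\t"),
                       sep = "\t")
        writeLines(lines, con)
    }
    invisible(file)
}

#' Read a truth or membership table of variant keys
#'
#' Accepts either a VCF (keys taken from its SNV records) or a tab-separated
#' table with columns chrom, pos, ref, alt (an optional header line is
#' recognised). The same format serves both individual-sequencing truth sets
#' and database-membership sidecar tables. Keys are deduplicated.
#'
#' @param file Path to a `.vcf` file or a 4-column TSV.
#' @return Character vector of unique `"chrom:pos:ref:alt"` keys.
#' @seealso [writeTruthSet()], [readCallSet()]
#' @export
readTruthSet <- function(file) {
    if (!file.exists(file))
        stop("truth file not found: ", file)
    if (grepl("\\.vcf(\\.gz|\\.bgz)?$", file, ignore.case = TRUE)) {
        vcf <- VariantAnnotation::readVcf(file, genome = "unknown")
        vcf <- VariantAnnotation::expand(vcf)
        rr <- SummarizedExperiment::rowRanges(vcf)
        keys <- makeKeys(as.character(GenomicRanges::seqnames(rr)),
                         GenomicRanges::start(rr),
                         as.character(VariantAnnotation::ref(vcf)),
                         as.character(VariantAnnotation::alt(vcf)))
        return(unique(keys))
    }
    lines <- readLines(file, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) return(character())
    fields <- strsplit(lines, "\t", fixed = TRUE)
    start <- 1L
    f1 <- fields[[1L]]
    if (length(f1) >= 2L && is.na(suppressWarnings(as.integer(f1[2L]))))
        start <- 2L                     # header line
    keys <- character(0)
    if (start <= length(lines)) {
        for (i in seq(start, length(lines))) {
            f <- fields[[i]]
            if (length(f) < 4L)
                stop("malformed truth line ", i, ": expected 4 ",
                     "tab-separated columns (chrom, pos, ref, alt)")
            if (is.na(suppressWarnings(as.integer(f[2L]))))
                stop("malformed truth line ", i, ": position '", f[2L],
                     "' is not an integer")
        }
        m <- do.call(rbind, fields[seq(start, length(lines))])
        keys <- makeKeys(m[, 1L], as.integer(m[, 2L]), m[, 3L], m[, 4L])
    }
    unique(keys)
}

#' Write a truth or membership table
#'
#' @param keys Character vector of `"chrom:pos:ref:alt"` keys.
#' @param file Output path (tab-separated, header `chrom pos ref alt`).
#' @return `file`, invisibly.
#' @export
writeTruthSet <- function(keys, file) {
    df <- if (length(keys)) splitKeys(unique(keys)) else
        data.frame(chrom = character(), pos = integer(),
                   ref = character(), alt = character())
    utils::write.table(df, file, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    invisible(file)
}

#' Write a per-variant allele-frequency table
#'
#' TSV with columns chrom, pos, ref, alt, the cohort AF (`pool_af`, the
#' unweighted mean of per-pool AFs) and one AF column per pool.
#'
#' @param cs A [PoolCallSet].
#' @param file Output path.
#' @inheritParams cohortAF
#' @return `file`, invisibly.
#' @export
writeAFTable <- function(cs, file, zeroDepth = c("exclude", "zero")) {
    zeroDepth <- match.arg(zeroDepth)
    rd <- SummarizedExperiment::rowData(cs)
    af <- perPoolAF(cs)
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(cs)),
                     pos = GenomicRanges::start(cs),
                     ref = rd$ref, alt = rd$alt,
                     pool_af = cohortAF(cs, zeroDepth = zeroDepth))
    afDf <- as.data.frame(af)
    names(afDf) <- colnames(cs)
    utils::write.table(cbind(df, afDf), file, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    invisible(file)
}
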