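#' Run the full filtering workflow on a call set
#'
#' Chains the guideline end to end: scan the QF grid and the MPF grid for
#' the thresholds minimising the KS D statistic between the in.db and novel
#' QUAL distributions, apply each filter at its selected threshold,
#' intersect the two survivor sets, and (when a truth set is supplied)
#' benchmark the unfiltered and filtered call sets, stratified by rare and
#' common variants.
#'
#' @param cs A [PoolCallSet].
#' @param truth Optional character vector of truth keys.
#' @param qfGrid,mpfGrid Threshold grids (defaults [defaultGrid()]).
#' @param subset,rarityCutoff Passed to [scanThresholds()]; the rarity
#'   cutoff is also used for the stratified benchmark.
#' @param outDir Optional directory: writes `scan_qf.tsv`, `scan_mpf.tsv`,
#'   per-scan JSON summaries, the filtered VCF (`filtered.vcf`), a
#'   validation TSV when truth is given, and a provenance JSON.
#' @return A list with elements `qfScan`, `mpfScan` ([ScanResult]), `qfOut`,
#'   `mpfOut` ([FilterOutcome]), `intersection` ([PoolCallSet]),
#'   `intersectionDstat`, and when truth was given, `validation` — a list
#'   with `unfiltered` and `filtered` stratified [TruthComparison] maps.
#' @examples
#' sim <- simulateCohort(simConfig(seed = 3, numPools = 12,
#'     numTrueVariants = 200, numErrorSites = 800))
#' res <- runPipeline(sim$callSet, truth = sim$truth$key[sim$truth$isTrue],
#'                    qfGrid = as.numeric(20:80))
#' res$qfScan
#' res$validation$filtered$all
#' @export
runPipeline <- function(cs, truth = NULL, qfGrid = NULL, mpfGrid = NULL,
                        subset = "all", rarityCutoff = 0.01,
                        outDir = NULL) {
    qfScan <- scanThresholds(cs, "qf", grid = qfGrid, subset = subset,
                             rarityCutoff = rarityCutoff)
    mpfScan <- scanThresholds(cs, "mpf", grid = mpfGrid, subset = subset,
                              rarityCutoff = rarityCutoff)
    qfOut <- applyQf(cs, bestThreshold(qfScan))
    mpfOut <- applyMpf(cs, bestThreshold(mpfScan))
    both <- intersectFilters(qfOut, mpfOut)

    interDstat <- tryCatch({
        sq <- stratifyQuals(both)
        ksD(sq$inDb, sq$novel)
    }, error = function(e) NA_real_)

    res <- list(qfScan = qfScan, mpfScan = mpfScan,
                qfOut = qfOut, mpfOut = mpfOut,
                intersection = both, intersectionDstat = interDstat)

    if (!is.null(truth)) {
        af0 <- cohortAF(cs)
        names(af0) <- variantKeys(cs)
        unf <- stratifiedTruthComparison(cs, truth,
                                         rarityCutoff = rarityCutoff,
                                         af = af0)
        fil <- stratifiedTruthComparison(both, truth,
                                         rarityCutoff = rarityCutoff,
                                         baseline = unf, af = af0)
        res$validation <- list(unfiltered = unf, filtered = fil)
    }

    if (!is.null(outDir)) {
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        utils::write.table(as.data.frame(qfScan),
            file.path(outDir, "scan_qf.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
        utils::write.table(as.data.frame(mpfScan),
            file.path(outDir, "scan_mpf.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
        jsonlite::write_json(
            list(qf = list(best_threshold = bestThreshold(qfScan),
                           best_dstat = bestDstat(qfScan)),
                 mpf = list(best_threshold = bestThreshold(mpfScan),
                            best_dstat = bestDstat(mpfScan)),
                 intersection = list(n = nrow(both),
                                     dstat = interDstat)),
            file.path(outDir, "summary.json"),
            auto_unbox = TRUE, digits = NA, na = "null")
        writeCallSet(both, file.path(outDir, "filtered.vcf"))
        if (!is.null(res$validation))
            utils::write.table(validationTable(res$validation),
                file.path(outDir, "validation.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
        writeProvenance(outDir, list(
            step = "pipeline", subset = subset,
            rarity_cutoff = rarityCutoff,
            qf_grid = range(qfScan@grid), mpf_grid = range(mpfScan@grid)))
    }
    res
}

#' Flatten a stratified validation result to a table
#'
#' @param validation A list with `unfiltered` and `filtered` elements as
#'   returned in `runPipeline()$validation`.
#' @return data.frame with columns stratum, filter_state, n_called, n_tp,
#'   tp_retained_percent, fpr_percent.
#' @export
validationTable <- function(validation) {
    rows <- list()
    for (state in names(validation))
        for (stratum in names(validation[[state]]))
            rows[[length(rows) + 1L]] <- cbind(
                data.frame(stratum = stratum, filter_state = state),
                as.data.frame(validation[[state]][[stratum]]))
    do.call(rbind, rows)
}

# Machine-readable provenance record written next to every CLI output.
writeProvenance <- function(outDir, extra = list()) {
    info <- c(list(
        package = "PoolSeqFilter",
        version = as.character(utils::packageVersion("PoolSeqFilter")),
        r_version = R.version.string,
        date = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")), extra)
    jsonlite::write_json(info, file.path(outDir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(NULL)
}
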